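#!/usr/bin/env Rscript
# Stage 1: draw the two-transect environmental table and a synthetic aligned
# amplicon community with planted sub-OTU structure; write them under
# results/data/ for the downstream stages.

library(oligoscope)

seed <- 20260923L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

env <- generate_env_table(13, seed = seed)
write_tsv_file(env, file.path(out, "env_table.tsv"))

design <- community_design(n_otus = 30, seed = seed)
sim <- generate_community(design, env)
write_alignments(sim$read_sets, file.path(out, "alignments"))

truth_slim <- lapply(sim$truth, function(tr)
  tr[c("otu_id", "scenario", "n_subpops", "variant_positions",
       "phylum", "class")])
jsonlite::write_json(truth_slim, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)

n_reads <- sum(vapply(sim$read_sets, function(r) nrow(r$reads), integer(1)))
cat(sprintf("simulated %d OTUs (%d reads) across %d sites\n",
            design$n_otus, n_reads, nrow(env)))
cat("scenario mix:\n")
print(table(design$scenarios))
cat(sprintf("depth range %.0f-%.0f m; depth-CPE correlation %.2f\n",
            min(env$depth), max(env$depth), cor(env$depth, env$cpe)))
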