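#!/usr/bin/env Rscript
# Stage 2: decompose each simulated OTU alignment into oligotypes by
# recursive maximum-entropy position selection (>100 reads per OTU, >=21
# sequences and >0.6 bits per round), drop incomplete-alignment reads,
# tabulate counts in transect site order and remove absolute singletons.

library(oligoscope)

env <- read_tsv_file("results/data/env_table.tsv")
read_sets <- read_alignments("results/data/alignments")
truth <- jsonlite::read_json("results/data/ground_truth.json")

params <- oligotyping_params()   # 21 / 0.6 bits / 100 reads
tables <- list()
n_singletons <- 0L
n_incomplete <- 0L
for (rs in read_sets) {
  if (nrow(rs$reads) <= params$min_otu_reads) next
  rs$taxonomy <- paste(truth[[rs$otu_id]]$phylum, truth[[rs$otu_id]]$class,
                       sep = ";")
  oset <- drop_incomplete(decompose(rs, params))
  n_incomplete <- n_incomplete + length(oset$incomplete_reads)
  tb <- remove_singletons(tabulate_oligotypes(oset, site_order(env)))
  n_singletons <- n_singletons + attr(tb, "n_removed")
  if (nrow(tb)) tables[[rs$otu_id]] <- tb
}

combined <- do.call(rbind, unname(tables))
write_tsv_file(combined, "results/oligotype_table.tsv")
tax <- do.call(rbind, lapply(tables, function(tb) {
  t2 <- strsplit(attr(tb, "taxonomy"), ";")[[1]]
  data.frame(otu_id = attr(tb, "otu_id"), phylum = t2[1], class = t2[2])
}))
write_tsv_file(tax, "results/otu_taxonomy.tsv")

per_otu <- vapply(tables, nrow, integer(1))
cat(sprintf("oligotyped %d OTUs into %d oligotypes (%d singletons removed, %d reads set aside as incomplete)\n",
            length(tables), nrow(combined), n_singletons, n_incomplete))
cat(sprintf("oligotypes per OTU: min %d, median %.0f, max %d\n",
            min(per_otu), median(per_otu), max(per_otu)))
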