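#' Assemble a pipeline run configuration
#'
#' Defaults reproduce the analysis conditions used throughout: oligotyping
#' thresholds 100 reads / 21 sequences / 0.6 bits, third-quartile C/T
#' screening, RDA at >50% constrained variation and adjusted p < 0.05 with
#' 999 permutations, IA networks at IA > 85 with 200 permutations and
#' adjusted p < 0.05, MCL inflation 2.5. One global seed deterministically
#' derives all per-stage seeds.
#'
#' @param out_dir output directory.
#' @param alignments_dir directory of aligned FASTA files; `NULL` to
#'   simulate instead.
#' @param simulate list of [community_design()] arguments (used when
#'   `alignments_dir` is `NULL`); at minimum `n_otus`.
#' @param env environmental table, or `NULL` to generate one.
#' @param min_otu_reads,min_reads_for_round,min_entropy oligotyping
#'   thresholds.
#' @param rda_alpha,rda_min_constrained,rda_permutations RDA stage settings.
#' @param ia_min,ia_alpha,ia_permutations,min_abundance network stage
#'   settings.
#' @param inflation MCL granularity.
#' @param stages character vector of stages to run, in order, among
#'   `simulate`, `oligotype`, `screen`, `rda`, `network`.
#' @param seed global integer seed.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir,
                       alignments_dir = NULL,
                       simulate = list(n_otus = 40L),
                       env = NULL,
                       min_otu_reads = 100L, min_reads_for_round = 21L,
                       min_entropy = 0.6,
                       rda_alpha = 0.05, rda_min_constrained = 0.5,
                       rda_permutations = 999L,
                       ia_min = 85, ia_alpha = 0.05, ia_permutations = 200L,
                       min_abundance = 2L, inflation = 2.5,
                       stages = c("simulate", "oligotype", "screen",
                                  "rda", "network"),
                       seed = 1L) {
  stopifnot(min_entropy > 0, rda_alpha > 0, rda_alpha < 1,
            ia_min >= 0, ia_min <= 100, inflation > 1)
  structure(as.list(environment()), class = "run_config")
}

#' Load / save a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config a `run_config`.
#' @return `read_run_config` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$env <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) * 131L + match(stage, c("simulate", "oligotype", "screen",
                                            "rda", "network"))) %% 2147483L
}

#' Run the oligotyping microdiversity pipeline
#'
#' Executes the enabled stages in order — simulate (or read alignments),
#' oligotype, screen, ordinate, network — writing per-stage TSV/JSON/GraphML
#' outputs under `config$out_dir` and a JSON run manifest recording seeds,
#' parameters and per-stage record counts (reads in, reads retained,
#' oligotypes, singletons removed, OTUs screened, models selected, network
#' nodes/edges, MCL clusters).
#'
#' @param config a [run_config()].
#' @return the manifest list, invisibly; also written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("oligoscope")),
                   seed = config$seed,
                   parameters = list(
                     min_otu_reads = config$min_otu_reads,
                     min_reads_for_round = config$min_reads_for_round,
                     min_entropy = config$min_entropy,
                     rda_alpha = config$rda_alpha,
                     rda_min_constrained = config$rda_min_constrained,
                     rda_permutations = config$rda_permutations,
                     ia_min = config$ia_min, ia_alpha = config$ia_alpha,
                     ia_permutations = config$ia_permutations,
                     min_abundance = config$min_abundance,
                     inflation = config$inflation),
                   stages = list())

  env <- config$env
  if (is.null(env))
    env <- generate_env_table(seed = stage_seed(config$seed, "simulate"))
  write_tsv_file(env, file.path(config$out_dir, "env_table.tsv"))

  truth <- NULL
  if ("simulate" %in% config$stages && is.null(config$alignments_dir)) {
    args <- config$simulate
    args$n_sites <- nrow(env)
    args$seed <- stage_seed(config$seed, "simulate")
    design <- do.call(community_design, args)
    sim <- generate_community(design, env)
    read_sets <- sim$read_sets
    truth <- sim$truth
    write_alignments(read_sets, file.path(config$out_dir, "alignments"))
    jsonlite::write_json(
      lapply(truth, function(tr) tr[c("otu_id", "scenario", "n_subpops",
                                      "variant_positions", "phylum", "class")]),
      file.path(config$out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
    manifest$stages$simulate <- list(
      complete = TRUE, n_otus = length(read_sets),
      n_reads = sum(vapply(read_sets, function(r) nrow(r$reads), integer(1))))
  } else {
    if (is.null(config$alignments_dir))
      stop("stage failure [simulate]: no alignments dir and simulation disabled")
    read_sets <- read_alignments(config$alignments_dir)
    manifest$stages$simulate <- list(
      complete = TRUE, n_otus = length(read_sets), source = config$alignments_dir,
      n_reads = sum(vapply(read_sets, function(r) nrow(r$reads), integer(1))))
  }

  params <- oligotyping_params(config$min_reads_for_round, config$min_entropy,
                               config$min_otu_reads)
  tables <- list()
  n_incomplete <- 0L
  n_singletons <- 0L
  reads_in_oligotypes <- 0L
  reads_total <- 0L
  reads_skipped <- 0L
  if ("oligotype" %in% config$stages) {
    for (rs in read_sets) {
      reads_total <- reads_total + nrow(rs$reads)
      if (nrow(rs$reads) <= config$min_otu_reads) {
        reads_skipped <- reads_skipped + nrow(rs$reads)
        next
      }
      oset <- drop_incomplete(decompose(rs, params))
      n_incomplete <- n_incomplete + length(oset$incomplete_reads)
      tb <- tabulate_oligotypes(oset, site_order(env))
      reads_in_oligotypes <- reads_in_oligotypes + sum(tb)
      tb <- remove_singletons(tb)
      n_singletons <- n_singletons + attr(tb, "n_removed")
      if (nrow(tb)) tables[[rs$otu_id]] <- tb
    }
    combined <- do.call(rbind, unname(tables))
    write_tsv_file(combined, file.path(config$out_dir, "oligotype_table.tsv"))
    manifest$stages$oligotype <- list(
      complete = TRUE,
      n_otus_oligotyped = length(tables),
      n_oligotypes = if (is.null(combined)) 0L else nrow(combined),
      n_reads_total = reads_total,
      n_reads_in_oligotypes = reads_in_oligotypes,
      n_reads_incomplete = n_incomplete,
      n_reads_skipped_small_otus = reads_skipped,
      n_singletons_removed = n_singletons)
  }

  if ("screen" %in% config$stages && length(tables) >= 4L) {
    screening <- screen_community(tables)
    write_tsv_file(screening, file.path(config$out_dir, "screening.tsv"))
    manifest$stages$screen <- list(
      complete = TRUE, n_scored = nrow(screening),
      n_selected = sum(screening$selected),
      q3_c = attr(screening, "q3_c"), q3_t = attr(screening, "q3_t"))
  }

  if ("rda" %in% config$stages && length(tables)) {
    models <- ordinate_community(tables, env,
                                 alpha = config$rda_alpha,
                                 n_perm = config$rda_permutations,
                                 seed = stage_seed(config$seed, "rda"))
    write_tsv_file(models, file.path(config$out_dir, "rda_models.tsv"))
    sel <- select_models(models, config$rda_min_constrained, config$rda_alpha)
    write_tsv_file(sel, file.path(config$out_dir, "rda_selected.tsv"))
    manifest$stages$rda <- list(
      complete = TRUE, n_models = nrow(models),
      n_nontrivial = sum(models$formula != "Y ~ 1"),
      n_selected = nrow(sel))
  }

  if ("network" %in% config$stages && length(tables)) {
    combined <- do.call(rbind, unname(tables))
    keep <- rowSums(combined) >= config$min_abundance
    combined <- combined[keep, , drop = FALSE]
    node_tax <- do.call(rbind, lapply(tables, function(tb) {
      tax <- strsplit(attr(tb, "taxonomy") %||% ";", ";")[[1]]
      data.frame(node = rownames(tb),
                 phylum = tax[1] %||% NA_character_,
                 class = if (length(tax) > 1) tax[2] else NA_character_,
                 stringsAsFactors = FALSE)
    }))
    null <- ia_null(combined, n_perm = config$ia_permutations,
                    seed = stage_seed(config$seed, "network"))
    g <- build_graph(combined, null, ia_min = config$ia_min,
                     alpha = config$ia_alpha,
                     min_abundance = config$min_abundance,
                     taxonomy = node_tax)
    stats <- network_stats(g)
    export_graph(g, file.path(config$out_dir, "network.graphml"),
                 file.path(config$out_dir, "network_edges.tsv"))
    jsonlite::write_json(stats, file.path(config$out_dir, "network_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    clusters <- if (igraph::ecount(g) > 0) {
      wsub <- igraph::set_edge_attr(g, "weight",
                                    value = rescale_edge_weights(igraph::E(g)$weight))
      mcl(wsub, inflation = config$inflation)
    } else list(membership = stats::setNames(seq_len(igraph::vcount(g)),
                                             igraph::V(g)$name),
                n_clusters = igraph::vcount(g), iterations = 0L)
    memb <- data.frame(node = names(clusters$membership),
                       cluster = unname(clusters$membership))
    write_tsv_file(memb, file.path(config$out_dir, "mcl_membership.tsv"))
    summ <- cluster_summary(clusters$membership,
                            data.frame(node = igraph::V(g)$name,
                                       abundance = igraph::V(g)$abundance,
                                       phylum = igraph::V(g)$phylum %||% NA,
                                       class = igraph::V(g)$class %||% NA))
    write_tsv_file(summ, file.path(config$out_dir, "mcl_clusters.tsv"))
    manifest$stages$network <- list(
      complete = TRUE, n_nodes = stats$n_nodes, n_edges = stats$n_edges,
      n_components = stats$n_components, n_mcl_clusters = clusters$n_clusters)
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
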