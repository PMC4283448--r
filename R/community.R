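ALPHABET   <- c("A", "C", "G", "T", "-")
BASES      <- c("A", "C", "G", "T")
MISSING    <- "."
SCENARIOS  <- c("depth_linear", "cpe_linked", "checkerboard_pair",
                "aggregated_block", "neutral")

# sample one element of x (safe for length-1 x, unlike sample())
sample1 <- function(x) x[sample.int(length(x), 1L)]

# taxon pool for simulated OTU annotation (used by screening / network reports)
TAXON_POOL <- data.frame(
  phylum = c("Acidobacteria", "Acidobacteria", "Actinobacteria", "Bacteroidetes",
             "Gemmatimonadetes", "Planctomycetes", "Proteobacteria", "Proteobacteria",
             "Proteobacteria", "Proteobacteria", "Verrucomicrobia", "Chloroflexi"),
  class  = c("Acidobacteria", "Subgroup 22", "Acidimicrobiia", "Flavobacteria",
             "Gemmatimonadetes", "Planctomycetacia", "Alphaproteobacteria",
             "Deltaproteobacteria", "Gammaproteobacteria", "Epsilonproteobacteria",
             "Verrucomicrobiae", "Anaerolineae"),
  stringsAsFactors = FALSE
)

#' Describe a synthetic community design
#'
#' Bundles and validates the parameters of the synthetic amplicon community
#' generator. Each OTU is assigned a scenario that shapes how its planted
#' sub-populations are distributed across sites:
#' \describe{
#'   \item{`depth_linear`}{expected counts log-linear in z-scored water depth,
#'     with sub-population-specific slopes of alternating sign.}
#'   \item{`cpe_linked`}{as above, driven by the CPE (pigment) gradient.}
#'   \item{`checkerboard_pair`}{sub-populations split into two blocks with
#'     mutually disjoint site support (and some sites occupied by neither),
#'     producing checkered presence patterns.}
#'   \item{`aggregated_block`}{all sub-populations share one site-support
#'     block, producing aggregated (togetherness) patterns.}
#'   \item{`neutral`}{uniform expected counts across sites.}
#' }
#'
#' @param n_otus number of OTUs to simulate.
#' @param n_sites number of sites (must match the environmental table).
#' @param reads_per_otu length-2 range of total reads per OTU.
#' @param variant_positions length-2 range for the number of planted
#'   high-entropy alignment positions per OTU (0 allowed for neutral OTUs).
#' @param read_length aligned read length in bases.
#' @param error_rate per-base substitution probability, in \[0, 0.5).
#' @param scenarios character vector of length `n_otus`; defaults to a mix
#'   drawn by [default_scenarios()].
#' @param incomplete_fraction fraction of reads carrying a terminal
#'   missing-coverage (`.`) stretch.
#' @param incomplete_max maximum length of a terminal `.` stretch.
#' @param site_depth_multiplier optional per-site sequencing-effort
#'   multiplier (length `n_sites`), defaults to even effort.
#' @param seed integer seed driving the whole generation.
#' @return a `community_design` list.
#' @export
community_design <- function(n_otus,
                             n_sites = 13L,
                             reads_per_otu = c(100L, 3000L),
                             variant_positions = c(0L, 5L),
                             read_length = 400L,
                             error_rate = 0.001,
                             scenarios = NULL,
                             incomplete_fraction = 0.05,
                             incomplete_max = 10L,
                             site_depth_multiplier = NULL,
                             seed = 1L) {
  if (n_otus < 1 || n_sites < 4 || read_length < 50)
    stop("invalid design: counts must be positive (n_sites >= 4, read_length >= 50)")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("invalid design: error_rate must lie in [0, 0.5)")
  if (length(reads_per_otu) != 2L || reads_per_otu[1] > reads_per_otu[2] ||
      reads_per_otu[1] < 1)
    stop("invalid design: reads_per_otu must be an increasing positive range")
  if (length(variant_positions) != 2L || variant_positions[1] > variant_positions[2] ||
      variant_positions[1] < 0 || variant_positions[2] > 5)
    stop("invalid design: variant_positions must be a range within [0, 5]")
  if (is.null(scenarios)) scenarios <- default_scenarios(n_otus, seed = seed)
  if (length(scenarios) != n_otus)
    stop("invalid design: scenario list length must equal n_otus")
  if (!all(scenarios %in% SCENARIOS))
    stop("invalid design: unknown scenario(s): ",
         paste(setdiff(scenarios, SCENARIOS), collapse = ", "))
  if (is.null(site_depth_multiplier)) site_depth_multiplier <- rep(1, n_sites)
  if (length(site_depth_multiplier) != n_sites || any(site_depth_multiplier <= 0))
    stop("invalid design: site_depth_multiplier must be positive, length n_sites")
  structure(list(
    n_otus = as.integer(n_otus), n_sites = as.integer(n_sites),
    reads_per_otu = as.integer(reads_per_otu),
    variant_positions = as.integer(variant_positions),
    read_length = as.integer(read_length), error_rate = error_rate,
    scenarios = scenarios,
    incomplete_fraction = incomplete_fraction,
    incomplete_max = as.integer(incomplete_max),
    site_depth_multiplier = site_depth_multiplier,
    seed = as.integer(seed)
  ), class = "community_design")
}

#' Default scenario mix for a simulated community
#'
#' Most OTUs are unstructured (neutral) with smaller fractions carrying
#' gradient responses and presence-pattern structure, mirroring the empirical
#' observation that only a minority of OTU-level microdiversity is strongly
#' structured by the measured variables.
#'
#' @param n_otus number of OTUs.
#' @param seed integer seed.
#' @return character vector of scenarios, length `n_otus`.
#' @export
default_scenarios <- function(n_otus, seed = 1L) {
  set.seed(seed)
  sample(SCENARIOS, n_otus, replace = TRUE,
         prob = c(0.20, 0.10, 0.15, 0.15, 0.40))
}

#' Generate a synthetic aligned amplicon community
#'
#' For each OTU, plants 1-5 sub-populations distinguished by fixed characters
#' (including the gap character `-`) at a small number of interior alignment
#' positions, draws per-site sub-population counts as Poisson variates around
#' scenario-defined expectations, writes reads as rows of a character matrix
#' sharing one base sequence, optionally masks terminal stretches with `.`
#' (missing coverage), and applies per-base sequencing error.
#'
#' @param design a [community_design()].
#' @param env an environmental table from [generate_env_table()] with
#'   `design$n_sites` rows.
#' @return a list with elements `read_sets` (list of `aligned_read_set`:
#'   `otu_id`, `reads` character matrix, `site_of_read`, `taxonomy`) and
#'   `truth` (per-OTU ground truth: sub-population of each read, variant
#'   positions, discriminant characters, expected and realized site
#'   profiles, scenario coefficients, taxonomy).
#' @export
generate_community <- function(design, env) {
  stopifnot(inherits(design, "community_design"))
  if (nrow(env) != design$n_sites)
    stop("invalid design: env has ", nrow(env), " rows but design expects ",
         design$n_sites, " sites")
  set.seed(design$seed)
  sites <- env$site_id
  zdepth <- as.numeric(scale(env$depth))
  zcpe   <- as.numeric(scale(env$cpe))
  effort <- design$site_depth_multiplier / mean(design$site_depth_multiplier)

  otu_ids <- sprintf("OTU%03d", seq_len(design$n_otus))
  read_sets <- vector("list", design$n_otus)
  truth <- vector("list", design$n_otus)
  names(read_sets) <- names(truth) <- otu_ids

  margin <- design$incomplete_max + 20L

  for (i in seq_len(design$n_otus)) {
    otu <- otu_ids[i]
    scen <- design$scenarios[i]
    lo <- design$reads_per_otu[1]; hi <- design$reads_per_otu[2]
    target <- round(stats::runif(1, lo, hi))

    k <- sample1(seq(design$variant_positions[1], design$variant_positions[2]))
    if (scen != "neutral" && k == 0L) k <- 1L
    s <- if (k == 0L) 1L else {
      smax <- max(2L, min(5L, floor(target / 40)))
      lo_s <- if (scen == "checkerboard_pair") min(4L, smax) else 2L
      sample1(seq(lo_s, smax))
    }

    # sub-population weights with a floor of 1/(2s): keeps every planted
    # variant column's minority fraction well above the 1:6 detectability limit
    w <- stats::rgamma(s, 5); w <- w / sum(w)
    f <- 1 / (2 * s)
    w <- (1 - s * f) * w + f

    # expected site profile per sub-population, by scenario
    E <- matrix(0, s, design$n_sites)
    coef <- list(scenario = scen)
    if (scen == "neutral") {
      E[] <- outer(w * target, rep(1 / design$n_sites, design$n_sites))
    } else if (scen %in% c("depth_linear", "cpe_linked")) {
      zz <- if (scen == "depth_linear") zdepth else zcpe
      b <- stats::runif(s, 0.8, 1.4) * rep_len(c(1, -1), s)
      coef$slope <- b
      for (j in seq_len(s)) {
        e <- exp(b[j] * zz)
        E[j, ] <- w[j] * target * e / sum(e)
      }
    } else if (scen == "checkerboard_pair") {
      m <- max(2L, floor(design$n_sites / 3))
      perm <- sample(design$n_sites)
      sup1 <- perm[seq_len(m)]; sup2 <- perm[m + seq_len(m)]
      block <- rep_len(c(1L, 2L), s)    # subpop 1 -> block 1, subpop 2 -> block 2
      coef$support <- list(sites[sup1], sites[sup2]); coef$block <- block
      for (j in seq_len(s)) {
        sup <- if (block[j] == 1L) sup1 else sup2
        E[j, sup] <- w[j] * target / length(sup)
      }
    } else if (scen == "aggregated_block") {
      m <- max(3L, min(design$n_sites - 2L, floor(design$n_sites / 2.5)))
      sup <- sample(design$n_sites, m)
      coef$support <- sites[sup]
      for (j in seq_len(s)) E[j, sup] <- w[j] * target / m
    }
    E <- sweep(E, 2, effort, `*`)
    E <- E * target / sum(E)

    # Poisson counts around the expectations; redraw if far off the target range
    for (try in 1:25) {
      N <- matrix(stats::rpois(length(E), E), s, design$n_sites)
      if (sum(N) >= lo && sum(N) <= hi) break
    }
    total <- sum(N)

    # discriminant characters: each sub-population gets its own character at
    # every variant position, so a single round per position separates them
    vpos <- if (k > 0) sort(sample(seq(margin + 1L, design$read_length - margin), k)) else integer(0)
    subpop_chars <- if (k > 0) {
      vapply(seq_len(k), function(p) sample(ALPHABET, s), character(s))
    } else matrix(character(0), nrow = 1)
    if (k > 0 && s == 1L) subpop_chars <- matrix(subpop_chars, nrow = 1)

    base <- sample(BASES, design$read_length, replace = TRUE)

    subpop_of_read <- rep(rep(seq_len(s), design$n_sites), as.vector(N))
    site_of_read <- rep(rep(sites, each = s), as.vector(N))
    reads <- matrix(rep(base, each = total), nrow = total)
    if (k > 0) for (p in seq_len(k))
      reads[, vpos[p]] <- subpop_chars[subpop_of_read, p]

    # terminal missing coverage
    if (design$incomplete_fraction > 0 && total > 0) {
      inc <- which(stats::runif(total) < design$incomplete_fraction)
      if (length(inc)) {
        len <- sample(design$incomplete_max, length(inc), replace = TRUE)
        at_start <- stats::runif(length(inc)) < 0.5
        for (q in seq_along(inc)) {
          if (at_start[q]) reads[inc[q], seq_len(len[q])] <- MISSING
          else reads[inc[q], design$read_length - seq_len(len[q]) + 1L] <- MISSING
        }
      }
    }

    if (design$error_rate > 0)
      reads <- inject_errors(reads, design$error_rate,
                             seed = design$seed %% 10000L * 1000L + i)

    tax <- TAXON_POOL[sample(nrow(TAXON_POOL), 1), ]
    rownames(reads) <- sprintf("%s|%s|%04d", otu, site_of_read, seq_len(total))
    read_sets[[i]] <- structure(list(
      otu_id = otu, reads = reads, site_of_read = site_of_read,
      taxonomy = paste(tax$phylum, tax$class, sep = ";")
    ), class = "aligned_read_set")

    realized <- matrix(0L, s, design$n_sites, dimnames = list(NULL, sites))
    for (j in seq_len(s)) realized[j, ] <- N[j, ]
    truth[[i]] <- list(
      otu_id = otu, scenario = scen, n_subpops = s,
      subpop_of_read = subpop_of_read,
      variant_positions = vpos,
      subpop_chars = subpop_chars,
      expected_profile = E, profile = realized,
      coefficients = coef,
      phylum = tax$phylum, class = tax$class
    )
  }
  list(read_sets = read_sets, truth = truth)
}

#' Inject per-base substitution errors into an aligned read matrix
#'
#' Each base (`A`, `C`, `G`, `T`) is independently substituted with
#' probability `error_rate`, uniformly over the three alternative bases.
#' Gap (`-`) and missing-coverage (`.`) characters are never mutated.
#'
#' @param reads character matrix of aligned reads.
#' @param error_rate substitution probability in \[0, 0.5).
#' @param seed integer seed; output is deterministic given the seed.
#' @return the mutated matrix.
#' @export
inject_errors <- function(reads, error_rate, seed = 1L) {
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  if (error_rate == 0) return(reads)
  set.seed(seed)
  eligible <- which(reads %in% BASES)
  hit <- eligible[stats::runif(length(eligible)) < error_rate]
  if (length(hit)) {
    cur <- reads[hit]
    pick <- function(b) BASES[BASES != b][sample.int(3L, 1L)]
    reads[hit] <- vapply(cur, pick, character(1), USE.NAMES = FALSE)
  }
  reads
}
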