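#' Pairwise checkerboard (C) score
#'
#' For two presence/absence vectors over the same sites, the Stone-Roberts
#' checkerboard unit count: `C = (r_i - S)(r_j - S)` where `r_i`, `r_j` are
#' the occupied-site counts and `S` the number of jointly occupied sites.
#' Equivalently, the number of 2x2 checkerboard submatrices the pair forms
#' over site pairs.
#'
#' @param x,y presence vectors (logical, or counts coerced by `> 0`).
#' @return non-negative integer score.
#' @export
pair_c_score <- function(x, y) {
  x <- x > 0; y <- y > 0
  stopifnot(length(x) == length(y))
  S <- sum(x & y)
  (sum(x) - S) * (sum(y) - S)
}

#' Pairwise togetherness (T) score
#'
#' `T = S * A`: the number of site pairs at which two oligotypes are jointly
#' present at one site and jointly absent at the other (`S` jointly-present
#' sites times `A` jointly-absent sites). High T marks aggregated occurrence.
#'
#' @inheritParams pair_c_score
#' @return non-negative integer score.
#' @export
pair_t_score <- function(x, y) {
  x <- x > 0; y <- y > 0
  stopifnot(length(x) == length(y))
  sum(x & y) * sum(!x & !y)
}

#' Mean C and T scores of an oligotype occurrence matrix
#'
#' Presence is `count > 0`; scores are averaged over all unordered oligotype
#' pairs and left in raw checkerboard/site-pair units.
#'
#' @param table oligotype-by-site count matrix with at least 2 rows.
#' @return named numeric vector `c(mean_c =, mean_t =)`.
#' @export
mean_ct_scores <- function(table) {
  m <- nrow(table)
  if (m < 2L)
    stop("undefined score: need at least 2 oligotypes, got ", m)
  P <- table > 0
  cs <- ts <- 0
  for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
    S <- sum(P[i, ] & P[j, ])
    A <- sum(!P[i, ] & !P[j, ])
    cs <- cs + (sum(P[i, ]) - S) * (sum(P[j, ]) - S)
    ts <- ts + S * A
  }
  np <- m * (m - 1L) / 2
  c(mean_c = cs / np, mean_t = ts / np)
}

#' Screen OTUs whose oligotypes show joint checkerboard and aggregation
#'
#' Computes the third quartile (linear-interpolation quantile) of the mean-C
#' and mean-T distributions across all OTU matrices and selects OTUs whose
#' mean scores strictly exceed both.
#'
#' @param scores data.frame with columns `otu_id`, `mean_c`, `mean_t` (one
#'   row per OTU; build with [screen_community()] or by hand), >= 4 rows.
#' @return the input with logical column `selected` added, plus attributes
#'   `q3_c` and `q3_t`.
#' @export
screen_by_quartile <- function(scores) {
  if (nrow(scores) < 4L) stop("need at least 4 OTUs to define quartiles")
  q3c <- stats::quantile(scores$mean_c, 0.75, type = 7, names = FALSE)
  q3t <- stats::quantile(scores$mean_t, 0.75, type = 7, names = FALSE)
  scores$selected <- scores$mean_c > q3c & scores$mean_t > q3t
  attr(scores, "q3_c") <- q3c
  attr(scores, "q3_t") <- q3t
  scores
}

#' Score every OTU's oligotype matrix and apply the quartile screen
#'
#' @param tables named list of oligotype-by-site count matrices (one per
#'   OTU, post singleton removal). Matrices with fewer than 2 rows are
#'   skipped.
#' @return data.frame (`otu_id`, `phylum`, `class`, `n_oligotypes`,
#'   `mean_c`, `mean_t`, `selected`) with quartile attributes, sorted as
#'   input.
#' @export
screen_community <- function(tables) {
  tables <- Filter(function(tb) nrow(tb) >= 2L, tables)
  if (length(tables) < 4L)
    stop("need at least 4 scoreable OTU matrices to define quartiles")
  rows <- lapply(tables, function(tb) {
    sc <- mean_ct_scores(tb)
    tax <- strsplit(attr(tb, "taxonomy") %||% ";", ";")[[1]]
    data.frame(otu_id = attr(tb, "otu_id"),
               phylum = tax[1] %||% NA_character_,
               class = if (length(tax) > 1) tax[2] else NA_character_,
               n_oligotypes = nrow(tb),
               mean_c = sc[["mean_c"]], mean_t = sc[["mean_t"]],
               stringsAsFactors = FALSE)
  })
  screen_by_quartile(do.call(rbind, c(rows, make.row.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Heatmap row order by UPGMA on Bray-Curtis dissimilarities
#'
#' Rows (oligotypes) are Hellinger-transformed, pairwise Bray-Curtis
#' dissimilarities computed, and the average-linkage (UPGMA) dendrogram's
#' leaf order returned, the ordering used for occurrence heatmaps.
#'
#' @param table oligotype-by-site count matrix, >= 2 rows.
#' @return integer permutation of the row indices.
#' @export
order_rows <- function(table) {
  if (nrow(table) < 2L) stop("need at least 2 rows to order")
  H <- hellinger(table)
  d <- vegan::vegdist(H, method = "bray")
  stats::hclust(d, method = "average")$order
}
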