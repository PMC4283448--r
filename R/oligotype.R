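#' Oligotyping thresholds
#'
#' A round of decomposition is attempted on a read group only when the group
#' holds at least `min_reads_for_round` sequences and some alignment position
#' has base-2 Shannon entropy strictly greater than `min_entropy`. At entropy
#' 0.6 one alternative character is expected for every six instances of the
#' dominant character; lower thresholds increasingly admit sequencing error
#' as structure, higher ones lose sensitivity. Only OTUs with more than
#' `min_otu_reads` reads are decomposed at all.
#'
#' @param min_reads_for_round minimum group size for a round (default 21).
#' @param min_entropy entropy threshold in bits, strict (default 0.6).
#' @param min_otu_reads minimum OTU read count, strict (default 100).
#' @return an `oligotyping_params` list.
#' @export
oligotyping_params <- function(min_reads_for_round = 21L,
                               min_entropy = 0.6,
                               min_otu_reads = 100L) {
  if (min_entropy <= 0 || min_entropy > log2(6))
    stop("min_entropy must lie in (0, log2(6)]")
  if (min_reads_for_round < 1 || min_otu_reads < 1)
    stop("count thresholds must be positive")
  structure(list(min_reads_for_round = as.integer(min_reads_for_round),
                 min_entropy = min_entropy,
                 min_otu_reads = as.integer(min_otu_reads)),
            class = "oligotyping_params")
}

#' Shannon entropy of an alignment column
#'
#' Base-2 entropy of the character frequencies over `{A, C, G, T, -}`;
#' missing-coverage characters (`.`) are excluded before frequencies are
#' computed. Monomorphic columns have entropy 0.
#'
#' @param column character vector (one alignment position across reads).
#' @return entropy in bits.
#' @export
column_entropy <- function(column) {
  column <- column[column != MISSING]
  if (!length(column))
    stop("undefined entropy: column empty after removing missing coverage")
  f <- tabulate(factor(column, levels = ALPHABET), nbins = length(ALPHABET))
  f <- f[f > 0] / sum(f)
  -sum(f * log2(f))
}

#' Percent occurrence of the dominant character in a column
#'
#' @param column character vector; `.` excluded as in [column_entropy()].
#' @return percentage in (0, 100\].
#' @export
dominant_fraction <- function(column) {
  column <- column[column != MISSING]
  if (!length(column))
    stop("undefined dominant fraction: column empty after removing missing coverage")
  100 * max(table(column)) / length(column)
}

# entropies of all columns of a character matrix; columns that are entirely
# missing get -Inf so they can never be selected
column_entropies <- function(mat) {
  apply(mat, 2, function(col) {
    col <- col[col != MISSING]
    if (!length(col)) return(-Inf)
    f <- tabulate(factor(col, levels = ALPHABET), nbins = 5L)
    f <- f[f > 0] / sum(f)
    -sum(f * log2(f))
  })
}

#' Alignment position with the greatest entropy
#'
#' @param alignment character matrix (rows reads, columns positions).
#' @return list with `position` (leftmost position attaining the maximum)
#'   and `entropy` (its value in bits).
#' @export
max_entropy_position <- function(alignment) {
  if (!nrow(alignment)) stop("empty alignment")
  H <- column_entropies(alignment)
  p <- which.max(H)           # which.max returns the leftmost maximum
  list(position = as.integer(p), entropy = max(H[p], 0))
}

#' Decompose an OTU alignment into oligotypes
#'
#' Recursive entropy decomposition: while a read group holds at least
#' `params$min_reads_for_round` sequences and its maximum column entropy
#' exceeds `params$min_entropy`, the group is split by the character carried
#' at the leftmost maximum-entropy position and each subgroup is decomposed
#' further; otherwise the group is a terminal oligotype. An oligotype's label
#' concatenates the characters at its ancestral discriminant positions in
#' selection order (gap characters appear as `-`). Reads with missing
#' coverage (`.`) at a discriminant position are set aside at that split and
#' belong to no oligotype (see [drop_incomplete()]).
#'
#' @param read_set an `aligned_read_set` (fields `otu_id`, `reads`,
#'   `site_of_read`) as produced by [generate_community()] or
#'   [read_alignments()].
#' @param params an [oligotyping_params()].
#' @return an `oligotype_set`: list with `otu_id`, `oligotypes` (each with
#'   `label`, `positions`, `reads` — row indices into the alignment — and
#'   `had_incomplete`, whether reads were set aside at splits on its path),
#'   `incomplete_reads` (indices set aside), `log` (per-round positions and
#'   entropies) and `n_reads`.
#' @export
decompose <- function(read_set, params = oligotyping_params()) {
  reads <- read_set$reads
  n <- nrow(reads)
  if (n <= params$min_otu_reads)
    stop("otu too small: ", read_set$otu_id, " has ", n,
         " reads; more than ", params$min_otu_reads, " required")

  oligos <- list()
  incomplete <- integer(0)
  log <- list()

  recurse <- function(idx, label, positions, had_incomplete) {
    if (length(idx) >= params$min_reads_for_round) {
      H <- column_entropies(reads[idx, , drop = FALSE])
      p <- which.max(H)
      if (H[p] > params$min_entropy) {
        log[[length(log) + 1L]] <<- list(label = label, position = as.integer(p),
                                         entropy = H[p], n = length(idx))
        chars <- reads[idx, p]
        miss <- chars == MISSING
        if (any(miss)) {
          incomplete <<- c(incomplete, idx[miss])
          had_incomplete <- TRUE
          idx <- idx[!miss]; chars <- chars[!miss]
        }
        for (ch in ALPHABET[ALPHABET %in% chars])
          recurse(idx[chars == ch], paste0(label, ch), c(positions, p),
                  had_incomplete)
        return(invisible(NULL))
      }
    }
    oligos[[length(oligos) + 1L]] <<- list(
      label = label, positions = as.integer(positions), reads = idx,
      had_incomplete = had_incomplete)
    invisible(NULL)
  }
  recurse(seq_len(n), "", integer(0), FALSE)

  structure(list(otu_id = read_set$otu_id, oligotypes = oligos,
                 incomplete_reads = sort(incomplete), log = log,
                 n_reads = n, site_of_read = read_set$site_of_read,
                 taxonomy = read_set$taxonomy),
            class = "oligotype_set")
}

#' Remove oligotypes touched by incomplete alignments
#'
#' Reads with missing coverage at a discriminant position are already set
#' aside during [decompose()]. With `remove_mixed = FALSE` (default) an
#' oligotype survives as long as it retains at least one complete read;
#' with `remove_mixed = TRUE` any oligotype on whose path incomplete reads
#' were shed is removed wholesale, its complete reads dropped too.
#'
#' @param oset an `oligotype_set`.
#' @param remove_mixed remove oligotypes that had incomplete siblings at a
#'   discriminant split (default `FALSE`).
#' @return the filtered `oligotype_set`, with attribute `retained_fraction`
#'   (retained reads / total reads) recorded in the `fill` field.
#' @export
drop_incomplete <- function(oset, remove_mixed = FALSE) {
  keep <- vapply(oset$oligotypes, function(o) {
    length(o$reads) >= 1L && !(remove_mixed && o$had_incomplete)
  }, logical(1))
  oset$oligotypes <- oset$oligotypes[keep]
  retained <- sum(vapply(oset$oligotypes, function(o) length(o$reads), integer(1)))
  oset$fill <- retained / oset$n_reads
  oset
}

#' Tabulate oligotypes into an oligotype-by-site count matrix
#'
#' @param oset an `oligotype_set` (after [drop_incomplete()]).
#' @param sites character vector fixing the column (site) order, normally
#'   [site_order()] of the environmental table.
#' @return integer matrix, rows oligotypes (rownames `<otu>:<label>`;
#'   attributes `otu_id`, `labels`, `positions`, `taxonomy`), columns sites.
#'   Row sums equal retained read counts per oligotype.
#' @export
tabulate_oligotypes <- function(oset, sites) {
  site_of_read <- oset$site_of_read
  unknown <- setdiff(unique(site_of_read), sites)
  if (length(unknown))
    stop("labeling error: site label(s) not in site order: ",
         paste(unknown, collapse = ", "))
  m <- length(oset$oligotypes)
  counts <- matrix(0L, m, length(sites),
                   dimnames = list(character(m), sites))
  labels <- character(m)
  for (i in seq_len(m)) {
    o <- oset$oligotypes[[i]]
    tab <- table(factor(site_of_read[o$reads], levels = sites))
    counts[i, ] <- as.integer(tab)
    labels[i] <- o$label
  }
  rownames(counts) <- paste0(oset$otu_id, ":", labels)
  attr(counts, "otu_id") <- oset$otu_id
  attr(counts, "labels") <- labels
  attr(counts, "positions") <- lapply(oset$oligotypes, `[[`, "positions")
  attr(counts, "taxonomy") <- oset$taxonomy
  counts
}

#' Remove absolute singletons from an oligotype table
#'
#' Drops oligotypes represented by at most one read in the whole dataset.
#'
#' @param table oligotype-by-site count matrix.
#' @return the filtered matrix, with attribute `n_removed`.
#' @export
remove_singletons <- function(table) {
  keep <- rowSums(table) > 1L
  out <- table[keep, , drop = FALSE]
  for (a in c("otu_id", "taxonomy")) attr(out, a) <- attr(table, a)
  if (!is.null(attr(table, "labels")))
    attr(out, "labels") <- attr(table, "labels")[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}
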