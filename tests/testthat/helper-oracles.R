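# Fixture builders and independent oracles used across the test files.

# build an aligned_read_set from sequence strings
make_read_set <- function(seqs, sites, otu = "OTUX") {
  reads <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(reads) <- sprintf("%s|%s|%04d", otu, sites, seq_along(seqs))
  structure(list(otu_id = otu, reads = reads, site_of_read = sites,
                 taxonomy = "TestPhylum;TestClass"),
            class = "aligned_read_set")
}

# a read set with one variant column: n_a reads carrying 'A', n_b 'T',
# n_dot '.' at position `pos` of an otherwise constant alignment
make_split_read_set <- function(n_a, n_b, n_dot = 0, pos = 5, len = 12,
                                sites = NULL) {
  n <- n_a + n_b + n_dot
  base <- strrep("G", len)
  seqs <- rep(base, n)
  ch <- c(rep("A", n_a), rep("T", n_b), rep(".", n_dot))
  seqs <- vapply(seq_len(n), function(i) {
    s <- strsplit(seqs[i], "")[[1]]; s[pos] <- ch[i]; paste0(s, collapse = "")
  }, character(1))
  if (is.null(sites)) sites <- rep(c("s1", "s2"), length.out = n)
  make_read_set(seqs, sites)
}

# brute-force C score: count 2x2 checkerboard submatrices over site pairs
brute_c <- function(x, y) {
  x <- x > 0; y <- y > 0
  n <- length(x); cnt <- 0L
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
    if ((x[a] && !y[a] && !x[b] && y[b]) || (!x[a] && y[a] && x[b] && !y[b]))
      cnt <- cnt + 1L
  }
  cnt
}

# brute-force T score: site pairs jointly present at one and jointly absent
# at the other
brute_t <- function(x, y) {
  x <- x > 0; y <- y > 0
  n <- length(x); cnt <- 0L
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
    if ((x[a] && y[a] && !x[b] && !y[b]) || (!x[a] && !y[a] && x[b] && y[b]))
      cnt <- cnt + 1L
  }
  cnt
}

brute_mean_ct <- function(tb) {
  m <- nrow(tb); cs <- ts <- 0
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    cs <- cs + brute_c(tb[i, ], tb[j, ])
    ts <- ts + brute_t(tb[i, ], tb[j, ])
  }
  c(cs, ts) / (m * (m - 1) / 2)
}

# independent reference implementation of the MCL expansion/inflation
# iteration, written with explicit loops; returns a membership vector
reference_mcl <- function(W, inflation = 2.5, prune = 1e-5, tol = 1e-8,
                          max_iter = 200) {
  n <- nrow(W)
  diag(W) <- 0
  for (j in seq_len(n)) {
    mx <- max(W[, j])
    W[j, j] <- if (mx > 0) mx else 1
  }
  for (j in seq_len(n)) W[, j] <- W[, j] / sum(W[, j])
  M <- W
  for (it in seq_len(max_iter)) {
    Mn <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      Mn[i, j] <- sum(M[i, ] * M[, j])
    Mn <- Mn^inflation
    Mn[Mn < prune] <- 0
    for (j in seq_len(n)) {
      s <- sum(Mn[, j]); if (s > 0) Mn[, j] <- Mn[, j] / s
    }
    if (max(abs(Mn - M)) < tol) { M <- Mn; break }
    M <- Mn
  }
  memb <- integer(n)
  nxt <- 0L
  attr_rows <- which(rowSums(M) > prune)
  assigned_cluster <- rep(NA_integer_, n)
  for (a in attr_rows) {
    members <- which(M[a, ] > 0)
    existing <- stats::na.omit(unique(assigned_cluster[c(a, members)]))
    cl <- if (length(existing)) existing[1] else { nxt <- nxt + 1L; nxt }
    assigned_cluster[c(a, members)] <- cl
  }
  for (j in which(is.na(assigned_cluster))) {
    nxt <- nxt + 1L; assigned_cluster[j] <- nxt
  }
  assigned_cluster
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# small helper: pooled ARI of recovered oligotype partitions vs planted
# sub-populations across a list of decompositions
pooled_recovery_ari <- function(sim, params = oligotyping_params()) {
  truth_all <- integer(0)
  found_all <- integer(0)
  off_t <- off_f <- 0L
  for (otu in names(sim$read_sets)) {
    rs <- sim$read_sets[[otu]]
    if (nrow(rs$reads) <= params$min_otu_reads) next
    oset <- drop_incomplete(decompose(rs, params))
    assign <- rep(NA_integer_, nrow(rs$reads))
    for (i in seq_along(oset$oligotypes))
      assign[oset$oligotypes[[i]]$reads] <- i
    keep <- !is.na(assign)
    truth_all <- c(truth_all, sim$truth[[otu]]$subpop_of_read[keep] + off_t)
    found_all <- c(found_all, assign[keep] + off_f)
    off_t <- off_t + max(sim$truth[[otu]]$subpop_of_read)
    off_f <- off_f + length(oset$oligotypes)
  }
  mclust::adjustedRandIndex(truth_all, found_all)
}
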