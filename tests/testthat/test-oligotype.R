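test_that("column entropy follows the base-2 Shannon formula", {
  expect_equal(column_entropy(c(rep("A", 6), "C")), 0.5917, tolerance = 1e-3)
  expect_equal(column_entropy(rep("A", 6)), 0)
  expect_equal(column_entropy(c("A", "A", "A", "T", "T", "T")), 1)
  # missing coverage excluded before frequencies
  expect_equal(column_entropy(c("A", "A", ".", ".")), 0)
  expect_error(column_entropy(c(".", ".")), "undefined entropy")
  # gap is a legitimate character
  expect_equal(column_entropy(c("A", "-")), 1)
})

test_that("dominant fraction matches the ratio calibration", {
  expect_equal(dominant_fraction(c(rep("A", 6), "C")), 85.7, tolerance = 0.05)
  expect_equal(dominant_fraction(c(rep("A", 10), "C")), 90.9, tolerance = 0.05)
  expect_equal(dominant_fraction(rep("G", 5)), 100)
})

test_that("max-entropy position takes the leftmost maximum", {
  mono <- matrix("A", 10, 4)
  expect_equal(max_entropy_position(mono), list(position = 1L, entropy = 0))
  tied <- mono; tied[1:5, 2] <- "T"; tied[1:5, 4] <- "T"
  expect_equal(max_entropy_position(tied)$position, 2L)
  # exhaustive scan oracle on random matrices
  set.seed(42)
  for (rep in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T"), 200, TRUE,
                       prob = c(0.85, 0.05, 0.05, 0.05)), 20, 10)
    oracle <- vapply(seq_len(ncol(m)), function(j) column_entropy(m[, j]),
                     numeric(1))
    got <- max_entropy_position(m)
    expect_equal(got$position, which.max(oracle))
    expect_equal(got$entropy, max(oracle))
  }
})

test_that("decompose splits above thresholds and stops below them", {
  p <- oligotyping_params(min_otu_reads = 50)
  # 60:40 split, H = 0.971 > 0.6: two oligotypes
  os <- decompose(make_split_read_set(60, 40), p)
  labs <- sort(vapply(os$oligotypes, `[[`, character(1), "label"))
  expect_equal(labs, c("A", "T"))
  expect_equal(sort(vapply(os$oligotypes, function(o) length(o$reads),
                           integer(1))), c(40L, 60L))
  # 86:14 split, H = 0.584 < 0.6: no round performed
  os2 <- decompose(make_split_read_set(86, 14), p)
  expect_length(os2$oligotypes, 1)
  expect_equal(os2$oligotypes[[1]]$label, "")
  # below the 21-sequence floor no round happens even at H = 1
  os3 <- decompose(make_split_read_set(10, 10), oligotyping_params(min_otu_reads = 15))
  expect_length(os3$oligotypes, 1)
  # OTU-size precondition
  expect_error(decompose(make_split_read_set(10, 10)), "otu too small")
})

test_that("recursion resolves nested variant structure with path labels", {
  # position 3 splits A/T; within the A branch position 7 splits C/G
  seqs <- c(rep("GGAGGGCGGG", 30), rep("GGAGGGGGGG", 30), rep("GGTGGGCGGG", 40))
  os <- decompose(make_read_set(seqs, rep(c("s1", "s2"), 50)),
                  oligotyping_params(min_otu_reads = 50))
  labs <- sort(vapply(os$oligotypes, `[[`, character(1), "label"))
  expect_equal(labs, c("AC", "AG", "T"))
  # every retained read belongs to exactly one oligotype
  all_reads <- sort(unlist(lapply(os$oligotypes, `[[`, "reads")))
  expect_equal(all_reads, 1:100)
})

test_that("missing coverage at a discriminant position sets reads aside", {
  os <- decompose(make_split_read_set(60, 40, n_dot = 20),
                  oligotyping_params(min_otu_reads = 50))
  expect_length(os$incomplete_reads, 20)
  # conservation: reads in = reads in oligotypes + set aside
  n_in_oligos <- sum(vapply(os$oligotypes, function(o) length(o$reads), integer(1)))
  expect_equal(n_in_oligos + length(os$incomplete_reads), os$n_reads)
  kept <- drop_incomplete(os)
  expect_length(kept$oligotypes, 2)
  expect_equal(kept$fill, 100 / 120)
  # wholesale removal drops oligotypes whose path shed incomplete reads
  removed <- drop_incomplete(os, remove_mixed = TRUE)
  expect_length(removed$oligotypes, 0)
})

test_that("drop_incomplete is the identity when coverage is complete", {
  os <- decompose(make_split_read_set(60, 40), oligotyping_params(min_otu_reads = 50))
  kept <- drop_incomplete(os)
  expect_length(kept$oligotypes, 2)
  expect_equal(kept$fill, 1)
})

test_that("tabulation conserves reads in fixed site order", {
  sites <- rep(c("s1", "s2", "s3"), length.out = 100)
  os <- decompose(make_split_read_set(60, 40, sites = sites),
                  oligotyping_params(min_otu_reads = 50))
  tb <- tabulate_oligotypes(drop_incomplete(os), c("s3", "s1", "s2"))
  expect_equal(colnames(tb), c("s3", "s1", "s2"))
  expect_equal(sum(tb), 100)
  expect_setequal(rowSums(tb), c(60, 40))
  expect_error(tabulate_oligotypes(drop_incomplete(os), c("s1", "s2")),
               "labeling error")
})

test_that("singleton removal drops rows with total count <= 1", {
  tb <- matrix(c(1, 0, 0, 2, 3, 0, 0, 1, 0), 3, 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  out <- remove_singletons(tb)
  expect_equal(rownames(out), "b")
  expect_equal(attr(out, "n_removed"), 2)
  no_single <- matrix(2, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(attr(remove_singletons(no_single), "n_removed"), 0)
  all_single <- matrix(c(1, 0, 0, 1), 2, 2,
                       dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(nrow(remove_singletons(all_single)), 0)
})

test_that("raising the entropy threshold never increases oligotype count", {
  env <- generate_env_table(13, seed = 2)
  d <- community_design(n_otus = 3, reads_per_otu = c(300, 800),
                        variant_positions = c(1, 3), seed = 31)
  sim <- generate_community(d, env)
  for (rs in sim$read_sets) {
    counts <- vapply(c(0.3, 0.6, 1.0, 1.5), function(h) {
      length(decompose(rs, oligotyping_params(min_entropy = h))$oligotypes)
    }, numeric(1))
    expect_false(is.unsorted(rev(counts)))
  }
})

test_that("error-free planted partitions are recovered exactly", {
  env <- generate_env_table(13, seed = 4)
  d <- community_design(n_otus = 5, error_rate = 0, seed = 47)
  sim <- generate_community(d, env)
  expect_equal(pooled_recovery_ari(sim), 1)
})
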