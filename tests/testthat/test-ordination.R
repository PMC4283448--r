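test_that("Hellinger transform takes square roots of row proportions", {
  expect_equal(hellinger(rbind(c(1, 1, 1, 1)))[1, ], rep(0.5, 4))
  expect_equal(hellinger(rbind(c(4, 0)))[1, ], c(1, 0))
  expect_equal(hellinger(rbind(c(1, 3)))[1, ], c(0.5, 0.8660), tolerance = 1e-4)
  expect_error(hellinger(rbind(c(-1, 2))), "negative")
  expect_warning(out <- hellinger(rbind(c(0, 0), c(2, 2))), "all-zero")
  expect_equal(out[1, ], c(0, 0))
  set.seed(3)
  m <- matrix(rpois(40, 5) + 1, 8, 5)
  expect_equal(unname(sqrt(rowSums(hellinger(m)^2))), rep(1, 8))
})

test_that("z-scoring centres and scales, excluding constant columns", {
  z <- zscore_env(data.frame(a = c(1, 2, 3)))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(as.numeric(zscore_env(data.frame(a = c(-1, 0, 1)))), c(-1, 0, 1),
               tolerance = 1e-12)
  expect_warning(z2 <- zscore_env(data.frame(a = 1:4, b = rep(2, 4))),
                 "degenerate")
  expect_equal(colnames(z2), "a")
})

test_that("RDA decomposes variance exactly and detects perfect fits", {
  set.seed(11)
  x <- rnorm(12)
  Y <- outer(x, c(1, -2, 0.5))            # exact linear response, no noise
  m <- rda_fit(Y, data.frame(x = x))
  expect_equal(m$constrained_fraction, 1.0, tolerance = 1e-10)
  X <- data.frame(a = rnorm(12), b = rnorm(12))
  Yn <- Y + matrix(rnorm(36), 12)
  m2 <- rda_fit(Yn, X)
  expect_equal(sum(m2$eigenvalues), m2$total_variance, tolerance = 1e-8)
  expect_true(m2$constrained_fraction >= 0 && m2$constrained_fraction <= 1)
  # joint row permutation leaves the constrained fraction unchanged
  perm <- sample(12)
  m3 <- rda_fit(Yn[perm, ], X[perm, ])
  expect_equal(m3$constrained_fraction, m2$constrained_fraction, tolerance = 1e-10)
  expect_error(rda_fit(Yn, data.frame(a = X$a, b = 2 * X$a)), "collinearity")
})

test_that("permutation p-values honour the add-one convention", {
  set.seed(21)
  x <- rnorm(13)
  Y <- outer(x, c(2, -1)) + matrix(rnorm(26, sd = 0.01), 13)
  m <- rda_fit(Y, data.frame(x = x))
  expect_equal(permutation_test(m, n_perm = 199, seed = 5), 1 / 200)
})

test_that("forward selection recovers the generator and gates pure noise", {
  env <- generate_env_table(13, seed = 8)
  set.seed(17)
  X <- as.data.frame(zscore_env(data.frame(depth = env$depth,
                                           junk1 = rnorm(13),
                                           junk2 = rnorm(13))))
  hits <- 0L
  for (r in 1:20) {
    Y <- outer(X$depth, runif(4, 0.5, 1.5) * rep_len(c(1, -1), 4)) +
      matrix(rnorm(52, sd = 0.3), 13)
    fs <- forward_select(Y, X, n_perm = 199, seed = r)
    hits <- hits + ("depth" %in% fs$selected)
  }
  expect_gte(hits, 18)
  empties <- 0L
  for (r in 1:20) {
    Y <- matrix(rnorm(52), 13)
    fs <- forward_select(Y, X, n_perm = 199, seed = 100 + r)
    empties <- empties + (length(fs$selected) == 0)
  }
  expect_gte(empties, 15)
  expect_equal(forward_select(matrix(rnorm(26), 13), data.frame())$selected,
               character(0))
})

test_that("variance inflation factors follow 1/(1-R^2)", {
  expect_equal(unname(vif_factors(data.frame(a = rnorm(10)))), 1)
  X <- data.frame(a = rep(c(1, -1), 5), b = rep(c(1, 1, -1, -1), length.out = 10))
  expect_equal(unname(vif_factors(X)), c(1, 1), tolerance = 1e-10)
  set.seed(9)
  a <- rnorm(30)
  near <- data.frame(a = a, b = a + rnorm(30, sd = 0.01))
  expect_true(all(vif_factors(near) > 10))
  exact <- data.frame(a = a, b = 2 * a)
  expect_true(all(is.infinite(vif_factors(exact))))
})

test_that("BH adjustment applies the step-up formula", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  expect_error(fdr_bh(c(0.1, 1.2)), "invalid p")
  # order-preserving and monotone
  p <- c(0.001, 0.01, 0.04, 0.2, 0.9)
  expect_false(is.unsorted(fdr_bh(p)))
})

test_that("model selection applies strict thresholds and report shape", {
  models <- data.frame(
    otu_id = c("A", "B", "C"), class = "x", n_oligotypes = 3:5,
    formula = c("Y ~ depth", "Y ~ easting + cpe + depth", "Y ~ 1"),
    constrained_fraction = c(0.49, 0.69, 0.80),
    p_adjusted = c(0.01, 0.01, 0.20))
  out <- select_models(models)
  expect_equal(out$otu_id, "B")
  expect_equal(out$constrained_pct, 69)
  empty <- select_models(models[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("ordination over a community flags depth-structured OTUs", {
  env <- generate_env_table(13, seed = 10)
  d <- community_design(n_otus = 8, reads_per_otu = c(300, 900),
                        scenarios = c(rep("depth_linear", 4), rep("neutral", 4)),
                        variant_positions = c(1, 2), seed = 83)
  sim <- generate_community(d, env)
  tables <- lapply(sim$read_sets, function(rs)
    remove_singletons(tabulate_oligotypes(drop_incomplete(decompose(rs)),
                                          site_order(env))))
  res <- suppressWarnings(
    ordinate_community(tables, env, n_perm = 199, seed = 3))
  expect_equal(nrow(res), 8)
  depth_models <- grepl("depth", res$formula[1:4])
  expect_gte(sum(depth_models), 3)
  expect_true(all(res$constrained_fraction >= 0 & res$constrained_fraction <= 1))
})
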