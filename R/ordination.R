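#' Hellinger transform of a count matrix
#'
#' Square root of row-relative abundances: `y'_hj = sqrt(y_hj / y_h+)`.
#' Rows summing to zero map to all-zero rows with a warning. Nonzero rows
#' have unit Euclidean norm after transformation.
#'
#' @param x non-negative matrix, objects as rows.
#' @return transformed matrix of the same shape.
#' @export
hellinger <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("invalid counts: negative entries")
  zero <- rowSums(x) == 0
  out <- x
  if (any(!zero))
    out[!zero, ] <- vegan::decostand(x[!zero, , drop = FALSE], "hellinger")
  if (any(zero)) {
    out[zero, ] <- 0
    warning(sum(zero), " all-zero row(s) left as zeros in Hellinger transform")
  }
  out
}

#' z-score environmental columns
#'
#' Columns are centred to zero mean and scaled to unit sample standard
#' deviation. Constant columns cannot be scaled; they are excluded with a
#' warning naming them.
#'
#' @param env data.frame or matrix of numeric explanatory variables.
#' @return numeric matrix of z-scored columns (constant columns dropped).
#' @export
zscore_env <- function(env) {
  env <- as.matrix(as.data.frame(env))
  sds <- apply(env, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- colnames(env)[sds == 0 | is.na(sds)]
    warning("degenerate variable(s) excluded (zero variance): ",
            paste(bad, collapse = ", "))
    env <- env[, !(colnames(env) %in% bad), drop = FALSE]
  }
  scale(env)
}

#' Fit a redundancy analysis model
#'
#' Least-squares projection of the (centred) response matrix onto the
#' explanatory matrix, with canonical axes from the eigen-decomposition of
#' the fitted values (vegan's RDA). Sites are objects (rows) of both
#' matrices.
#'
#' @param Y site-by-oligotype response matrix (normally Hellinger-transformed).
#' @param X site-by-variable explanatory data.frame/matrix (normally z-scored).
#' @return an `rda_model`: list with the vegan fit (`fit`), `eigenvalues`
#'   (constrained then unconstrained), `constrained_fraction`, `adj_r2`,
#'   `vif` (per constraint), and scaling-2 `scores` (sites, species, biplot).
#' @export
rda_fit <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.data.frame(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must have aligned rows (sites)")
  if (nrow(Y) <= ncol(X) + 1)
    stop("need n_sites > n_variables + 1")
  qrX <- qr(scale(as.matrix(X)))
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("collinearity: explanatory columns are linearly dependent: ",
         paste(dep, collapse = ", "))
  }
  fit <- vegan::rda(Y ~ ., data = X)
  eig <- c(fit$CCA$eig, fit$CA$eig)
  cf <- fit$CCA$tot.chi / fit$tot.chi
  sc <- vegan::scores(fit, display = c("sites", "species", "bp"),
                      scaling = 2, tidy = FALSE)
  structure(list(fit = fit,
                 eigenvalues = eig,
                 total_variance = fit$tot.chi,
                 constrained_fraction = cf,
                 adj_r2 = vegan::RsquareAdj(fit)$adj.r.squared,
                 vif = vegan::vif.cca(fit),
                 variables = colnames(X),
                 scores = sc),
            class = "rda_model")
}

#' Permutation test of an RDA model
#'
#' Permutes response rows and recomputes the pseudo-F statistic
#' (constrained over unconstrained variance, df-adjusted);
#' `p = (1 + #permuted F >= observed F) / (1 + n_perm)`.
#'
#' @param model an `rda_model` from [rda_fit()] (or a vegan `rda` fit).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return the permutation p-value.
#' @export
permutation_test <- function(model, n_perm = 999, seed = 1L) {
  fit <- if (inherits(model, "rda_model")) model$fit else model
  set.seed(seed)
  a <- vegan::anova.cca(fit, permutations = n_perm)
  a$`Pr(>F)`[1]
}

#' Forward selection of explanatory variables (double stopping)
#'
#' Blanchet-style forward selection for RDA: (1) the global model holding
#' all candidates must be significant at `alpha`, otherwise the empty
#' (intercept-only) model is returned; (2) variables are added greedily by
#' largest gain in explained variance, each addition requiring a marginal
#' permutation p-value (partialling out the variables already selected)
#' `<= alpha` and the cumulative adjusted R-squared not to exceed that of
#' the global model. The adjusted-R-squared cap applies from the second
#' variable onward: once the global gate has passed, the first significant
#' variable is always admissible, because the single-variable adjusted
#' R-squared estimates the same quantity as the global one and exceeds it
#' by sampling noise about half the time whenever one variable carries
#' most of the signal — capping there would void the procedure's power
#' exactly in the clearest cases.
#'
#' @param Y site-by-oligotype response (Hellinger-transformed).
#' @param X site-by-variable candidate data.frame (z-scored).
#' @param alpha significance level for both gates (default 0.05).
#' @param n_perm permutations per test (default 999).
#' @param seed integer seed.
#' @return list with `selected` (possibly empty character vector in
#'   selection order), `global_p`, `global_adj_r2`.
#' @export
forward_select <- function(Y, X, alpha = 0.05, n_perm = 999, seed = 1L) {
  X <- as.data.frame(X)
  if (ncol(X) == 0)
    return(list(selected = character(0), global_p = NA_real_,
                global_adj_r2 = NA_real_))
  Y <- as.matrix(Y)
  global <- vegan::rda(Y ~ ., data = X)
  set.seed(seed)
  global_p <- vegan::anova.cca(global, permutations = n_perm)$`Pr(>F)`[1]
  global_adj <- vegan::RsquareAdj(global)$adj.r.squared
  if (is.na(global_p) || global_p > alpha)
    return(list(selected = character(0), global_p = global_p,
                global_adj_r2 = global_adj))

  selected <- character(0)
  remaining <- colnames(X)
  step <- 0L
  repeat {
    if (!length(remaining) || length(selected) >= nrow(Y) - 2L) break
    r2 <- vapply(remaining, function(v) {
      m <- vegan::rda(Y ~ ., data = X[, c(selected, v), drop = FALSE])
      m$CCA$tot.chi / m$tot.chi
    }, numeric(1))
    best <- remaining[which.max(r2)]
    cand_model <- vegan::rda(Y ~ ., data = X[, c(selected, best), drop = FALSE])
    # marginal test of the candidate, conditioning on what is selected
    step <- step + 1L
    set.seed(seed + step)
    p <- if (length(selected)) {
      d <- X[, c(selected, best), drop = FALSE]
      f <- stats::as.formula(paste("Y ~", best, "+ Condition(",
                                   paste(selected, collapse = "+"), ")"))
      m <- vegan::rda(f, data = d)
      vegan::anova.cca(m, permutations = n_perm)$`Pr(>F)`[1]
    } else {
      vegan::anova.cca(cand_model, permutations = n_perm)$`Pr(>F)`[1]
    }
    if (is.na(p) || p > alpha) break
    if (length(selected) >= 1L &&
        vegan::RsquareAdj(cand_model)$adj.r.squared > global_adj) break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  list(selected = selected, global_p = global_p, global_adj_r2 = global_adj)
}

#' Variance inflation factors of an explanatory matrix
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from regressing variable
#' `k` on the remaining variables. A single variable has VIF 1; perfectly
#' collinear variables report `Inf`.
#'
#' @param X matrix or data.frame of explanatory variables (>= 1 column).
#' @return named numeric vector of VIFs.
#' @export
vif_factors <- function(X) {
  X <- as.matrix(as.data.frame(X))
  if (ncol(X) < 1) stop("need at least one variable")
  if (ncol(X) == 1) return(stats::setNames(1, colnames(X)))
  vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, k] - mean(X[, k]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(X))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return BH-adjusted p-values (step-up, monotone, capped at 1).
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("invalid p-value(s): outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select strongly environmentally structured models
#'
#' Keeps models whose constrained-variation fraction strictly exceeds
#' `min_constrained` and whose FDR-adjusted p-value is below `alpha`,
#' emitting the per-OTU report (formula, constrained percentage).
#'
#' @param models data.frame with columns `otu_id`, `class`, `n_oligotypes`,
#'   `formula`, `constrained_fraction`, `p_adjusted` (build with
#'   [ordinate_community()]).
#' @param min_constrained minimum constrained fraction, strict (default 0.5).
#' @param alpha adjusted-p threshold, strict (default 0.05).
#' @return the filtered data.frame with `constrained_pct` added.
#' @export
select_models <- function(models, min_constrained = 0.5, alpha = 0.05) {
  if (!nrow(models)) return(cbind(models, constrained_pct = numeric(0)))
  keep <- !is.na(models$p_adjusted) &
    models$constrained_fraction > min_constrained &
    models$p_adjusted < alpha
  out <- models[keep, , drop = FALSE]
  out$constrained_pct <- round(100 * out$constrained_fraction)
  rownames(out) <- NULL
  out
}

#' Run RDA with forward selection over every OTU's oligotype matrix
#'
#' Per OTU: the oligotype-by-site counts are transposed to sites-as-rows and
#' Hellinger-transformed; candidate variables are z-scored; forward
#' selection picks a model; the final model's permutation p-value is
#' recorded (the global model's where selection is empty, so every OTU
#' contributes one test to the FDR family).
#'
#' @param tables named list of oligotype-by-site count matrices.
#' @param env environmental table ([generate_env_table()]).
#' @param candidates candidate variable names among the env columns
#'   (default protein, CPE, easting, northing, depth and porosity).
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return data.frame, one row per analysed OTU: `otu_id`, `class`, `order`
#'   (NA for simulated data), `n_oligotypes`, `formula`,
#'   `constrained_fraction`, `p_value`, `p_adjusted`, `max_vif`,
#'   `selected` (logical, the >50% and FDR filter).
#' @export
ordinate_community <- function(tables, env,
                               candidates = c("protein", "cpe", "easting",
                                              "northing", "depth", "porosity"),
                               alpha = 0.05, n_perm = 999, seed = 1L) {
  X0 <- zscore_env(env[, candidates, drop = FALSE])
  rows <- list()
  k <- 0L
  for (tb in tables) {
    if (nrow(tb) < 2L) next
    k <- k + 1L
    Y <- hellinger(t(tb[, env$site_id, drop = FALSE]))
    fs <- forward_select(Y, as.data.frame(X0), alpha = alpha,
                         n_perm = n_perm, seed = seed + 97L * k)
    if (length(fs$selected)) {
      m <- rda_fit(Y, as.data.frame(X0)[, fs$selected, drop = FALSE])
      p <- permutation_test(m, n_perm = n_perm, seed = seed + 97L * k + 1L)
      cf <- m$constrained_fraction
      maxv <- max(m$vif)
      form <- paste("Y ~", paste(fs$selected, collapse = " + "))
    } else {
      p <- fs$global_p
      cf <- 0
      maxv <- NA_real_
      form <- "Y ~ 1"
    }
    tax <- strsplit(attr(tb, "taxonomy") %||% ";", ";")[[1]]
    rows[[k]] <- data.frame(
      otu_id = attr(tb, "otu_id"), class = if (length(tax) > 1) tax[2] else NA,
      order = NA_character_, n_oligotypes = nrow(tb), formula = form,
      constrained_fraction = cf, p_value = p, max_vif = maxv,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$p_adjusted <- fdr_bh(out$p_value)
  out$selected <- out$constrained_fraction > 0.5 & out$p_adjusted < 0.05 &
    out$formula != "Y ~ 1"
  out
}
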