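# Explaining log10 p50 by seed traits: ML (phylogenetic) generalized
# least squares over a fixed candidate set, AICc ranking, Akaike weights,
# full model averaging, and the classical group comparisons.
#
# Everything is maximum likelihood (not REML) so log-likelihoods are
# AIC-comparable across fixed-effect structures. The parameter count K is
# intercept + slopes + 1 for the residual variance, plus 1 whenever
# lambda is estimated.

ALL_PREDICTORS <- c("log10_vs", "log10_tsw", "log10_mct",
                    "non_endospermic", "py", "pd")

#' Specify a candidate regression model
#'
#' @param predictors Character vector drawn from
#'   `log10_vs, log10_tsw, log10_mct, non_endospermic, py, pd`
#'   (empty = intercept-only null model).
#' @param label Optional display label.
#' @return A `model_spec` list.
#' @export
model_spec <- function(predictors = character(), label = NULL) {
  bad <- setdiff(predictors, ALL_PREDICTORS)
  if (length(bad)) {
    stop_seedspan(sprintf("unknown predictor(s): %s",
                          paste(bad, collapse = ", ")),
                  "seedspan_invalid_input")
  }
  structure(list(predictors = predictors,
                 label = label %||%
                   (if (length(predictors)) paste(predictors, collapse = " + ")
                    else "null")),
            class = "model_spec")
}

#' The default ten-model candidate set
#'
#' The fixed candidate set used throughout: the full six-predictor model,
#' single-trait models for each predictor, physical dormancy plus coat
#' thickness, shape plus mass, and the intercept-only null model.
#'
#' @return A list of [model_spec()] objects.
#' @export
candidate_models <- function() {
  list(
    model_spec(c("log10_vs", "log10_tsw", "log10_mct",
                 "non_endospermic", "pd", "py"), "full"),
    model_spec("py"),
    model_spec(c("log10_mct", "py")),
    model_spec("non_endospermic"),
    model_spec("pd"),
    model_spec("log10_vs"),
    model_spec(c("log10_vs", "log10_tsw")),
    model_spec(character(), "null"),
    model_spec("log10_mct"),
    model_spec("log10_tsw")
  )
}

model_frame <- function(am, spec, response = "log10_p50") {
  cols <- c(response, spec$predictors)
  missing_cols <- setdiff(cols, names(am))
  if (length(missing_cols)) {
    stop_seedspan(sprintf("analysis matrix lacks column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "seedspan_schema_error")
  }
  keep <- stats::complete.cases(am[, cols, drop = FALSE])
  dropped <- rownames(am)[!keep]
  d <- am[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(d[, spec$predictors, drop = FALSE]))
  list(y = d[[response]], X = X, species = rownames(d), dropped = dropped)
}

# Core GLS machinery shared by gls_fit and pgls_fit. V = NULL means
# identity covariance (the star-phylogeny / conventional model).
gls_core <- function(y, X, V = NULL) {
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    stop_seedspan(sprintf("rank-deficient design; check columns: %s",
                          paste(colnames(X), collapse = ", ")),
                  "seedspan_fit_error")
  }
  if (is.null(V)) {
    zy <- y; zX <- X; logdet <- 0
  } else {
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) {
      stop_seedspan("singular phylogenetic covariance", "seedspan_fit_error")
    }
    zy <- backsolve(R, y, transpose = TRUE)
    zX <- backsolve(R, X, transpose = TRUE)
    logdet <- 2 * sum(log(diag(R)))
  }
  XtX <- crossprod(zX)
  XtXinv <- solve(XtX)
  beta <- drop(XtXinv %*% crossprod(zX, zy))
  e <- zy - drop(zX %*% beta)
  rss <- sum(e * e)
  sigma2_ml <- rss / n
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdet + n)
  sigma2_se <- if (n > p) rss / (n - p) else NA_real_
  se <- sqrt(diag(XtXinv) * sigma2_se)
  names(beta) <- names(se) <- colnames(X)
  list(coefficients = beta, se = se, sigma2_ml = sigma2_ml,
       log_likelihood = loglik, rss = rss)
}

new_model_fit <- function(spec, core, n, K, lambda_hat, phylo, dropped) {
  aicc_val <- aicc(core$log_likelihood, K, n)
  structure(list(
    spec = spec, coefficients = core$coefficients, se = core$se,
    lambda_hat = lambda_hat, log_likelihood = core$log_likelihood,
    sigma2_ml = core$sigma2_ml, K = K, n = n, AICc = aicc_val,
    phylogenetic = phylo, dropped_species = dropped,
    degenerate = core$sigma2_ml < 1e-12),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s model '%s': n = %d, K = %d, logLik = %.3f, AICc = %.3f\n",
              if (x$phylogenetic) "PGLS" else "GLS", x$spec$label,
              x$n, x$K, x$log_likelihood, x$AICc))
  if (x$phylogenetic) cat(sprintf("  lambda = %.3f\n", x$lambda_hat))
  print(cbind(Estimate = x$coefficients, SE = x$se))
  invisible(x)
}

#' Non-phylogenetic GLS fit (maximum likelihood)
#'
#' Ordinary linear model under an identity residual covariance (the
#' star-phylogeny assumption), fitted by ML so the log-likelihood is
#' AICc-comparable with the phylogenetic fits. Rows with missing
#' predictors are dropped and recorded on the fit.
#'
#' @param am An [build_analysis_matrix()] data.frame.
#' @param spec A [model_spec()].
#' @param response Response column (default `log10_p50`).
#' @return A `model_fit`.
#' @export
gls_fit <- function(am, spec, response = "log10_p50") {
  mf <- model_frame(am, spec, response)
  n <- length(mf$y)
  K <- ncol(mf$X) + 1L
  if (n <= K + 1L) {
    stop_seedspan("too few complete cases for this model",
                  "seedspan_invalid_input")
  }
  core <- gls_core(mf$y, mf$X)
  if (core$sigma2_ml < 1e-12) {
    warning("residual variance ~ 0: degenerate fit", call. = FALSE)
  }
  new_model_fit(spec, core, n, K, NA_real_, FALSE, mf$dropped)
}

#' Phylogenetic GLS fit with ML lambda
#'
#' GLS with residual covariance `sigma2 * V(lambda)`, where V comes from
#' the dated tree and lambda is estimated jointly by maximum likelihood on
#' \[0, 1\] (bounded scalar search; boundary optima reported exactly). With
#' `lambda = 0` the coefficients reduce to the non-phylogenetic fit on an
#' ultrametric tree.
#'
#' @inheritParams gls_fit
#' @param tree Dated `phylo` containing all analysis species as tips.
#' @param lambda Fix lambda instead of estimating it (number in \[0, 1\]).
#' @return A `model_fit` with `lambda_hat`.
#' @export
pgls_fit <- function(am, spec, tree, response = "log10_p50", lambda = NULL) {
  mf <- model_frame(am, spec, response)
  n <- length(mf$y)
  tree2 <- ape::collapse.singles(tree)
  unmatched <- setdiff(mf$species, tree2$tip.label)
  if (length(unmatched)) {
    stop_seedspan(sprintf("species not in tree: %s",
                          paste(unmatched, collapse = ", ")),
                  "seedspan_invalid_input")
  }
  V <- phylo_covariance(ape::keep.tip(tree2, mf$species))
  V <- V[mf$species, mf$species]
  estimate_lambda <- is.null(lambda)
  K <- ncol(mf$X) + 1L + as.integer(estimate_lambda)
  if (n <= K + 1L) {
    stop_seedspan("too few complete cases for this model",
                  "seedspan_invalid_input")
  }
  ll_at <- function(lam) {
    gls_core(mf$y, mf$X, lambda_transform(V, lam))$log_likelihood
  }
  if (estimate_lambda) {
    opt <- stats::optimize(ll_at, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(0, opt$maximum, 1)
    vals <- c(ll_at(0), opt$objective, ll_at(1))
    lambda <- cand[which.max(vals)]
  }
  core <- gls_core(mf$y, mf$X, lambda_transform(V, lambda))
  new_model_fit(spec, core, n, K, lambda, TRUE, mf$dropped)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2K + 2K(K + 1)/(n - K - 1)`.
#'
#' @param logLik Maximized log-likelihood.
#' @param K Number of estimated parameters (including the residual
#'   variance and, for PGLS, lambda).
#' @param n Sample size; must exceed `K + 1`.
#' @export
aicc <- function(logLik, K, n) {
  if (n <= K + 1) {
    stop_seedspan("AICc requires n > K + 1", "seedspan_invalid_input")
  }
  -2 * logLik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' AICc differences and Akaike weights
#'
#' @param aicc_values Finite numeric vector of AICc values.
#' @return List with `delta` (AICc - min) and `weight`
#'   (`exp(-delta/2)` normalized to sum 1).
#' @export
akaike_weights <- function(aicc_values) {
  if (!length(aicc_values) || any(!is.finite(aicc_values))) {
    stop_seedspan("AICc values must be a non-empty finite vector",
                  "seedspan_invalid_input")
  }
  delta <- aicc_values - min(aicc_values)
  rel <- exp(-delta / 2)
  list(delta = delta, weight = rel / sum(rel))
}

#' Fit a candidate model set and rank it by AICc
#'
#' Fits every spec in `specs` (GLS, or PGLS with per-model ML lambda when
#' `phylo = TRUE`), computes AICc differences and Akaike weights, and
#' returns the set with a ranking table.
#'
#' @inheritParams gls_fit
#' @param specs List of [model_spec()]s; default [candidate_models()].
#' @param phylo Use PGLS.
#' @param tree Dated tree (required when `phylo = TRUE`).
#' @return A `model_set`: list of fits plus a `table` data.frame
#'   (label, lambda, K, logLik, AICc, delta, weight).
#' @export
fit_candidate_set <- function(am, specs = candidate_models(), phylo = FALSE,
                              tree = NULL, response = "log10_p50") {
  if (phylo && is.null(tree)) {
    stop_seedspan("phylo = TRUE needs a tree", "seedspan_invalid_input")
  }
  fits <- lapply(specs, function(s) {
    if (phylo) pgls_fit(am, s, tree, response) else gls_fit(am, s, response)
  })
  aw <- akaike_weights(vapply(fits, `[[`, 0, "AICc"))
  tab <- data.frame(
    model = vapply(fits, function(f) f$spec$label, ""),
    lambda = vapply(fits, `[[`, 0, "lambda_hat"),
    K = vapply(fits, `[[`, 0L, "K"),
    logLik = vapply(fits, `[[`, 0, "log_likelihood"),
    AICc = vapply(fits, `[[`, 0, "AICc"),
    delta = aw$delta,
    weight = aw$weight,
    stringsAsFactors = FALSE
  )
  ord <- order(tab$AICc)
  structure(list(fits = fits[ord], table = tab[ord, ],
                 phylogenetic = phylo),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("%s candidate set (%d models, n = %d)\n",
              if (x$phylogenetic) "Phylogenetic" else "Non-phylogenetic",
              nrow(x$table), x$fits[[1]]$n))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Full model averaging over a candidate set
#'
#' Averages every coefficient over ALL models, substituting 0 where a
#' model omits it, with Akaike weights as model probabilities. The
#' unconditional standard error combines within-model variance and
#' between-model spread:
#' `SE = sqrt( sum_i w_i * (se_i^2 + (b_i - b_bar)^2) )`.
#' z = |estimate| / SE with a two-sided normal p-value.
#'
#' @param set A `model_set` from [fit_candidate_set()] (weights must sum
#'   to 1).
#' @return An `averaged_model` data.frame: estimate, SE, z, p per
#'   coefficient, plus the weight-averaged lambda for PGLS sets.
#' @export
model_average <- function(set) {
  stopifnot(inherits(set, "model_set"))
  w <- set$table$weight
  if (abs(sum(w) - 1) > 1e-9) {
    stop_seedspan("model weights do not sum to 1", "seedspan_invalid_input")
  }
  coef_names <- unique(unlist(lapply(set$fits, function(f)
    names(f$coefficients))))
  est <- se <- stats::setNames(numeric(length(coef_names)), coef_names)
  for (j in seq_along(coef_names)) {
    nm <- coef_names[j]
    b <- vapply(set$fits, function(f) unname(f$coefficients[nm]) %|NA|% 0, 0)
    v <- vapply(set$fits, function(f) unname(f$se[nm]^2) %|NA|% 0, 0)
    bbar <- sum(w * b)
    est[j] <- bbar
    se[j] <- sqrt(sum(w * (v + (b - bbar)^2)))
  }
  z <- abs(est) / se
  out <- data.frame(coefficient = coef_names, estimate = est,
                    unconditional_se = se, z_value = z,
                    p_value = 2 * stats::pnorm(z, lower.tail = FALSE),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "lambda_avg") <- if (set$phylogenetic)
    sum(w * set$table$lambda) else NA_real_
  class(out) <- c("averaged_model", "data.frame")
  out
}

`%|NA|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a

#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares decomposition; at least two
#' groups, at least one group with two or more values, and non-zero
#' within-group variance are required.
#'
#' @param values Numeric response.
#' @param groups Group labels, same length.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) {
    stop_seedspan("need at least 2 groups", "seedspan_invalid_input")
  }
  if (length(values) != length(groups)) {
    stop_seedspan("values and groups lengths differ", "seedspan_invalid_input")
  }
  groups <- droplevels(groups)
  gm <- tapply(values, groups, mean)
  ng <- tapply(values, groups, length)
  ss_between <- sum(ng * (gm - mean(values))^2)
  ss_within <- sum((values - gm[groups])^2)
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  if (df2 < 1L || ss_within == 0) {
    stop_seedspan("no within-group variance: F undefined",
                  "seedspan_invalid_input")
  }
  F <- (ss_between / df1) / (ss_within / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted all-pairs comparisons after a one-way
#' ANOVA; requires at least two values per group.
#'
#' @inheritParams one_way_anova
#' @return A data.frame: pair, difference in means, adjusted p.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) {
    stop_seedspan("need at least 2 groups", "seedspan_invalid_input")
  }
  if (any(tapply(values, groups, length) < 2L)) {
    stop_seedspan("every group needs >= 2 values for Tukey HSD",
                  "seedspan_invalid_input")
  }
  tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
  data.frame(pair = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-group mean, standard error and n
#'
#' Reported on the raw (untransformed) scale; a single-member group gets
#' SE 0 by convention.
#'
#' @inheritParams one_way_anova
#' @return A data.frame: group, mean, se, n.
#' @export
group_summary <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (!length(values)) {
    stop_seedspan("no values", "seedspan_invalid_input")
  }
  n <- as.integer(tapply(values, groups, length))
  m <- as.numeric(tapply(values, groups, mean))
  s <- as.numeric(tapply(values, groups, stats::sd)) / sqrt(n)
  s[n == 1L] <- 0
  data.frame(group = levels(groups), mean = m, se = s, n = n,
             stringsAsFactors = FALSE)
}
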