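test_that("AICc matches the printed candidate-table rows", {
  # printed logLik values are rounded, hence the loose third decimal
  expect_equal(aicc(-9.97, 3, 35), 26.72, tolerance = 0.015)
  expect_equal(aicc(0.60, 8, 35), 20.35, tolerance = 0.015)
  expect_equal(aicc(-12.3, 0, 50), 24.6)
  expect_error(aicc(-10, 8, 9), class = "seedspan_invalid_input")
})

test_that("Akaike weights are normalized relative likelihoods", {
  expect_equal(akaike_weights(42)$weight, 1)
  expect_equal(akaike_weights(c(10, 10))$weight, c(0.5, 0.5))
  aw <- akaike_weights(c(20.35, 26.72, 29.20, 36.04, 40.30, 47.79, 50.09,
                         50.13, 52.28, 52.31))
  expect_equal(sum(aw$weight), 1)
  expect_equal(which.max(aw$weight), which.min(aw$delta))
  expect_equal(aw$delta[1], 0)
  # brute-force arithmetic oracle
  d <- c(20.35, 26.72) - 20.35
  expect_equal(akaike_weights(c(20.35, 26.72))$weight,
               exp(-d / 2) / sum(exp(-d / 2)))
  expect_error(akaike_weights(c(1, Inf)), class = "seedspan_invalid_input")
})

test_that("GLS: null model recovers the mean, slopes recover at stated noise", {
  am <- build_analysis_matrix(fixture_table())
  null <- gls_fit(am, model_spec(character()))
  expect_equal(unname(null$coefficients["(Intercept)"]),
               mean(am$log10_p50), tolerance = 1e-10)
  set.seed(31)
  x <- rnorm(200)
  y <- 2 + 0.5 * x + rnorm(200, sd = 0.1)
  am2 <- data.frame(log10_p50 = y, log10_tsw = x)
  rownames(am2) <- sprintf("s%03d", 1:200)
  class(am2) <- c("analysis_matrix", "data.frame")
  f <- gls_fit(am2, model_spec("log10_tsw"))
  expect_gt(unname(f$coefficients["log10_tsw"]), 0.45)
  expect_lt(unname(f$coefficients["log10_tsw"]), 0.55)
  # response identical to a predictor: slope 1, flagged degenerate
  am3 <- am2
  am3$log10_p50 <- am3$log10_tsw
  f3 <- suppressWarnings(gls_fit(am3, model_spec("log10_tsw")))
  expect_equal(unname(f3$coefficients["log10_tsw"]), 1, tolerance = 1e-8)
  expect_true(f3$degenerate)
  # rank deficiency is an error
  am4 <- am2
  am4$log10_vs <- am4$log10_tsw
  expect_error(gls_fit(am4, model_spec(c("log10_tsw", "log10_vs"))),
               class = "seedspan_fit_error")
})

test_that("PGLS with lambda fixed at 0 reproduces the GLS coefficients", {
  am <- build_analysis_matrix(fixture_table())
  tree <- fixture_tree()
  spec <- model_spec(c("non_endospermic", "py", "pd"))
  g <- gls_fit(am, spec)
  p <- suppressWarnings(pgls_fit(am, spec, tree, lambda = 0))
  expect_equal(p$coefficients, g$coefficients, tolerance = 1e-8)
  expect_equal(p$lambda_hat, 0)
})

test_that("PGLS recovers lambda and slope on Brownian data", {
  set.seed(32)
  tree <- balanced_tree(128)
  lam_hat <- slope_hat <- numeric(50)
  for (i in 1:50) {
    x <- rnorm(128)
    names(x) <- tree$tip.label
    resid <- gen_bm_traits(tree, sigma2 = 0.04 / 100, lambda = 1)
    y <- 1 + 0.5 * x + resid
    am <- data.frame(log10_p50 = unname(y[tree$tip.label]),
                     log10_tsw = unname(x[tree$tip.label]))
    rownames(am) <- tree$tip.label
    class(am) <- c("analysis_matrix", "data.frame")
    f <- pgls_fit(am, model_spec("log10_tsw"), tree)
    lam_hat[i] <- f$lambda_hat
    slope_hat[i] <- f$coefficients["log10_tsw"]
  }
  expect_gte(median(lam_hat), 0.8)
  expect_lt(abs(median(slope_hat) - 0.5), 0.05)
})

test_that("candidate sets rank by AICc with weights summing to one", {
  am <- build_analysis_matrix(fixture_table())
  specs <- Filter(function(s)
    all(s$predictors %in% c("non_endospermic", "py", "pd")),
    candidate_models())
  set <- fit_candidate_set(am, specs)
  expect_equal(sum(set$table$weight), 1)
  expect_true(!is.unsorted(set$table$AICc))
  expect_equal(set$table$delta[1], 0)
  expect_equal(which.max(set$table$weight), 1L)
  pset <- suppressWarnings(
    fit_candidate_set(am, specs, phylo = TRUE, tree = fixture_tree()))
  expect_equal(sum(pset$table$weight), 1)
  expect_true(all(pset$table$lambda >= 0 & pset$table$lambda <= 1))
})

fake_set <- function(weights, coefs, ses) {
  fits <- mapply(function(b, s) {
    list(coefficients = b, se = s)
  }, coefs, ses, SIMPLIFY = FALSE)
  structure(list(
    fits = fits,
    table = data.frame(model = seq_along(weights), lambda = NA, K = 2,
                       logLik = 0, AICc = 0, delta = 0, weight = weights),
    phylogenetic = FALSE), class = "model_set")
}

test_that("full model averaging follows the stated arithmetic", {
  # single model: averaged coefficients equal that model's
  s1 <- fake_set(1, list(c(`(Intercept)` = 1.5, py = 0.4)),
                 list(c(`(Intercept)` = 0.1, py = 0.2)))
  a1 <- model_average(s1)
  expect_equal(a1$estimate, c(1.5, 0.4))
  expect_equal(a1$unconditional_se, c(0.1, 0.2))
  # coefficient present in one of two equal-weight models with SE 0
  s2 <- fake_set(c(0.5, 0.5),
                 list(c(`(Intercept)` = 0, py = 1), c(`(Intercept)` = 0)),
                 list(c(`(Intercept)` = 0, py = 0), c(`(Intercept)` = 0)))
  expect_equal(model_average(s2)$estimate[2], 0.5)
  # a dominant model (w = 0.95) pins averaged coefficients within 6 %
  s3 <- fake_set(c(0.95, 0.05),
                 list(c(`(Intercept)` = 1, py = 0.5),
                      c(`(Intercept)` = 1.2)),
                 list(c(`(Intercept)` = 0.1, py = 0.1),
                      c(`(Intercept)` = 0.1)))
  a3 <- model_average(s3)
  expect_lt(abs(a3$estimate[a3$coefficient == "py"] - 0.5) / 0.5, 0.06)
  # broken weights are rejected
  s4 <- fake_set(c(0.6, 0.5),
                 list(c(`(Intercept)` = 1), c(`(Intercept)` = 1)),
                 list(c(`(Intercept)` = 0.1), c(`(Intercept)` = 0.1)))
  expect_error(model_average(s4), class = "seedspan_invalid_input")
})

test_that("one-way ANOVA equals brute-force sums of squares", {
  v <- c(1.2, 0.8, 1.5, 2.4, 2.6, 2.0)
  g <- c("a", "a", "a", "b", "b", "b")
  res <- one_way_anova(v, g)
  # hand computation
  ssb <- 3 * (mean(v[1:3]) - mean(v))^2 + 3 * (mean(v[4:6]) - mean(v))^2
  ssw <- sum((v[1:3] - mean(v[1:3]))^2) + sum((v[4:6] - mean(v[4:6]))^2)
  expect_equal(res$F, (ssb / 1) / (ssw / 4))
  expect_equal(res$df1, 1L)
  expect_equal(res$df2, 4L)
  expect_equal(res$p, pf(res$F, 1, 4, lower.tail = FALSE))
  # affine invariance of F
  res2 <- one_way_anova(10 * v - 3, g)
  expect_equal(res2$F, res$F)
  # equal group means: F ~ 0
  expect_lt(one_way_anova(c(1, 3, 2, 2 - 1e-9, 2 + 1e-9, 2), g)$F, 1e-3)
  expect_error(one_way_anova(v, rep("a", 6)), class = "seedspan_invalid_input")
  expect_error(one_way_anova(rep(1, 6), g), class = "seedspan_invalid_input")
})

test_that("Tukey HSD reduces to the ANOVA p with two groups", {
  set.seed(33)
  v <- c(rnorm(6), rnorm(6, 1))
  g <- rep(c("a", "b"), each = 6)
  tk <- tukey_hsd(v, g)
  expect_equal(tk$p_adj, one_way_anova(v, g)$p, tolerance = 1e-6)
  # zero differences give p = 1
  v2 <- rep(c(1, 2), 3)
  g2 <- rep(c("a", "b", "c"), each = 2)
  v2 <- c(1, 2, 1, 2, 1, 2)
  expect_true(all(tukey_hsd(v2, g2)$p_adj > 0.999))
  expect_error(tukey_hsd(c(1, 2, 3), c("a", "a", "b")),
               class = "seedspan_invalid_input")
})

test_that("group summaries report raw-scale mean, SE and n", {
  gs <- group_summary(c(10, 20, 30, 5), c("x", "x", "x", "y"))
  expect_equal(gs$mean, c(20, 5))
  expect_equal(gs$se, c(sd(c(10, 20, 30)) / sqrt(3), 0))
  expect_equal(gs$n, c(3L, 1L))
})
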