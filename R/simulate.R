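# Synthetic data with known ground truth for every pipeline stage.
#
# The generator's defaults emulate the study design the package targets:
# withdrawals every 15 days to day 210, 50 seeds per withdrawal, initial
# viability Ki = 2.054 NED (~98 % germinable at day 0), 39 species in a
# taxonomy-shaped tree, binary seed traits at the study's prevalences
# (14/39 endospermic, 7 physically and 12 physiologically dormant) and
# effects of +0.33 (endosperm absence), +0.47 (physical dormancy) and
# -0.33 (physiological dormancy) on log10 p50 around an intercept of
# 1.05, with phylogenetically structured residuals of tip standard
# deviation 0.24 (the residual scale implied by the study's full-model
# likelihood).

#' Solve sigma from a target p50
#'
#' [p50_of_initial()] is linear in sigma, so the inversion is closed
#' form: `sigma = p50 / (Ki - qnorm(pnorm(Ki)/2))`.
#'
#' @param p50 Target days to half of initial viability (> 0).
#' @param Ki Initial viability in NED.
#' @export
sigma_for_p50 <- function(p50, Ki = 2.054) {
  assert_positive(p50, "p50")
  p50 / (Ki - stats::qnorm(stats::pnorm(Ki) / 2))
}

#' Simulate a germination time-course
#'
#' At each withdrawal time p, germinated counts are
#' `Binomial(n_tested, pnorm(Ki - p/sigma))`. Uses the current RNG
#' state; call `set.seed()` for reproducibility.
#'
#' @param Ki,sigma Viability-equation parameters (NED; days per NED).
#' @param schedule Withdrawal days, strictly increasing (default every 15
#'   days to 210).
#' @param n_tested Seeds per withdrawal (default 50).
#' @param species_id Label for the time-course.
#' @return A [timecourse()].
#' @export
gen_timecourse <- function(Ki, sigma, schedule = seq(0, 210, by = 15),
                           n_tested = 50, species_id = "sim") {
  assert_positive(sigma, "sigma")
  p <- stats::pnorm(Ki - schedule / sigma)
  timecourse(species_id, schedule, n_tested,
             stats::rbinom(length(schedule), n_tested, p))
}

#' Simulate a continuous trait under (lambda-damped) Brownian motion
#'
#' One multivariate-normal draw with mean `root` and covariance
#' `sigma2 * V(lambda)`, V the tree covariance. `lambda = 1` is pure
#' Brownian motion; `lambda = 0` gives independent tips.
#'
#' @param tree Dated `phylo`.
#' @param sigma2 Brownian rate (trait variance per Myr), >= 0.
#' @param root Root state.
#' @param lambda Damping of the shared covariance, in \[0, 1\].
#' @return Named vector of tip values.
#' @export
gen_bm_traits <- function(tree, sigma2 = 1, root = 0, lambda = 1) {
  if (sigma2 < 0) {
    stop_seedspan("sigma2 must be >= 0", "seedspan_invalid_input")
  }
  tree <- ape::collapse.singles(tree)
  n <- ape::Ntip(tree)
  if (sigma2 == 0) {
    return(stats::setNames(rep(root, n), tree$tip.label))
  }
  V <- lambda_transform(phylo_covariance(tree), lambda)
  R <- chol(sigma2 * V)
  stats::setNames(root + drop(crossprod(R, stats::rnorm(n))),
                  rownames(V))
}

#' Simulate a binary trait
#'
#' `threshold-BM`: a Brownian liability is simulated on the tree and the
#' `round(prevalence * n)` tips with the largest liability take state 1
#' (rank thresholding matches the prevalence exactly). `random`: i.i.d.
#' labels at the prevalence.
#'
#' @param tree Dated `phylo`.
#' @param prevalence Fraction of tips in state 1, strictly inside (0, 1).
#' @param model `"threshold-BM"` (default) or `"random"`.
#' @return Named 0/1 vector over tips.
#' @export
gen_binary_threshold <- function(tree, prevalence,
                                 model = c("threshold-BM", "random")) {
  model <- match.arg(model)
  tree <- ape::collapse.singles(tree)
  n <- ape::Ntip(tree)
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop_seedspan("prevalence must lie strictly between 0 and 1",
                  "seedspan_invalid_input")
  }
  if (model == "random") {
    return(stats::setNames(stats::rbinom(n, 1, prevalence), tree$tip.label))
  }
  liab <- gen_bm_traits(tree, sigma2 = 1, root = 0, lambda = 1)
  k <- round(prevalence * n)
  k <- min(max(k, 1L), n - 1L)
  stats::setNames(as.numeric(rank(liab, ties.method = "first") > n - k),
                  names(liab))
}

random_taxonomy <- function(n_species) {
  n_orders <- max(2L, round(n_species / 3))
  n_families <- max(n_orders, round(n_species / 2))
  ords <- sprintf("Order%02d", seq_len(n_orders))
  fams <- sprintf("Family%02d", seq_len(n_families))
  fam_order <- stats::setNames(sample(ords, n_families, replace = TRUE), fams)
  sp_fam <- sample(fams, n_species, replace = TRUE)
  genus <- sprintf("Genus%02d", as.integer(factor(sp_fam)))
  data.frame(
    species = sprintf("%s sp%02d", genus, seq_len(n_species)),
    family = sp_fam,
    order = fam_order[sp_fam],
    stringsAsFactors = FALSE
  )
}

synthetic_ages <- function(taxonomy, root_age) {
  ords <- unique(taxonomy$order)
  fams <- unique(taxonomy$family)
  ages <- c(Root = root_age,
            stats::setNames(stats::runif(length(ords), 0.55, 0.8) * root_age,
                            ords))
  fam_age <- vapply(fams, function(f) {
    o <- taxonomy$order[match(f, taxonomy$family)]
    stats::runif(1, 0.3, 0.8) * ages[[o]]
  }, 0)
  c(ages, stats::setNames(fam_age, fams))
}

#' Build a simulation tree
#'
#' @param n_species Number of tips.
#' @param shape `"taxonomy"` (random nested orders/families/genera dated
#'   by even interpolation), `"balanced"` (fully balanced bifurcating,
#'   ultrametric) or `"star"`.
#' @param root_age Tree depth in Myr.
#' @return A dated `phylo`.
#' @export
gen_tree <- function(n_species, shape = c("taxonomy", "balanced", "star"),
                     root_age = 160) {
  shape <- match.arg(shape)
  assert_positive(root_age, "root_age")
  if (shape == "star") {
    tree <- ape::stree(n_species, type = "star")
    tree$edge.length <- rep(root_age, n_species)
    tree$tip.label <- sprintf("t%03d", seq_len(n_species))
    return(tree)
  }
  if (shape == "balanced") {
    depth <- max(1L, ceiling(log2(n_species)))
    len <- format(root_age / depth, digits = 12)
    build <- function(labs) {
      if (length(labs) == 1L) return(labs)
      half <- length(labs) / 2
      sprintf("(%s:%s,%s:%s)",
              build(labs[seq_len(half)]), len,
              build(labs[-seq_len(half)]), len)
    }
    n_full <- 2^depth
    labs <- sprintf("t%03d", seq_len(n_full))
    tree <- ape::read.tree(text = paste0(build(labs), ";"))
    if (n_full > n_species) {
      tree <- ape::keep.tip(tree, sprintf("t%03d", seq_len(n_species)))
    }
    return(tree)
  }
  tax <- random_taxonomy(n_species)
  bladj_adjust(build_taxonomy_tree(
    data.frame(tax, endosperm = "N", dormancy = "ND",
               p50 = 1, p50_se = 0, stringsAsFactors = FALSE)),
    synthetic_ages(tax, root_age))
}

#' Generate a complete study-like dataset with known truth
#'
#' Builds a dated tree, draws binary seed traits (physical dormancy is
#' confined to non-endospermic species, mirroring the study design, and
#' excludes physiological dormancy), sets
#' `log10 p50 = intercept + effects . x + BM(lambda) residual`,
#' converts each species' p50 to viability-equation parameters (Ki fixed,
#' sigma solved in closed form) and simulates a germination time-course
#' per species. Uses the current RNG state.
#'
#' @param n_species Number of species (default 39).
#' @param tree_shape Passed to [gen_tree()].
#' @param effects Named effects on log10 p50 for `non_endospermic`, `py`,
#'   `pd`.
#' @param intercept Baseline log10 p50.
#' @param resid_sd Tip standard deviation of the phylogenetic residual.
#' @param lambda Phylogenetic structure of the residual, in \[0, 1\].
#' @param prevalence Named fractions for `non_endospermic`, `py`, `pd`.
#' @param Ki Initial viability (NED) shared by all species.
#' @param schedule,n_tested Controlled-ageing design per species.
#' @param root_age Tree depth in Myr.
#' @return List: `tree`, `traits` (an `analysis_matrix` plus continuous
#'   dummy traits), `timecourses`, `truth` (all generating parameters and
#'   per-species true p50).
#' @export
gen_study <- function(n_species = 39,
                      tree_shape = "taxonomy",
                      effects = c(non_endospermic = 0.33, py = 0.47,
                                  pd = -0.33),
                      intercept = 1.05,
                      resid_sd = 0.24,
                      lambda = 0.5,
                      prevalence = c(non_endospermic = 25 / 39, py = 7 / 39,
                                     pd = 12 / 39),
                      Ki = 2.054,
                      schedule = seq(0, 210, by = 15),
                      n_tested = 50,
                      root_age = 160) {
  tree <- gen_tree(n_species, tree_shape, root_age)
  tree <- ape::collapse.singles(tree)
  n <- ape::Ntip(tree)
  tips <- tree$tip.label

  nonendo <- gen_binary_threshold(tree, prevalence[["non_endospermic"]])
  # physical dormancy: rank-threshold an independent liability WITHIN the
  # non-endospermic tips
  k_py <- min(max(round(prevalence[["py"]] * n), 1L), sum(nonendo) - 1L)
  liab_py <- gen_bm_traits(tree, 1, 0, 1)
  py <- stats::setNames(rep(0, n), tips)
  cand <- names(sort(liab_py[nonendo == 1], decreasing = TRUE))
  py[cand[seq_len(k_py)]] <- 1
  # physiological dormancy among the non-PY tips
  k_pd <- min(max(round(prevalence[["pd"]] * n), 1L), sum(py == 0) - 1L)
  liab_pd <- gen_bm_traits(tree, 1, 0, 1)
  pd <- stats::setNames(rep(0, n), tips)
  cand <- names(sort(liab_pd[py == 0], decreasing = TRUE))
  pd[cand[seq_len(k_pd)]] <- 1

  resid <- if (resid_sd > 0) {
    gen_bm_traits(tree, sigma2 = resid_sd^2 / root_age, root = 0,
                  lambda = lambda)
  } else stats::setNames(rep(0, n), tips)
  log10_p50 <- intercept + effects[["non_endospermic"]] * nonendo +
    effects[["py"]] * py + effects[["pd"]] * pd + resid
  p50 <- 10^log10_p50
  sigma <- sigma_for_p50(p50, Ki)

  traits <- data.frame(
    species = tips,
    log10_p50 = unname(log10_p50),
    non_endospermic = unname(nonendo),
    py = unname(py),
    pd = unname(pd),
    log10_tsw = unname(gen_bm_traits(tree, 0.25 / root_age, 0, lambda)),
    log10_vs = unname(gen_bm_traits(tree, 0.25 / root_age, -1, lambda)),
    log10_mct = unname(gen_bm_traits(tree, 0.25 / root_age, -1, lambda)),
    stringsAsFactors = FALSE
  )
  rownames(traits) <- tips
  class(traits) <- c("analysis_matrix", "data.frame")

  tcs <- lapply(tips, function(s) {
    gen_timecourse(Ki, sigma[[s]], schedule, n_tested, species_id = s)
  })
  names(tcs) <- tips

  list(tree = tree, traits = traits, timecourses = tcs,
       truth = list(effects = effects, intercept = intercept,
                    resid_sd = resid_sd, lambda = lambda, Ki = Ki,
                    p50 = p50, sigma = sigma))
}
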