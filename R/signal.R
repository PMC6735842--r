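# Phylogenetic signal statistics.
#
# All three statistics judge a tip trait against Brownian motion (BM) on
# the dated tree, under which the expected trait covariance among tips is
# proportional to shared branch length. They are implemented directly on
# the phylogenetic covariance matrix, which handles polytomies without any
# contrast decomposition.

match_trait_to_tree <- function(tree, trait) {
  if (is.null(names(trait))) {
    stop_seedspan("trait vector must be named by tip label",
                  "seedspan_invalid_input")
  }
  tree <- ape::collapse.singles(tree)
  unmatched <- setdiff(names(trait), tree$tip.label)
  if (length(unmatched)) {
    stop_seedspan(sprintf("trait names not in tree: %s",
                          paste(unmatched, collapse = ", ")),
                  "seedspan_invalid_input")
  }
  if (length(trait) < ape::Ntip(tree)) {
    tree <- ape::keep.tip(tree, names(trait))
  }
  list(tree = tree, trait = trait[tree$tip.label])
}

# Profile log-likelihood of a single-trait BM model with covariance
# sigma2 * V: the GLS mean and the ML variance are profiled analytically.
profile_loglik <- function(y, V) {
  n <- length(y)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    stop_seedspan("phylogenetic covariance is singular", "seedspan_fit_error")
  }
  one <- rep(1, n)
  z_y <- backsolve(R, y, transpose = TRUE)
  z_1 <- backsolve(R, one, transpose = TRUE)
  mu <- sum(z_1 * z_y) / sum(z_1 * z_1)
  e <- z_y - mu * z_1
  sigma2 <- sum(e * e) / n
  logdet <- 2 * sum(log(diag(R)))
  list(loglik = -0.5 * (n * log(2 * pi * sigma2) + logdet + n),
       mu = mu, sigma2 = sigma2)
}

new_signal_result <- function(statistic, estimate, p_vs_star, p_vs_brownian,
                              n_tips, n_permutations = NA_integer_,
                              log_likelihood = NA_real_, extra = list()) {
  structure(c(list(
    statistic = statistic, estimate = estimate,
    p_vs_star = p_vs_star, p_vs_brownian = p_vs_brownian,
    n_tips = n_tips, n_permutations = n_permutations,
    log_likelihood = log_likelihood), extra),
    class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s = %.4f  (n = %d tips)\n", x$statistic, x$estimate, x$n_tips))
  cat(sprintf("  p vs star/random: %.4g;  p vs Brownian: %.4g\n",
              x$p_vs_star, x$p_vs_brownian))
  invisible(x)
}

#' Pagel's lambda for a continuous trait
#'
#' Maximum-likelihood estimate of the off-diagonal multiplier lambda in
#' \[0, 1\]: the trait is modelled as multivariate normal with mean mu and
#' covariance sigma2 * V(lambda), mu and sigma2 profiled analytically, and
#' lambda found by bounded scalar optimization (tolerance 1e-6; boundary
#' optima are reported exactly at 0 or 1). Significance against the star
#' phylogeny (lambda = 0) and the Brownian model (lambda = 1) is by
#' likelihood-ratio test on one degree of freedom.
#'
#' @param tree Dated `phylo`.
#' @param trait Named numeric vector (names = tip labels); at least 4
#'   tips, non-constant.
#' @return A `signal_result` with `estimate`, `log_likelihood`,
#'   `p_vs_star`, `p_vs_brownian`.
#' @export
pagel_lambda <- function(tree, trait) {
  m <- match_trait_to_tree(tree, trait)
  y <- m$trait
  n <- length(y)
  if (n < 4L) {
    stop_seedspan("lambda needs at least 4 tips (unidentifiable below that)",
                  "seedspan_invalid_input")
  }
  if (stats::var(y) == 0) {
    stop_seedspan("trait is constant across tips", "seedspan_invalid_input")
  }
  V <- phylo_covariance(m$tree)
  ll <- function(lam) profile_loglik(y, lambda_transform(V, lam))$loglik
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(0, opt$maximum, 1)
  vals <- c(ll(0), opt$objective, ll(1))
  best <- which.max(vals)
  lam_hat <- cand[best]
  ll_hat <- vals[best]
  new_signal_result(
    "lambda", lam_hat,
    p_vs_star = stats::pchisq(2 * (ll_hat - vals[1]), 1, lower.tail = FALSE),
    p_vs_brownian = stats::pchisq(2 * (ll_hat - vals[3]), 1, lower.tail = FALSE),
    n_tips = n, log_likelihood = ll_hat)
}

blomberg_stats <- function(y, Vinv, w) {
  a_hat <- sum(w * y)
  e <- y - a_hat
  mse0 <- sum(e * e)
  mse <- drop(t(e) %*% Vinv %*% e)
  c(mse0 = mse0, mse = mse)
}

#' Blomberg's K for a continuous trait
#'
#' K is the ratio of observed to Brownian-expected (MSE0 / MSE), where
#' MSE0 is the mean squared deviation of tips from the phylogenetically
#' weighted mean and MSE is the GLS residual mean square under the tree
#' covariance. K = 1 under Brownian motion; K > 1 means relatives are more
#' similar than BM predicts. Significance follows the original
#' randomization test: tip values are shuffled `n_perm` times and the
#' p-value is the proportion of shuffles whose MSE is at most the observed
#' MSE (a low observed MSE indicates signal).
#'
#' @inheritParams pagel_lambda
#' @param n_perm Number of randomizations (default 1000).
#' @param seed Integer seed for the shuffles.
#' @return A `signal_result`; `p_vs_star` holds the randomization p.
#' @export
blomberg_k <- function(tree, trait, n_perm = 1000, seed = 1) {
  m <- match_trait_to_tree(tree, trait)
  y <- m$trait
  n <- length(y)
  if (n < 4L) {
    stop_seedspan("K needs at least 4 tips", "seedspan_invalid_input")
  }
  if (stats::var(y) == 0) {
    stop_seedspan("trait is constant across tips", "seedspan_invalid_input")
  }
  V <- phylo_covariance(m$tree)
  Vinv <- solve(V)
  w <- colSums(Vinv) / sum(Vinv)
  obs <- blomberg_stats(y, Vinv, w)
  expected_ratio <- (sum(diag(V)) - n / sum(Vinv)) / (n - 1)
  K <- (obs["mse0"] / obs["mse"]) / expected_ratio
  mse_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    blomberg_stats(sample(y), Vinv, w)[["mse"]]
  }, 0))
  new_signal_result(
    "K", unname(K),
    p_vs_star = mean(mse_perm <= obs[["mse"]]),
    p_vs_brownian = NA_real_,
    n_tips = n, n_permutations = n_perm)
}

# Sum of absolute changes in estimated nodal values: tips carry the
# observed states, each internal node the mean of its daughters
# (post-order), and d sums |child - parent| over every branch.
d_sum <- function(val_tips, children, postorder_nodes, edge) {
  n_tip <- length(val_tips)
  val <- c(val_tips, rep(NA_real_, length(postorder_nodes)))
  for (v in postorder_nodes) {
    val[v] <- mean(val[children[[as.character(v)]]])
  }
  sum(abs(val[edge[, 2]] - val[edge[, 1]]))
}

#' Fritz-Purvis D for a binary trait
#'
#' Measures phylogenetic signal in a 0/1 character by the sum of absolute
#' changes d in nodal values estimated by daughter averaging. D scales
#' d_obs between the mean d of `n_sim` prevalence-preserving random
#' shuffles (D = 1, star phylogeny) and the mean d of `n_sim` simulated
#' Brownian liabilities thresholded at the observed prevalence (D = 0,
#' Brownian conservatism); negative D is stronger conservatism than
#' Brownian. One-sided p-values follow the usual orientation:
#' `p_vs_star` is the fraction of random shuffles with d at most d_obs
#' (small = signal present), `p_vs_brownian` the fraction of Brownian
#' simulations with d at least d_obs (small = even more conserved than
#' BM).
#'
#' @inheritParams pagel_lambda
#' @param trait Named binary (0/1 or logical) vector; both states
#'   present. Below 10 tips, or with fewer than 2 tips in a state, a
#'   warning flags wide uncertainty.
#' @param n_sim Number of permutations/simulations per reference model
#'   (default 1000).
#' @param seed Integer seed.
#' @return A `signal_result` with `estimate` = D.
#' @export
fritz_purvis_d <- function(tree, trait, n_sim = 1000, seed = 1) {
  trait <- stats::setNames(as.numeric(trait), names(trait))
  m <- match_trait_to_tree(tree, trait)
  y <- m$trait
  n <- length(y)
  if (!all(y %in% c(0, 1))) {
    stop_seedspan("trait must be binary 0/1", "seedspan_invalid_input")
  }
  k1 <- sum(y == 1)
  if (k1 == 0L || k1 == n) {
    stop_seedspan("trait is monomorphic; D undefined", "seedspan_invalid_input")
  }
  if (n < 10L) warning("fewer than 10 tips: D is very uncertain", call. = FALSE)
  if (min(k1, n - k1) < 2L) {
    warning("a state is carried by fewer than 2 tips: D is very uncertain",
            call. = FALSE)
  }
  tree <- ape::collapse.singles(m$tree)
  n_tip <- ape::Ntip(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  # post-order: reverse of a preorder BFS over internal nodes
  root <- n_tip + 1L
  pre <- root
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    kids <- children[[as.character(v)]]
    kids <- kids[kids > n_tip]
    pre <- c(pre, kids)
    queue <- c(queue, kids)
  }
  post <- rev(pre)
  d_obs <- d_sum(y, children, post, tree$edge)
  V <- phylo_covariance(tree)
  R <- chol(V)
  sims <- with_seed(seed, {
    d_rand <- vapply(seq_len(n_sim), function(i) {
      d_sum(sample(y), children, post, tree$edge)
    }, 0)
    d_bm <- vapply(seq_len(n_sim), function(i) {
      liab <- drop(crossprod(R, stats::rnorm(n_tip)))
      sim <- as.numeric(rank(liab, ties.method = "first") > n_tip - k1)
      d_sum(sim, children, post, tree$edge)
    }, 0)
    list(d_rand = d_rand, d_bm = d_bm)
  })
  d_rand <- sims$d_rand
  d_bm <- sims$d_bm
  D <- (d_obs - mean(d_bm)) / (mean(d_rand) - mean(d_bm))
  new_signal_result(
    "D", D,
    p_vs_star = mean(d_rand <= d_obs),
    p_vs_brownian = mean(d_bm >= d_obs),
    n_tips = n, n_permutations = n_sim,
    extra = list(d_obs = d_obs, mean_d_random = mean(d_rand),
                 mean_d_brownian = mean(d_bm)))
}
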