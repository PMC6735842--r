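# Shared fixtures and independent oracles. Everything is built in code;
# no binary files.

fixture_table <- function() grassland_p50_table()

fixture_tree <- function() {
  suppressWarnings(bladj_adjust(build_taxonomy_tree(fixture_table()),
                                load_node_ages()))
}

# three-tip hand-checkable tree: A and B diverge 25 Myr ago, root 100 Myr
tree3 <- function() ape::read.tree(text = "((A:25,B:25):75,C:100);")

# balanced ultrametric bifurcating tree of depth `age` with 2^k tips
balanced_tree <- function(n_tips, age = 100) {
  gen_tree(n_tips, shape = "balanced", root_age = age)
}

# exact counts on the probit viability curve (rounded to integers)
exact_probit_tc <- function(Ki, sigma, times, n) {
  timecourse("exact", times, n, round(n * pnorm(Ki - times / sigma)))
}

# Independent oracle for the probit ML fit: exhaustive grid search over
# (Ki, sigma) maximizing the same binomial log-likelihood, refined once
# around the coarse optimum with a 10x finer step.
grid_probit_oracle <- function(tc, Ki_range = c(-1, 5), Ki_step = 0.01,
                               sigma_range = c(1, 400), sigma_step = 0.5) {
  t <- tc$time_days; g <- tc$n_germinated; n <- tc$n_tested
  const <- sum(lchoose(n, g))
  best_of <- function(Kis, sigmas) {
    best <- c(ll = -Inf, Ki = NA, sigma = NA)
    inv_s <- 1 / sigmas
    for (K in Kis) {
      p <- pnorm(K - outer(inv_s, t))           # n_sigma x n_times
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll <- const + drop(log(p) %*% g + log1p(-p) %*% (n - g))
      j <- which.max(ll)
      if (ll[j] > best["ll"]) best <- c(ll = ll[j], Ki = K, sigma = sigmas[j])
    }
    best
  }
  coarse <- best_of(seq(Ki_range[1], Ki_range[2], by = Ki_step),
                    seq(sigma_range[1], sigma_range[2], by = sigma_step))
  fine <- best_of(
    seq(coarse["Ki"] - Ki_step, coarse["Ki"] + Ki_step, by = Ki_step / 10),
    seq(max(sigma_range[1], coarse["sigma"] - sigma_step),
        coarse["sigma"] + sigma_step, by = sigma_step / 10))
  fine
}

# Independent multivariate-normal log-likelihood (dense solve/determinant
# path, no Cholesky shortcuts) with profiled GLS mean and ML variance.
mvn_profile_ll_oracle <- function(y, V) {
  n <- length(y)
  Vinv <- solve(V)
  one <- rep(1, n)
  mu <- drop(t(one) %*% Vinv %*% y) / drop(t(one) %*% Vinv %*% one)
  e <- y - mu
  s2 <- drop(t(e) %*% Vinv %*% e) / n
  -0.5 * (n * log(2 * pi * s2) + determinant(V)$modulus[1] + n)
}

# root-to-MRCA shared path lengths computed naively from node paths
vcv_oracle <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(n + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  path <- function(v) {
    out <- integer()
    while (v != root) { out <- c(out, v); v <- parent[v] }
    out
  }
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), path)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    V[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
    if (i == j) V[i, j] <- sum(elen[paths[[i]]])
  }
  V
}
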