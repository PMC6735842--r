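# Viability-curve fitting for controlled-ageing germination time-courses.
#
# The primary model is the viability equation: viability in normal
# equivalent deviates (NED) declines linearly with ageing time,
#   v(p) = Ki - p / sigma,
# so the germinating fraction at time p is pnorm(Ki - p/sigma). Fitting is
# binomial maximum likelihood with a probit link (equivalent to probit
# regression of germinated/tested on time: intercept Ki, slope -1/sigma).
# A negative logistic alternative is provided; model choice is by AIC.
#
# p50 here is the time at which viability reaches 50 % OF INITIAL fitted
# viability (not an absolute 50 %), which stays defined when initial
# viability is below 100 %; the classical absolute definition is also
# provided.

#' Construct a germination time-course
#'
#' @param species_id Species identifier.
#' @param time_days Withdrawal times in days, strictly increasing, >= 0.
#' @param n_tested Seeds tested at each withdrawal (positive integers).
#' @param n_germinated Seeds germinated (0 <= n_germinated <= n_tested).
#' @return A `timecourse` data.frame with attribute `species_id`.
#' @export
timecourse <- function(species_id, time_days, n_tested, n_germinated) {
  if (length(time_days) != length(n_germinated) ||
      length(time_days) != length(n_tested) && length(n_tested) != 1L) {
    stop_seedspan("time_days, n_tested and n_germinated lengths differ",
                  "seedspan_invalid_input")
  }
  n_tested <- rep_len(n_tested, length(time_days))
  if (any(time_days < 0) || is.unsorted(time_days, strictly = TRUE)) {
    stop_seedspan("withdrawal times must be non-negative and strictly increasing",
                  "seedspan_invalid_input")
  }
  if (any(n_tested <= 0 | n_tested != round(n_tested))) {
    stop_seedspan("n_tested must be positive integers", "seedspan_invalid_input")
  }
  if (any(n_germinated < 0 | n_germinated > n_tested)) {
    stop_seedspan("need 0 <= n_germinated <= n_tested at every withdrawal",
                  "seedspan_invalid_input")
  }
  tc <- data.frame(time_days = as.numeric(time_days),
                   n_tested = as.integer(n_tested),
                   n_germinated = as.integer(n_germinated))
  attr(tc, "species_id") <- as.character(species_id)
  class(tc) <- c("timecourse", "data.frame")
  tc
}

#' Read germination time-courses from a long-format CSV
#'
#' Expects columns `species, time_days, n_tested, n_germinated`.
#'
#' @param path CSV path.
#' @return A named list of `timecourse` objects, one per species.
#' @export
read_timecourses <- function(path) {
  if (!file.exists(path)) {
    stop_seedspan(sprintf("file not found: %s", path), "seedspan_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "time_days", "n_tested", "n_germinated")
  if (!all(need %in% names(df))) {
    stop_seedspan(sprintf("time-course CSV needs columns: %s",
                          paste(need, collapse = ", ")),
                  "seedspan_schema_error")
  }
  lapply(split(df, df$species), function(d) {
    d <- d[order(d$time_days), ]
    timecourse(d$species[1], d$time_days, d$n_tested, d$n_germinated)
  })
}

check_timecourse <- function(tc) {
  if (!inherits(tc, "timecourse")) {
    stop_seedspan("not a timecourse object", "seedspan_invalid_input")
  }
  if (nrow(tc) < 3L) {
    stop_seedspan("at least 3 withdrawals are required for fitting",
                  "seedspan_invalid_input")
  }
  invisible(tc)
}

new_viability_fit <- function(model, pars, p50, p50_se, logLik, converged,
                              censored, degenerate, vcov, tc) {
  structure(c(
    list(model = model), pars,
    list(p50 = p50, p50_se = p50_se, log_likelihood = logLik,
         converged = converged, censored = censored, degenerate = degenerate,
         vcov = vcov, n_withdrawals = nrow(tc),
         species_id = attr(tc, "species_id"), timecourse = tc)),
    class = "viability_fit")
}

#' @export
print.viability_fit <- function(x, ...) {
  cat(sprintf("Viability fit (%s) for %s\n", x$model, x$species_id))
  if (x$model == "probit") {
    cat(sprintf("  Ki = %.4f NED, sigma = %.4f days/NED\n", x$Ki, x$sigma))
  } else {
    cat(sprintf("  alpha = %.3f, beta = %.5f /day, c = %.3f days\n",
                x$alpha, x$beta, x$c))
  }
  cat(sprintf("  p50 = %.3f +/- %.3f days%s%s\n", x$p50, x$p50_se,
              if (x$censored) " [censored: beyond observed window]" else "",
              if (x$degenerate) " [degenerate fit; SE unreliable]" else ""))
  cat(sprintf("  logLik = %.4f, converged = %s\n",
              x$log_likelihood, x$converged))
  invisible(x)
}

#' Time to 50 % of initial viability
#'
#' Solves `pnorm(Ki - p/sigma) = pnorm(Ki) / 2` for p, i.e.
#' `p50 = sigma * (Ki - qnorm(pnorm(Ki) / 2))`. Defined for all real Ki;
#' as Ki grows it converges to the classical `Ki * sigma`.
#'
#' @param Ki Initial viability in NED.
#' @param sigma Standard deviation of seed deaths in time (days per NED),
#'   > 0.
#' @return Days until half the initial fitted viability remains.
#' @export
p50_of_initial <- function(Ki, sigma) {
  assert_positive(sigma, "sigma")
  sigma * (Ki - stats::qnorm(stats::pnorm(Ki) / 2))
}

#' Time to an absolute viability of 50 %
#'
#' The classical definition: `p50 = Ki * sigma` (viability in NED reaches
#' 0). Requires initial viability above 50 %, i.e. Ki > 0.
#'
#' @inheritParams p50_of_initial
#' @export
p50_absolute <- function(Ki, sigma) {
  assert_positive(sigma, "sigma")
  if (any(Ki <= 0)) {
    stop_seedspan("p50_absolute undefined for Ki <= 0 (initial viability <= 50 %)",
                  "seedspan_invalid_input")
  }
  Ki * sigma
}

probit_loglik <- function(tc, Ki, sigma) {
  p <- stats::pnorm(Ki - tc$time_days / sigma)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(lchoose(tc$n_tested, tc$n_germinated) +
        tc$n_germinated * log(p) +
        (tc$n_tested - tc$n_germinated) * log1p(-p))
}

#' Fit the probit viability model to a time-course
#'
#' Binomial maximum likelihood with success probability
#' `pnorm(Ki - t/sigma)` (iteratively reweighted least squares, i.e. probit
#' GLM). Standard errors come from the observed information; the p50
#' standard error is delta-method, propagated through
#' [p50_of_initial()].
#'
#' Degenerate data (no viability decline, complete separation, fewer than
#' three informative withdrawals) yield `degenerate = TRUE` with an
#' unreliable (infinite) p50 SE rather than an error. A fit whose p50 lies
#' beyond the last observed withdrawal is flagged `censored = TRUE`; the
#' extrapolated value is still returned.
#'
#' @param tc A [timecourse()].
#' @return A `viability_fit` object.
#' @export
fit_probit <- function(tc) {
  check_timecourse(tc)
  frac <- tc$n_germinated / tc$n_tested
  if (all(tc$n_germinated == 0L)) {
    stop_seedspan("all withdrawals germinated 0 %: no viability information",
                  "seedspan_invalid_input")
  }
  if (all(tc$n_germinated == tc$n_tested)) {
    stop_seedspan("all withdrawals germinated 100 %: no decline observed",
                  "seedspan_invalid_input")
  }
  degenerate <- FALSE
  informative <- sum(tc$n_germinated > 0L & tc$n_germinated < tc$n_tested)
  if (informative < 3L) degenerate <- TRUE
  if (stats::var(frac) == 0) degenerate <- TRUE

  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(n_germinated, n_tested - n_germinated) ~ time_days,
               family = stats::binomial(link = "probit"), data = tc,
               control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (warned) degenerate <- TRUE  # separation / fitted probabilities at 0 or 1
  if (!fit$converged && !degenerate) {
    stop_seedspan(sprintf("probit fit did not converge in %d IRLS iterations",
                          fit$iter), "seedspan_fit_error")
  }

  b <- stats::coef(fit)
  Ki <- unname(b[1])
  slope <- unname(b[2])
  if (!is.finite(slope) || slope >= 0) {
    # viability not declining: p50 undefined/unstable
    degenerate <- TRUE
    slope <- min(slope, -1e-8)
  }
  sigma <- -1 / slope
  p50 <- p50_of_initial(Ki, sigma)

  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V))) {
    degenerate <- TRUE
    p50_se <- Inf
  } else {
    # delta method on (b0, b1): p50 = g(b0) * (-1/b1),
    # g(K) = K - qnorm(pnorm(K)/2)
    gK <- Ki - stats::qnorm(stats::pnorm(Ki) / 2)
    half <- stats::qnorm(stats::pnorm(Ki) / 2)
    dg <- 1 - stats::dnorm(Ki) / (2 * stats::dnorm(half))
    grad <- c(sigma * dg, gK / slope^2)
    p50_se <- sqrt(drop(t(grad) %*% V %*% grad))
    if (!is.finite(p50_se)) {
      degenerate <- TRUE
      p50_se <- Inf
    }
  }
  new_viability_fit(
    model = "probit",
    pars = list(Ki = Ki, sigma = sigma),
    p50 = p50, p50_se = p50_se,
    logLik = probit_loglik(tc, Ki, sigma),
    converged = fit$converged,
    censored = p50 > max(tc$time_days),
    degenerate = degenerate, vcov = V, tc = tc)
}

#' Probit fit by NED regression (secondary cross-check)
#'
#' Transform-then-regress fallback: each withdrawal's germinated fraction
#' is converted to a normal equivalent deviate with the (r + 0.5)/(n + 1)
#' correction (which keeps 0 % and 100 % finite) and Ki, sigma come from an
#' ordinary least-squares line, weighted by seeds tested. Offered only for
#' cross-checking the maximum-likelihood fit; the ML fit is the primary
#' method.
#'
#' @inheritParams fit_probit
#' @return List with `Ki`, `sigma`, `p50`.
#' @export
fit_probit_ned <- function(tc) {
  check_timecourse(tc)
  ned <- stats::qnorm((tc$n_germinated + 0.5) / (tc$n_tested + 1))
  fit <- stats::lm(ned ~ tc$time_days, weights = tc$n_tested)
  b <- stats::coef(fit)
  if (b[2] >= 0) {
    stop_seedspan("NED regression slope is non-negative: no viability decline",
                  "seedspan_fit_error")
  }
  sigma <- -1 / unname(b[2])
  Ki <- unname(b[1])
  list(Ki = Ki, sigma = sigma, p50 = p50_of_initial(Ki, sigma))
}

logistic_curve <- function(t, alpha, beta, cc) {
  (100 - alpha) / (1 + exp(beta * (t - cc)))
}

#' Fit the declining logistic viability model
#'
#' Fits `germination(%) = (100 - alpha) / (1 + exp(beta * (t - c)))` by
#' binomial maximum likelihood: a sigmoid that starts near `100 - alpha`
#' and falls to 0, with `c` the midpoint (and hence this model's p50) and
#' `beta` the decline rate. The curve is implemented in its declining
#' orientation: germination must fall with ageing time, so the exponent
#' carries `+beta (t - c)` with `beta > 0`.
#'
#' @inheritParams fit_probit
#' @return A `viability_fit` object (`model = "logistic"`).
#' @export
fit_logistic <- function(tc) {
  check_timecourse(tc)
  frac <- tc$n_germinated / tc$n_tested
  if (all(tc$n_germinated == 0L) || all(tc$n_germinated == tc$n_tested)) {
    stop_seedspan("time-course carries no decline information",
                  "seedspan_invalid_input")
  }
  nll <- function(par) {
    p <- logistic_curve(tc$time_days, par[1], exp(par[2]), par[3]) / 100
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(tc$n_germinated * log(p) +
           (tc$n_tested - tc$n_germinated) * log1p(-p))
  }
  # moment starts: alpha from the initial plateau, c near the half-way
  # crossing, beta from the steepest observed drop
  a0 <- max(0, min(99, 100 * (1 - max(frac))))
  target <- max(frac) / 2
  c0 <- tc$time_days[which.min(abs(frac - target))]
  c0 <- max(c0, min(tc$time_days[-1]))
  b0 <- 4 / max(diff(range(tc$time_days)) / 4, 1e-3)
  best <- NULL
  starts <- list(c(a0, log(b0), c0), c(0, log(b0 / 4), c0),
                 c(a0, log(b0 * 2), max(tc$time_days) / 2))
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B",
                   lower = c(0, log(1e-6), 1e-6),
                   upper = c(99.99, log(100), max(tc$time_days) * 20),
                   hessian = TRUE),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    stop_seedspan("logistic fit failed from all starts", "seedspan_fit_error")
  }
  alpha <- best$par[1]; beta <- exp(best$par[2]); cc <- best$par[3]
  degenerate <- FALSE
  # SE of c from the observed information (delta through the log-beta
  # parameterization is unnecessary: c is a direct parameter)
  se_c <- tryCatch({
    covm <- solve(best$hessian)
    sqrt(covm[3, 3])
  }, error = function(e) NA_real_)
  if (!is.finite(se_c)) {
    degenerate <- TRUE
    se_c <- Inf
  }
  ll <- -best$value + sum(lchoose(tc$n_tested, tc$n_germinated))
  new_viability_fit(
    model = "logistic",
    pars = list(alpha = alpha, beta = beta, c = cc),
    p50 = cc, p50_se = se_c, logLik = ll,
    converged = best$convergence == 0,
    censored = cc > max(tc$time_days),
    degenerate = degenerate, vcov = NULL, tc = tc)
}

fit_aic <- function(fit) {
  k <- if (fit$model == "probit") 2 else 3
  -2 * fit$log_likelihood + 2 * k
}

#' Choose between probit and logistic fits of one time-course
#'
#' Selects the model with the lower AIC (binomial likelihoods on the same
#' data); ties go to the probit model, the default for this analysis.
#'
#' @param probit_fit,logistic_fit `viability_fit` objects for the same
#'   time-course.
#' @return `"probit"` or `"logistic"`.
#' @export
compare_fits <- function(probit_fit, logistic_fit) {
  stopifnot(probit_fit$model == "probit", logistic_fit$model == "logistic")
  if (fit_aic(logistic_fit) < fit_aic(probit_fit)) "logistic" else "probit"
}

#' Delta-method standard error of p50
#'
#' @param fit A `viability_fit`.
#' @return SE in days (`Inf` when the fit is degenerate).
#' @export
p50_standard_error <- function(fit) {
  stopifnot(inherits(fit, "viability_fit"))
  fit$p50_se
}

#' Predicted percent viable along a fitted survival curve
#'
#' @param fit A `viability_fit`.
#' @param times Days (non-negative numeric vector).
#' @return Percent viable at each time; monotone non-increasing.
#' @export
predict_survival_curve <- function(fit, times) {
  stopifnot(inherits(fit, "viability_fit"))
  if (any(times < 0)) {
    stop_seedspan("times must be >= 0", "seedspan_invalid_input")
  }
  if (fit$model == "probit") {
    100 * stats::pnorm(fit$Ki - times / fit$sigma)
  } else {
    logistic_curve(times, fit$alpha, fit$beta, fit$c)
  }
}

#' Fit viability curves for a batch of species
#'
#' @param tcs Named list of [timecourse()] objects (see
#'   [read_timecourses()]).
#' @param model `"probit"`, `"logistic"` or `"auto"` (AIC choice per
#'   species, ties to probit).
#' @return A data.frame, one row per species: model, parameters, p50,
#'   p50_se, censored and degenerate flags, log-likelihood.
#' @export
fit_viability <- function(tcs, model = c("auto", "probit", "logistic")) {
  model <- match.arg(model)
  rows <- lapply(tcs, function(tc) {
    f <- switch(model,
      probit = fit_probit(tc),
      logistic = fit_logistic(tc),
      auto = {
        fp <- fit_probit(tc)
        fl <- tryCatch(fit_logistic(tc), error = function(e) NULL)
        if (!is.null(fl) && compare_fits(fp, fl) == "logistic") fl else fp
      })
    data.frame(species = f$species_id, model = f$model,
               Ki = f$Ki %||% NA_real_, sigma = f$sigma %||% NA_real_,
               alpha = f$alpha %||% NA_real_, beta = f$beta %||% NA_real_,
               c = f$c %||% NA_real_,
               p50 = f$p50, p50_se = f$p50_se, censored = f$censored,
               degenerate = f$degenerate, logLik = f$log_likelihood,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}
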