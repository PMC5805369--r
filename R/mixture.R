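# Two-component noncentral chi-square mixture over per-tissue Wald
# statistics, fitted by EM: the low-noncentrality component is an empirical
# null (tissues inflated only by cross-tissue annotation correlation), the
# high-noncentrality component holds the trait-relevant tissues.

#' Noncentral chi-square density
#'
#' Density of the noncentral chi-square distribution with `df` degrees of
#' freedom and noncentrality `lambda` (the Poisson-weighted central
#' chi-square mixture). `lambda = 0` reduces to the central density.
#'
#' @param x nonnegative evaluation points.
#' @param df degrees of freedom (positive).
#' @param lambda noncentrality parameter (nonnegative).
#' @return Density values.
#' @export
ncchisq_density <- function(x, df, lambda = 0) {
  if (any(x < 0)) stop("'x' must be nonnegative")
  if (df <= 0 || lambda < 0) stop("invalid df or noncentrality")
  stats::dchisq(x, df = df, ncp = lambda)
}

#' Fit a two-component noncentral chi-square mixture by EM
#'
#' Models a vector of per-tissue Wald statistics as a mixture
#' `(1 - pi) * ncchisq(df, lambda0) + pi * ncchisq(df, lambda1)` with shared
#' degrees of freedom and `lambda1 > lambda0`. The E-step computes
#' responsibilities; the M-step updates `pi` as the mean responsibility and
#' each noncentrality by moment matching, `lambda_k = max(0, weighted mean of
#' w - df)` (the mean of a noncentral chi-square is `df + lambda`). Multiple
#' jittered restarts are run and the best log-likelihood kept.
#'
#' @param wald_stats vector of nonnegative statistics (>= 2 values).
#' @param df shared degrees of freedom (number of annotations fitted).
#' @param n_restarts number of jittered EM restarts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @return Object of class `chisq_mixture`: list with `pi`, `lambda0`,
#'   `lambda1`, `df`, `pp` (per-input posterior probability of the
#'   alternative component), `loglik`, `loglik_trace`, `converged`,
#'   `n_iter`, and `degenerate` (set when the statistics carry no
#'   separation and the fit collapses).
#' @export
chisq_mixture <- function(wald_stats, df, n_restarts = 10L,
                          tol = 1e-8, max_iter = 1000L) {
  w <- as.numeric(wald_stats)
  if (length(w) < 2L || any(!is.finite(w)) || any(w < 0)) {
    stop("need >= 2 finite nonnegative statistics")
  }
  if (stats::sd(w) == 0) {
    # no separation: pin the mixture at a single component
    lam <- max(0, w[1L] - df)
    out <- list(pi = 0.5, lambda0 = lam, lambda1 = lam, df = df,
                pp = rep(0.5, length(w)),
                loglik = sum(log(comp_density(w, df, lam))),
                loglik_trace = NULL, converged = TRUE, n_iter = 0L,
                degenerate = TRUE)
    class(out) <- "chisq_mixture"
    return(out)
  }
  init0 <- list(lambda0 = max(0, stats::median(w) - df),
                lambda1 = max(max(0, stats::median(w) - df) + 1, max(w) - df),
                pi = 0.2)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- init0
    if (r > 1L) {
      # deterministic jitter (no RNG use): spread starts around the default
      f <- 0.5 + (r - 1L) / n_restarts
      init$lambda0 <- init0$lambda0 * f
      init$lambda1 <- init0$lambda1 * (2 - f) + 0.5 * r
      init$pi <- min(0.9, max(0.05, init0$pi * f))
    }
    fit <- em_run(w, df, init, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$df <- df
  class(best) <- "chisq_mixture"
  best
}

comp_density <- function(w, df, lambda) {
  # dchisq's noncentral series is impractically slow for very large
  # noncentrality; beyond that scale the density is effectively normal with
  # mean df + lambda and variance 2(df + 2 lambda)
  if (lambda > 1e4) {
    d <- stats::dnorm(w, mean = df + lambda, sd = sqrt(2 * (df + 2 * lambda)))
  } else {
    d <- stats::dchisq(w, df = df, ncp = lambda)
  }
  pmax(d, 1e-300)
}

obs_loglik <- function(w, df, pi1, l0, l1) {
  sum(log((1 - pi1) * comp_density(w, df, l0) + pi1 * comp_density(w, df, l1)))
}

em_run <- function(w, df, init, tol, max_iter) {
  pi1 <- init$pi; l0 <- init$lambda0; l1 <- init$lambda1
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    d0 <- (1 - pi1) * comp_density(w, df, l0)
    d1 <- pi1 * comp_density(w, df, l1)
    tot <- d0 + d1
    gamma <- d1 / tot
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    pi_new <- mean(gamma)
    s1 <- sum(gamma); s0 <- length(w) - s1
    l1_new <- if (s1 > 0) max(0, sum(gamma * w) / s1 - df) else l1
    l0_new <- if (s0 > 0) max(0, sum((1 - gamma) * w) / s0 - df) else l0
    # The moment-matching update is cheap but is not the exact M-step; if it
    # would lower the observed log-likelihood, fall back to numerically
    # maximizing the expected complete-data log-likelihood (a true M-step,
    # which restores the EM ascent guarantee).
    if (obs_loglik(w, df, pi_new, l0_new, l1_new) < ll) {
      upper <- max(w) + df
      l1_new <- stats::optimize(function(l) sum(gamma * log(comp_density(w, df, l))),
                                c(0, upper), maximum = TRUE)$maximum
      l0_new <- stats::optimize(function(l) sum((1 - gamma) * log(comp_density(w, df, l))),
                                c(0, upper), maximum = TRUE)$maximum
      if (obs_loglik(w, df, pi_new, l0_new, l1_new) < ll) {
        converged <- TRUE  # at a stationary point up to numerical precision
        break
      }
    }
    pi1 <- pi_new; l0 <- l0_new; l1 <- l1_new
    # relabel so that lambda1 > lambda0
    if (l1 < l0) {
      tmp <- l0; l0 <- l1; l1 <- tmp
      pi1 <- 1 - pi1
    }
  }
  d0 <- (1 - pi1) * comp_density(w, df, l0)
  d1 <- pi1 * comp_density(w, df, l1)
  pp <- d1 / (d0 + d1)
  degenerate <- (l1 - l0) < 1e-10
  if (degenerate) pp <- rep(pi1, length(w))
  list(pi = pi1, lambda0 = l0, lambda1 = l1, pp = pp,
       loglik = sum(log(d0 + d1)), loglik_trace = trace,
       converged = converged, n_iter = it, degenerate = degenerate)
}

#' @export
print.chisq_mixture <- function(x, ...) {
  cat(sprintf(
    "Noncentral chi-square mixture (df = %s): pi = %.3f, lambda0 = %.3f, lambda1 = %.3f\n",
    format(x$df), x$pi, x$lambda0, x$lambda1))
  cat(sprintf("log-likelihood %.4f after %d iteration(s)%s%s\n",
              x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)",
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Classify tissues from a fitted mixture
#'
#' @param fit a [chisq_mixture()] object.
#' @param tissues optional tissue labels aligned with the fitted statistics.
#' @param threshold posterior-probability cutoff for calling a tissue
#'   trait-relevant (strictly greater than).
#' @return List with `relevant` (labels with `pp > threshold`), `top`
#'   (argmax tissue, always reported even when below threshold), and the
#'   `pp` vector (named when labels are given).
#' @export
classify_tissues <- function(fit, tissues = NULL, threshold = 0.5) {
  stopifnot(inherits(fit, "chisq_mixture"))
  pp <- fit$pp
  if (is.null(tissues)) tissues <- paste0("tissue", seq_along(pp))
  names(pp) <- tissues
  list(relevant = tissues[pp > threshold],
       top = tissues[which.max(pp)],
       pp = pp)
}
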