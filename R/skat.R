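# Annotation-informed SNP weights and the weighted kernel (SKAT-style)
# SNP-set association test, with Davies/Imhof tail probabilities for the
# mixture-of-chi-squares null distribution and a Liu moment-matching
# fallback.

#' Model-based per-SNP effect-size variances
#'
#' Computes `sigma2_j = A_j' alpha*` from fitted annotation coefficients,
#' applying the centering statistics of the fitting cohort to the supplied
#' raw annotation values. The result may be negative before the weight
#' transformation ([construct_weights()] shifts it positive).
#'
#' @param A_gene raw annotation values for the SNPs of interest: numeric
#'   matrix (SNPs x annotations) or vector for a single SNP; columns must
#'   match the annotations used in fitting.
#' @param alpha_star fitted coefficient vector (`alpha0` then annotation
#'   coefficients), e.g. `coef()` of a [gee_fit()].
#' @param centering optional centered [annotation_matrix()] whose
#'   `center`/`scale` statistics are applied to `A_gene` first. When `NULL`,
#'   `A_gene` is assumed already centered (an intercept column is added if
#'   absent).
#' @return Numeric vector of per-SNP variances.
#' @export
snp_variances <- function(A_gene, alpha_star, centering = NULL) {
  if (!is.null(centering)) {
    A <- apply_centering(centering, A_gene)
  } else {
    A <- if (is.null(dim(A_gene))) matrix(A_gene, nrow = 1L) else as.matrix(A_gene)
    if (ncol(A) == length(alpha_star) - 1L) A <- cbind(1, A)
  }
  if (ncol(A) != length(alpha_star)) {
    stop("annotation columns (", ncol(A), ") do not match coefficients (",
         length(alpha_star), ")")
  }
  drop(A %*% alpha_star)
}

#' Construct positive SNP weights from model variances
#'
#' Shifts the per-SNP variances positive by subtracting the minimum and
#' adding a small constant (1e-15), then shrinks towards equal weights by
#' the posterior probability of the top trait-relevant tissue:
#' `w_j = pp * (sigma2_j - min(sigma2) + 1e-15) + (1 - pp)`. With `pp = 0`
#' the weights are exactly equal, so the test degrades gracefully when no
#' tissue appears trait-relevant.
#'
#' @param sigma2 per-SNP variances from [snp_variances()].
#' @param pp posterior probability of the top tissue, in `[0, 1]`.
#' @return Object of class `snp_weights`: list with `sigma2`, `weights`
#'   (all strictly positive) and `pp`.
#' @export
construct_weights <- function(sigma2, pp) {
  if (length(pp) != 1L || !is.finite(pp) || pp < 0 || pp > 1) {
    stop("'pp' must be a single value in [0, 1]")
  }
  if (length(sigma2) < 1L) stop("need at least one SNP")
  v <- sigma2 - min(sigma2) + 1e-15
  w <- pp * v + (1 - pp)
  structure(list(sigma2 = sigma2, weights = w, pp = pp),
            class = "snp_weights")
}

#' @export
print.snp_weights <- function(x, ...) {
  cat(sprintf("SNP weights for %d SNP(s); tissue posterior probability %.3f\n",
              length(x$weights), x$pp))
  print(utils::head(data.frame(sigma2 = x$sigma2, weight = x$weights)))
  if (length(x$weights) > 6L) cat("...\n")
  invisible(x)
}

#' Fit the SNP-set test null model
#'
#' @param y phenotype vector: quantitative, or 0/1 for a binary trait.
#' @param covariates optional numeric matrix/data frame of covariates (an
#'   intercept is always included).
#' @param family `"quantitative"` (least squares) or `"binary"`
#'   (logistic regression).
#' @return Object of class `skat_null`: list with `family`, `residuals`
#'   (`y - fitted`), `fitted`, `X` (covariate design including intercept),
#'   and for the quantitative case `sigma2` (residual variance under the
#'   null), for the binary case `var_weights` (`mu * (1 - mu)`).
#' @export
skat_null_model <- function(y, covariates = NULL,
                            family = c("quantitative", "binary")) {
  family <- match.arg(family)
  y <- as.numeric(y)
  X <- cbind(intercept = rep(1, length(y)),
             if (!is.null(covariates)) as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("covariates are rank deficient")
  if (family == "quantitative") {
    fit <- stats::lm.fit(X, y)
    res <- fit$residuals
    out <- list(family = family, residuals = res, fitted = fit$fitted.values,
                X = X, sigma2 = sum(res^2) / (length(y) - ncol(X)))
  } else {
    if (!all(y %in% c(0, 1))) stop("binary phenotype must be coded 0/1")
    fit <- stats::glm.fit(X, y, family = stats::binomial())
    if (!fit$converged || any(fit$fitted.values < 1e-10) ||
        any(fit$fitted.values > 1 - 1e-10)) {
      stop("logistic null model did not converge (possible separation); ",
           "check covariates or use fewer of them")
    }
    mu <- fit$fitted.values
    out <- list(family = family, residuals = y - mu, fitted = mu,
                X = X, var_weights = mu * (1 - mu))
  }
  class(out) <- "skat_null"
  out
}

#' Weighted kernel SNP-set association test
#'
#' Computes the variance-component score statistic `Q = r' G W G' r` for a
#' genotype block `G` with diagonal SNP weights `W` and null-model residuals
#' `r`, and evaluates its p-value against the null distribution
#' `sum_k xi_k chi2_1`, where the `xi_k` are the eigenvalues of
#' `W^{1/2} G' P G W^{1/2}` and `P` is the null-model variance/projection
#' operator. Tail probabilities use Imhof/Davies numerical inversion with a
#' Liu-type moment-matching fallback. Genotype columns are centered by their
#' sample means before entering the kernel.
#'
#' @param G genotype block, individuals x SNPs (dosages).
#' @param weights a [construct_weights()] object, or a bare numeric vector
#'   of nonnegative per-SNP weights.
#' @param null a [skat_null_model()] object.
#' @param gene_id optional label carried into the result.
#' @return Object of class `skat_result`: list with `gene_id`, `n_snps`,
#'   `Q`, `pvalue` and `method` ("davies" or "liu"). An all-zero genotype
#'   block returns `Q = 0`, `pvalue = 1` with a flag.
#' @export
skat_test <- function(G, weights, null, gene_id = NA_character_) {
  stopifnot(inherits(null, "skat_null"))
  G <- as.matrix(G)
  w <- if (inherits(weights, "snp_weights")) weights$weights else as.numeric(weights)
  if (ncol(G) != length(w)) stop("genotype columns (", ncol(G),
                                 ") do not match weights (", length(w), ")")
  if (any(w < 0)) stop("weights must be nonnegative")
  Gc <- sweep(G, 2L, colMeans(G), `-`)
  Z <- sweep(Gc, 2L, sqrt(w), `*`)
  r <- null$residuals
  Q <- sum(drop(crossprod(Z, r))^2)
  if (all(Gc == 0) || all(w == 0)) {
    return(structure(list(gene_id = gene_id, n_snps = ncol(G), Q = 0,
                          pvalue = 1, method = "degenerate", degenerate = TRUE),
                     class = "skat_result"))
  }
  lam <- skat_eigenvalues(Z, null)
  pv <- mixture_chisq_tail(Q, lam)
  structure(list(gene_id = gene_id, n_snps = ncol(G), Q = Q,
                 pvalue = pv$p, method = pv$method, degenerate = FALSE),
            class = "skat_result")
}

#' @export
print.skat_result <- function(x, ...) {
  cat(sprintf("SNP-set test%s: %d SNPs, Q = %.4f, p = %.4g (%s)\n",
              if (!is.na(x$gene_id)) paste0(" [", x$gene_id, "]") else "",
              x$n_snps, x$Q, x$pvalue, x$method))
  invisible(x)
}

# Eigenvalues of W^{1/2} G' P G W^{1/2} for the null distribution of Q.
# Quantitative: P = sigma2 * (I - H) with H the hat matrix of the null
# covariates; binary: P = V - V X (X'VX)^{-1} X'V with V = diag(mu(1-mu)).
skat_eigenvalues <- function(Z, null) {
  X <- null$X
  if (null$family == "quantitative") {
    Zp <- Z - X %*% solve(crossprod(X), crossprod(X, Z))
    K <- null$sigma2 * crossprod(Z, Zp)
  } else {
    v <- null$var_weights
    VZ <- Z * v
    VX <- X * v
    K <- crossprod(Z, VZ) -
      crossprod(Z, VX) %*% solve(crossprod(X, VX), crossprod(VX, Z))
  }
  lam <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10 * max(lam, 0)]
  lam
}

# P(sum_k lam_k chi2_1 > q) by Davies/Imhof numerical inversion: the
# oscillatory inversion integral is summed piecewise over half-periods
# (each piece is smooth, and the piece magnitudes eventually decay like
# u^{-(1 + k/2)}), with a Liu-type moment-matching fallback if the
# summation does not settle.
mixture_chisq_tail <- function(q, lam) {
  if (length(lam) == 0L) return(list(p = 1, method = "degenerate"))
  if (length(lam) == 1L) {
    return(list(p = stats::pchisq(q / lam, df = 1, lower.tail = FALSE),
                method = "exact"))
  }
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lam, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lam^2, u^2))))
    sin(theta) / (u * rho)
  }
  # half-period of the fastest oscillation the phase can reach; each
  # half-period is integrated with 16-point Gauss-Legendre quadrature
  # (machine accuracy for a smooth piece), batched for vectorization
  h <- pi / (0.5 * (q + sum(lam)))
  batch <- 256L
  acc <- 0
  lo <- 0
  converged <- FALSE
  # successive pieces essentially alternate in sign, so the truncation error
  # is of the order of the last piece; 1e-9 suffices for the p-value scales
  # at which the Davies route is trusted
  for (b in seq_len(80L)) {
    edges <- lo + h * (0:batch)
    mids <- (edges[-1L] + edges[-(batch + 1L)]) / 2
    half <- h / 2
    u <- outer(gl16_nodes * half, mids, `+`)   # 16 x batch evaluation points
    vals <- matrix(integrand(as.vector(u)), nrow = 16L)
    pieces <- colSums(vals * gl16_weights) * half
    acc <- acc + sum(pieces)
    lo <- lo + batch * h
    if (max(abs(pieces[(batch - 15L):batch])) < 1e-9) {
      converged <- TRUE
      break
    }
  }
  if (converged && is.finite(acc)) {
    p <- 0.5 + acc / pi
    if (p > 1e-11 && p <= 1 + 1e-8) {
      return(list(p = min(max(p, 1e-300), 1), method = "davies"))
    }
  }
  list(p = liu_tail(q, lam), method = "liu")
}

# 16-point Gauss-Legendre nodes and weights on [-1, 1]
gl16_nodes <- c(-0.9894009349916499, -0.9445750230732326, -0.8656312023878318,
                -0.7554044083550030, -0.6178762444026438, -0.4580167776572274,
                -0.2816035507792589, -0.0950125098376374, 0.0950125098376374,
                0.2816035507792589, 0.4580167776572274, 0.6178762444026438,
                0.7554044083550030, 0.8656312023878318, 0.9445750230732326,
                0.9894009349916499)
gl16_weights <- c(0.0271524594117541, 0.0622535239386479, 0.0951585116824928,
                  0.1246289712555339, 0.1495959888165767, 0.1691565193950025,
                  0.1826034150449236, 0.1894506104550685, 0.1894506104550685,
                  0.1826034150449236, 0.1691565193950025, 0.1495959888165767,
                  0.1246289712555339, 0.0951585116824928, 0.0622535239386479,
                  0.0271524594117541)

# Liu et al. moment-matching approximation to the mixture tail.
liu_tail <- function(q, lam) {
  c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3); c4 <- sum(lam^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    delta <- 0
    df <- 1 / s2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- df + delta; sigma_x <- sqrt(2 * (df + 2 * delta))
  t_star <- (q - mu_q) / sigma_q * sigma_x + mu_x
  stats::pchisq(t_star, df = df, ncp = delta, lower.tail = FALSE)
}

#' Assemble gene-based SNP sets
#'
#' Extends each gene by a flanking window (default 10 kb on both sides),
#' collects the SNPs falling in the extended window (inclusive bounds), and
#' drops genes with fewer than `min_snps` SNPs.
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive) and optionally `strand`.
#' @param snps SNP table (`snp_id`, `chrom`, `pos`).
#' @param window flank size in bp added on both sides (or upstream of the
#'   transcription start / downstream of the end when `stranded = TRUE`).
#' @param min_snps minimum number of SNPs for a gene set to be kept.
#' @param upstream,downstream optional asymmetric flanks (bp) relative to
#'   transcription direction, overriding `window`; for `-`-strand genes (a
#'   `strand` column is then required) upstream extends past `end` and
#'   downstream past `start`. The default symmetric window is
#'   strand-agnostic.
#' @return List of gene sets, each a list with `gene_id`, `chrom`,
#'   `window_start`, `window_end`, `snp_ids` and `snp_indices` (row indices
#'   into the supplied, sorted SNP table). Malformed gene rows are skipped
#'   with a warning. The number of kept/dropped genes is reported via
#'   `message()`.
#' @export
assemble_gene_sets <- function(genes, snps, window = 10000L, min_snps = 10L,
                               upstream = NULL, downstream = NULL) {
  genes <- as.data.frame(genes)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(genes))) {
    stop("gene table must have columns ", paste(need, collapse = ", "))
  }
  snps <- validate_snp_table(snps)
  bad <- !is.finite(genes$start) | !is.finite(genes$end) | genes$start > genes$end
  if (any(bad)) {
    warning("skipping ", sum(bad), " malformed gene row(s)")
    genes <- genes[!bad, , drop = FALSE]
  }
  out <- list()
  dropped <- 0L
  asym <- !is.null(upstream) || !is.null(downstream)
  if (asym) {
    if (is.null(upstream)) upstream <- window
    if (is.null(downstream)) downstream <- window
    if (!"strand" %in% names(genes)) {
      stop("asymmetric windows require a 'strand' column")
    }
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (asym && identical(as.character(g$strand), "-")) {
      lo <- g$start - downstream; hi <- g$end + upstream
    } else if (asym) {
      lo <- g$start - upstream; hi <- g$end + downstream
    } else {
      lo <- g$start - window; hi <- g$end + window
    }
    sel <- which(snps$chrom == as.character(g$chrom) &
                   snps$pos >= lo & snps$pos <= hi)
    if (length(sel) >= min_snps) {
      out[[length(out) + 1L]] <- list(gene_id = as.character(g$gene_id),
                                      chrom = as.character(g$chrom),
                                      window_start = lo, window_end = hi,
                                      snp_ids = snps$snp_id[sel],
                                      snp_indices = sel)
    } else {
      dropped <- dropped + 1L
    }
  }
  message(length(out), " gene set(s) kept, ", dropped,
          " dropped with fewer than ", min_snps, " SNPs")
  out
}
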