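# Synthetic-data generator: genotypes with block-wise LD, tissue-correlated
# annotations, annotation-dependent effect sizes, marginal association
# scans, and the two full simulation designs (trait-relevant tissue
# identification; weighted SNP-set testing) with power/FDR evaluation.

#' Simulate unphased genotypes
#'
#' Draws Hardy-Weinberg genotypes (0/1/2) with per-SNP minor allele
#' frequencies uniform on `maf_range`. With `ld = "ar1"` a latent Gaussian
#' copula with within-block correlation `rho^|i-j|` induces block-wise
#' linkage disequilibrium; blocks are contiguous windows of `block_size`
#' SNPs and are mutually independent.
#'
#' @param n number of individuals.
#' @param m number of SNPs.
#' @param maf_range range for the uniform minor-allele-frequency draw.
#' @param ld `"independent"` or `"ar1"`.
#' @param rho AR(1) copula correlation (used for `ld = "ar1"`).
#' @param block_size SNPs per LD block.
#' @param maf optional vector of fixed allele frequencies (overrides
#'   `maf_range`).
#' @param seed optional integer seed (set before any draws).
#' @return Numeric `n x m` matrix with entries in `{0, 1, 2}`; the allele
#'   frequencies used are attached as attribute `"maf"`.
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               ld = c("independent", "ar1"), rho = 0.5,
                               block_size = 100L, maf = NULL, seed = NULL) {
  ld <- match.arg(ld)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) {
    if (maf_range[1] <= 0 || maf_range[2] > 0.5) stop("maf_range must lie in (0, 0.5]")
    maf <- stats::runif(m, maf_range[1], maf_range[2])
  }
  X <- matrix(0, n, m)
  # latent-normal thresholds reproducing Hardy-Weinberg genotype frequencies
  a <- stats::qnorm((1 - maf)^2)
  b <- stats::qnorm(1 - maf^2)
  s <- sqrt(1 - rho^2)
  starts <- seq.int(1L, m, by = block_size)
  for (st in starts) {
    en <- min(st + block_size - 1L, m)
    z <- stats::rnorm(n)
    X[, st] <- (z > a[st]) + (z > b[st])
    if (en > st) {
      for (j in (st + 1L):en) {
        z <- if (ld == "ar1") rho * z + s * stats::rnorm(n) else stats::rnorm(n)
        X[, j] <- (z > a[j]) + (z > b[j])
      }
    }
  }
  attr(X, "maf") <- maf
  X
}

#' Simulate correlated tissue-specific annotations
#'
#' Emulates binary histone-mark occupancy tracks: peaks cover runs of
#' consecutive SNPs (a two-state Markov chain along the genome with the
#' given occupancy and mean on-run length), and annotations are strongly
#' correlated across tissues. For each mark a shared template track is
#' drawn; each tissue follows the template over segments covering a
#' `sqrt(cross_tissue_corr)` fraction of SNPs and substitutes an
#' independent track elsewhere, so the realized pairwise cross-tissue
#' correlation is approximately `cross_tissue_corr` and increases
#' monotonically in it.
#'
#' @param m number of SNPs.
#' @param n_tissues number of tissues.
#' @param occupancy per-mark genome occupancy (vector; its length sets the
#'   number of annotations per tissue). Defaults to typical enhancer- and
#'   promoter-mark occupancies (about 18% and 11%).
#' @param cross_tissue_corr target cross-tissue correlation in `[0, 1)`.
#' @param run_length mean number of consecutive SNPs covered by one peak
#'   run; `1` gives independent per-SNP draws.
#' @param labels optional annotation labels (defaults to `mark1`, ...).
#' @param seed optional integer seed.
#' @return Named list of `n_tissues` uncentered [annotation_matrix()]
#'   objects with binary annotation columns.
#' @export
simulate_tissue_annotations <- function(m, n_tissues = 10L,
                                        occupancy = c(0.18, 0.11),
                                        cross_tissue_corr = 0.7,
                                        run_length = 5,
                                        labels = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(occupancy <= 0 | occupancy >= 1)) stop("occupancy must be in (0, 1)")
  if (cross_tissue_corr < 0 || cross_tissue_corr >= 1) {
    stop("cross_tissue_corr must be in [0, 1)")
  }
  k <- length(occupancy)
  if (is.null(labels)) labels <- paste0("mark", seq_len(k))
  keep_rate <- sqrt(cross_tissue_corr)
  templates <- lapply(occupancy, function(q) segment_track(m, q, run_length))
  out <- vector("list", n_tissues)
  names(out) <- paste0("tissue", seq_len(n_tissues))
  for (t in seq_len(n_tissues)) {
    C <- matrix(0, m, k)
    for (j in seq_len(k)) {
      keep <- segment_track(m, keep_rate, run_length)
      fresh <- segment_track(m, occupancy[j], run_length)
      C[, j] <- ifelse(keep == 1, templates[[j]], fresh)
    }
    colnames(C) <- labels
    out[[t]] <- annotation_matrix(C, labels = labels, tissue = names(out)[t])
  }
  out
}

# Stationary two-state Markov chain along SNP positions: occupancy q, mean
# on-run length L SNPs (L = 1 reduces to independent Bernoulli draws).
segment_track <- function(m, q, L = 5) {
  if (L <= 1) return(as.numeric(stats::runif(m) < q))
  p10 <- 1 / L
  p01 <- q / ((1 - q) * L)
  if (p01 >= 1) return(as.numeric(stats::runif(m) < q))
  u <- stats::runif(m)
  x <- numeric(m)
  x[1L] <- u[1L] < q
  for (j in 2L:m) {
    x[j] <- if (x[j - 1L] == 1) u[j] > p10 else u[j] < p01
  }
  x
}

#' Simulate causality-correlated annotation pairs
#'
#' Generates the two-annotation scheme used to study weighted SNP-set tests:
#' non-causal SNPs draw both annotations from N(0, 1); causal SNPs are
#' randomly divided into three groups with the given proportions, the first
#' annotation is elevated (N(10, 1)) in groups 2 and 3 and the second in
#' groups 1 and 3. In group 3 the two annotations share the same elevated
#' value (they are identical there), so the proportion of group 3 controls
#' the correlation between the two annotations among causal SNPs.
#'
#' @param m number of SNPs.
#' @param causal_indices integer indices of the causal SNPs.
#' @param group_proportions length-3 nonnegative proportions summing to 1.
#' @param elevated_mean mean of the elevated annotation distribution.
#' @param seed optional integer seed.
#' @return List with `C` (an `m x 2` annotation value matrix) and `groups`
#'   (integer group label 1-3 per causal SNP, in `causal_indices` order).
#' @export
simulate_causal_annotations <- function(m, causal_indices,
                                        group_proportions = c(1/3, 1/3, 1/3),
                                        elevated_mean = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(group_proportions) != 3L ||
      abs(sum(group_proportions) - 1) > 1e-8 || any(group_proportions < 0)) {
    stop("group_proportions must be 3 nonnegative values summing to 1")
  }
  C <- matrix(stats::rnorm(2 * m), m, 2, dimnames = list(NULL, c("anno1", "anno2")))
  nc <- length(causal_indices)
  groups <- sample(rep.int(1:3, round_proportions(nc, group_proportions)))
  elev1 <- causal_indices[groups %in% c(2L, 3L)]
  elev2 <- causal_indices[groups %in% c(1L, 3L)]
  C[elev1, 1L] <- C[elev1, 1L] + elevated_mean
  C[elev2, 2L] <- C[elev2, 2L] + elevated_mean
  shared <- causal_indices[groups == 3L]
  C[shared, 2L] <- C[shared, 1L]
  list(C = C, groups = groups)
}

# Largest-remainder apportionment of n into 3 integer counts.
round_proportions <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate effect sizes and phenotype under the annotation model
#'
#' Each (causal) SNP effect is drawn `beta_j ~ N(0, sigma2_j / m)` with
#' `sigma2_j = A_j' alpha*` computed from centered annotations and clamped
#' below at zero (a negative linear predictor cannot be a variance);
#' phenotypes are `y = X beta + e`, `e ~ N(0, sigma_e2)`.
#'
#' @param X standardized genotype matrix (columns mean 0, variance 1).
#' @param A centered [annotation_matrix()] for the trait-relevant tissue (or
#'   a bare matrix including the intercept column).
#' @param alpha_star coefficient vector (`alpha0`, then annotation
#'   coefficients).
#' @param sigma_e2 residual variance.
#' @param causal optional integer indices; SNPs outside the set get zero
#'   effects.
#' @param seed optional integer seed.
#' @return List with `beta`, `y`, `sigma2` (per-SNP variance after
#'   clamping, zeroed outside `causal`), and `genetic` (the genetic values
#'   `X beta`). Warns when a nonzero `alpha_star` is requested but clamping
#'   removes all variance.
#' @export
simulate_effects_phenotype <- function(X, A, alpha_star, sigma_e2,
                                       causal = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- if (inherits(A, "annotation_matrix")) A$values else as.matrix(A)
  m <- ncol(X)
  if (nrow(V) != m) stop("annotation rows must match genotype columns")
  sigma2 <- pmax(drop(V %*% alpha_star), 0)
  if (all(sigma2 == 0) && any(alpha_star != 0)) {
    warning("all SNP variances clamped to zero under nonzero coefficients")
  }
  if (!is.null(causal)) {
    mask <- rep(0, m); mask[causal] <- 1
    sigma2 <- sigma2 * mask
  }
  beta <- stats::rnorm(m, 0, sqrt(sigma2 / m))
  nz <- which(beta != 0)
  genetic <- if (length(nz) < m / 4) {
    drop(X[, nz, drop = FALSE] %*% beta[nz])
  } else {
    drop(X %*% beta)
  }
  y <- genetic + stats::rnorm(nrow(X), 0, sqrt(sigma_e2))
  list(beta = beta, y = y, sigma2 = sigma2, genetic = genetic)
}

#' Single-SNP association scan
#'
#' Fits a simple linear regression of the phenotype on each SNP in turn and
#' returns marginal z-statistics and chi-square statistics (`z^2`).
#' Zero-variance SNPs yield `NA` with a message.
#'
#' @param X genotype matrix (any column scaling; an intercept is implicit).
#' @param y phenotype vector.
#' @return Data frame with columns `z` and `chisq`; attribute `"n"` holds
#'   the sample size.
#' @export
marginal_scan <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  cs <- drop(crossprod(X, yc))
  mu <- colMeans(X)
  sxx <- drop(crossprod(rep(1, n), X^2)) - n * mu^2
  bad <- sxx <= 0
  if (any(bad)) message(sum(bad), " zero-variance SNP(s) set to NA")
  r2 <- cs^2 / (sxx * syy)
  r2 <- pmin(r2, 1)
  t2 <- r2 * (n - 2) / pmax(1 - r2, .Machine$double.eps)
  z <- sign(cs) * sqrt(t2)
  z[bad] <- NA_real_
  out <- data.frame(z = z, chisq = z^2)
  attr(out, "n") <- n
  out
}

# Fast scan for columns already standardized to mean 0, sd 1 (sxx = n-1).
scan_standardized <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  cs <- drop(crossprod(X, yc))
  r2 <- pmin(cs^2 / ((n - 1) * syy), 1)
  r2 * (n - 2) / pmax(1 - r2, .Machine$double.eps)
}

#' Per-block proportion of phenotypic variance explained
#'
#' `PVE_b = Var(X_b beta_b) / Var(y)`, the realized share of phenotype
#' variance attributable to the SNPs of each block.
#'
#' @param beta effect-size vector.
#' @param X genotype matrix used to generate the phenotype.
#' @param blocks list of SNP index vectors partitioning the columns of `X`.
#' @param y the phenotype vector.
#' @return Numeric vector of per-block PVE values.
#' @export
per_block_pve <- function(beta, X, blocks, y) {
  vy <- stats::var(y)
  vapply(blocks, function(ix) {
    b <- beta[ix]
    nz <- which(b != 0)
    if (length(nz) == 0L) return(0)
    g <- drop(X[, ix[nz], drop = FALSE] %*% b[nz])
    stats::var(g) / vy
  }, 0)
}

#' Power at a target false discovery rate from posterior probabilities
#'
#' Pools all (replicate, tissue) posterior probabilities, sorts them in
#' decreasing order (ties broken by stable input order, replicates varying
#' slowest), and walks down the list: at each cutoff the empirical FDR is
#' `FP / (FP + TP)` and the power at level `t` is `TP / n_replicates`
#' evaluated at the most permissive cutoff whose FDR is at most `t`.
#'
#' @param pp_table numeric matrix, replicates in rows, tissues in columns.
#' @param truth integer vector giving the index of the one true
#'   trait-relevant tissue per replicate.
#' @param fdr_levels FDR levels at which to report power.
#' @return Named numeric vector of power values, one per FDR level.
#' @export
evaluate_power_at_fdr <- function(pp_table, truth,
                                  fdr_levels = c(0.05, 0.1, 0.2)) {
  pp_table <- as.matrix(pp_table)
  R <- nrow(pp_table)
  stopifnot(length(truth) == R)
  is_true <- matrix(FALSE, R, ncol(pp_table))
  is_true[cbind(seq_len(R), truth)] <- TRUE
  pp <- as.vector(t(pp_table))       # replicate-major pooling order
  lab <- as.vector(t(is_true))
  ord <- order(-pp)                  # stable for ties
  lab <- lab[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  fdr <- fp / (fp + tp)
  out <- vapply(fdr_levels, function(t) {
    ok <- which(fdr <= t)
    if (length(ok) == 0L) 0 else tp[max(ok)] / R
  }, 0)
  names(out) <- paste0("fdr", fdr_levels)
  out
}

#' Sample non-adjacent blocks
#'
#' Uniformly samples `k` block indices from `1..n_blocks` such that no two
#' selected blocks are adjacent (rejection sampling).
#'
#' @param n_blocks total number of blocks.
#' @param k number of blocks to select.
#' @return Sorted integer vector of block indices.
#' @export
sample_nonadjacent_blocks <- function(n_blocks, k) {
  if (k > (n_blocks + 1) %/% 2) stop("cannot place ", k, " non-adjacent blocks")
  repeat {
    sel <- sort(sample.int(n_blocks, k))
    if (k < 2L || all(diff(sel) > 1L)) return(sel)
  }
}

#' SNP heritability implied by the generative parameters
#'
#' With centered annotations the expected total genetic variance equals the
#' variance intercept, so `h2 = alpha0 / (alpha0 + sigma_e2)`.
#'
#' @param alpha0 variance intercept.
#' @param sigma_e2 residual variance.
#' @return Implied SNP heritability.
#' @export
implied_heritability <- function(alpha0, sigma_e2) {
  alpha0 / (alpha0 + sigma_e2)
}
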