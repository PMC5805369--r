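# Block-diagonal LD estimation from a reference panel and construction of
# the moment-equation design matrix for the chi-square regression.

#' Estimate block-diagonal LD from a reference panel
#'
#' Partitions SNPs into contiguous blocks and computes the Pearson
#' correlation matrix of the reference genotypes within each block. The
#' block-diagonal approximation captures the dominant block-wise linkage
#' disequilibrium of the genome while keeping computation and storage linear
#' in the number of SNPs.
#'
#' @param ref_genotypes numeric matrix of reference-panel genotypes,
#'   individuals in rows, SNPs in columns.
#' @param block_size number of SNPs per contiguous block (ignored when
#'   `boundaries` is given).
#' @param boundaries optional two-column matrix/data frame of 1-based
#'   (start, end) SNP indices that partition `1..m`.
#' @param adjust logical; apply the unbiased squared-correlation adjustment
#'   `r2_adj = r2 - (1 - r2) / (n_ref - 2)` toward the population value when
#'   squared correlations are consumed downstream (default `TRUE`).
#' @return An object of class `ld_blocks`: list with `blocks` (list of index
#'   ranges), `corr` (list of per-block correlation matrices), `n_ref`,
#'   `adjust`, and `m`. Monomorphic reference SNPs are flagged and treated as
#'   LD-independent (identity row/column).
#' @export
estimate_ld_blocks <- function(ref_genotypes, block_size = 1000L,
                               boundaries = NULL, adjust = TRUE) {
  X <- as.matrix(ref_genotypes)
  m <- ncol(X)
  n_ref <- nrow(X)
  if (is.null(boundaries)) {
    starts <- seq.int(1L, m, by = block_size)
    boundaries <- cbind(starts, pmin(starts + block_size - 1L, m))
  } else {
    boundaries <- as.matrix(boundaries)[, 1:2, drop = FALSE]
  }
  idx <- unlist(lapply(seq_len(nrow(boundaries)),
                       function(b) boundaries[b, 1L]:boundaries[b, 2L]))
  if (length(idx) != m || any(sort(idx) != seq_len(m))) {
    stop("block boundaries must partition 1..m")
  }
  mono <- logical(m)
  corr <- vector("list", nrow(boundaries))
  blocks <- vector("list", nrow(boundaries))
  for (b in seq_len(nrow(boundaries))) {
    ix <- boundaries[b, 1L]:boundaries[b, 2L]
    blocks[[b]] <- ix
    Xb <- X[, ix, drop = FALSE]
    sds <- apply(Xb, 2L, stats::sd)
    bad <- sds == 0 | !is.finite(sds)
    r <- diag(length(ix))
    if (any(!bad)) {
      r_ok <- stats::cor(Xb[, !bad, drop = FALSE])
      r[!bad, !bad] <- r_ok
    }
    if (any(bad)) {
      mono[ix[bad]] <- TRUE
      r[bad, ] <- 0; r[, bad] <- 0; diag(r) <- 1
    }
    corr[[b]] <- r
  }
  if (any(mono)) {
    warning(sum(mono), " monomorphic reference SNP(s) treated as LD-independent")
  }
  structure(list(blocks = blocks, corr = corr, n_ref = n_ref,
                 adjust = adjust, m = m, monomorphic = which(mono)),
            class = "ld_blocks")
}

#' Identity (no-LD) block structure
#'
#' Convenience constructor for a trivial LD structure where every SNP is its
#' own block; useful for testing and for summary statistics already pruned to
#' approximate linkage equilibrium. Note that the blocks also serve as the
#' sandwich-covariance clusters of [gee_fit()], so the default keeps every
#' SNP as its own cluster; pass a larger `block_size` to group them.
#'
#' @param m number of SNPs.
#' @param block_size optional block size; blocks still carry identity
#'   correlation matrices.
#' @return An `ld_blocks` object with identity correlations.
#' @export
identity_ld <- function(m, block_size = 1L) {
  starts <- seq.int(1L, m, by = block_size)
  boundaries <- cbind(starts, pmin(starts + block_size - 1L, m))
  blocks <- lapply(seq_len(nrow(boundaries)),
                   function(b) boundaries[b, 1L]:boundaries[b, 2L])
  corr <- lapply(blocks, function(ix) diag(length(ix)))
  structure(list(blocks = blocks, corr = corr, n_ref = Inf,
                 adjust = FALSE, m = m, monomorphic = integer(0)),
            class = "ld_blocks")
}

#' @export
print.ld_blocks <- function(x, ...) {
  cat(sprintf("LD blocks: %d SNPs in %d block(s); reference n = %s; r2 adjustment %s\n",
              x$m, length(x$blocks),
              if (is.finite(x$n_ref)) x$n_ref else "none",
              if (x$adjust) "on" else "off"))
  invisible(x)
}

# Squared within-block correlations, optionally bias-adjusted toward the
# population value (adjustment clamped below at 0; diagonal kept at 1).
block_r2 <- function(ld, b) {
  r2 <- ld$corr[[b]]^2
  if (isTRUE(ld$adjust) && is.finite(ld$n_ref) && ld$n_ref > 2) {
    r2 <- r2 - (1 - r2) / (ld$n_ref - 2)
    r2[r2 < 0] <- 0
    diag(r2) <- 1
  }
  r2
}

#' Build the chi-square regression design matrix
#'
#' Under the annotation-dependent variance model the expected marginal
#' chi-square statistic of SNP `j` is
#' `E[chisq_j] = 1 + (n/m) * sum_l r2_jl * A_l' alpha*`, with the sum over
#' SNPs `l` in the LD block of `j`. This routine computes the design rows
#' `d_j = (n/m) * sum_l r2_jl * A_l` together with the LD scores
#' `l_j = sum_l r2_jl`.
#'
#' @param ld an [estimate_ld_blocks()] / [identity_ld()] object covering all
#'   `m` SNPs.
#' @param A a centered [annotation_matrix()] with `m` rows.
#' @param n GWAS sample size.
#' @param m number of SNPs (defaults to `nrow(A$values)`).
#' @return An object of class `design_matrix`: list with `D` (`m x (c+1)`),
#'   `ld_scores`, `n`, `m`, and the LD block structure.
#' @export
build_design <- function(ld, A, n, m = nrow(A$values)) {
  stopifnot(inherits(ld, "ld_blocks"), inherits(A, "annotation_matrix"))
  if (!A$centered) stop("annotation matrix must be centered before building the design")
  if (nrow(A$values) != ld$m) stop("annotation rows (", nrow(A$values),
                                   ") do not match LD structure (", ld$m, ")")
  V <- A$values
  D <- matrix(0, nrow = ld$m, ncol = ncol(V), dimnames = dimnames(V))
  ell <- numeric(ld$m)
  for (b in seq_along(ld$blocks)) {
    ix <- ld$blocks[[b]]
    r2 <- block_r2(ld, b)
    D[ix, ] <- r2 %*% V[ix, , drop = FALSE]
    ell[ix] <- rowSums(r2)
  }
  D <- (n / m) * D
  structure(list(D = D, ld_scores = ell, n = n, m = m, ld = ld),
            class = "design_matrix")
}
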