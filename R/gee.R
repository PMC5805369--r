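# GEE fit of the annotation-coefficient model to marginal chi-square
# statistics, with robust (sandwich) covariance clustered by LD block.

#' Construct a summary-statistics object
#'
#' @param snp_id character vector of SNP identifiers.
#' @param chisq per-SNP marginal chi-square statistics (squared z-scores).
#' @param n GWAS sample size (scalar).
#' @return Object of class `summary_stats`: data frame with columns `snp_id`
#'   and `chisq`, plus attributes `n` and `m`.
#' @export
summary_stats <- function(snp_id, chisq, n) {
  chisq <- as.numeric(chisq)
  if (any(!is.finite(chisq)) || any(chisq < 0)) {
    stop("chi-square statistics must be finite and nonnegative")
  }
  if (length(n) != 1L || n < 1) stop("'n' must be a single sample size >= 1")
  out <- data.frame(snp_id = as.character(snp_id), chisq = chisq,
                    stringsAsFactors = FALSE)
  attr(out, "n") <- as.numeric(n)
  attr(out, "m") <- nrow(out)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Convert z-scores to marginal chi-square statistics
#'
#' @param snp_id SNP identifiers.
#' @param z per-SNP marginal z-scores; SNPs with missing z are dropped with
#'   a message.
#' @param n GWAS sample size.
#' @return A [summary_stats()] object with `chisq = z^2`.
#' @export
chisq_from_z <- function(snp_id, z, n) {
  z <- as.numeric(z)
  keep <- is.finite(z)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " SNP(s) with missing z-scores")
  }
  summary_stats(snp_id[keep], z[keep]^2, n)
}

#' Precompute the GEE solve for repeated fits
#'
#' Factors the working covariance against the design once, so that many
#' response vectors (e.g. simulation replicates) can be fitted cheaply.
#'
#' @param design a [build_design()] object.
#' @param working working covariance of the chi-square statistics:
#'   `"independence"` (identity) or `"ld"` (within-block `V_jl = 2 r2_jl`,
#'   the null covariance of squared jointly normal scores).
#' @param columns optional integer subset of design columns (intercept must
#'   be included), used for univariate-annotation fits.
#' @return Object of class `gee_prep` holding `ViD = V^{-1} D`, the bread
#'   inverse `Bi = (D' V^{-1} D)^{-1}`, the block index list and labels.
#' @export
gee_prepare <- function(design, working = c("ld", "independence"),
                        columns = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  working <- match.arg(working)
  D <- design$D
  if (!is.null(columns)) {
    if (!(1L %in% columns)) stop("column subset must include the intercept column")
    D <- D[, columns, drop = FALSE]
  }
  p <- ncol(D)
  if (nrow(D) < p) stop("fewer SNPs than coefficients (", nrow(D), " < ", p, ")")
  ld <- design$ld
  if (working == "independence") {
    ViD <- D
  } else {
    ViD <- D
    for (b in seq_along(ld$blocks)) {
      ix <- ld$blocks[[b]]
      V <- 2 * block_r2(ld, b)
      ViD[ix, ] <- tryCatch(solve(V, D[ix, , drop = FALSE]),
                            error = function(e) {
                              solve(V + diag(1e-8 * 2, nrow(V)),
                                    D[ix, , drop = FALSE])
                            })
    }
  }
  B <- crossprod(D, ViD)
  Bi <- tryCatch(solve(B), error = function(e) {
    d <- svd(B, nu = 0L, nv = 0L)$d
    bad <- colnames(D)[d < 1e-12 * d[1L]]
    stop("singular GEE system; collinear design column(s): ",
         paste(if (length(bad)) bad else colnames(D), collapse = ", "),
         call. = FALSE)
  })
  structure(list(ViD = ViD, Bi = Bi, D = D, blocks = ld$blocks,
                 working = working, labels = colnames(D)),
            class = "gee_prep")
}

# Closed-form GEE solve for one response vector; returns coefficients,
# sandwich covariance and the Wald statistic over the annotation block.
gee_solve <- function(prep, s) {
  u0 <- s - 1
  alpha <- drop(prep$Bi %*% crossprod(prep$ViD, u0))
  resid <- u0 - drop(prep$D %*% alpha)
  p <- length(alpha)
  M <- matrix(0, p, p)
  for (ix in prep$blocks) {
    g <- crossprod(prep$ViD[ix, , drop = FALSE], resid[ix])
    M <- M + tcrossprod(g)
  }
  cov <- prep$Bi %*% M %*% prep$Bi
  names(alpha) <- prep$labels
  dimnames(cov) <- list(prep$labels, prep$labels)
  list(alpha = alpha, cov = cov, residuals = resid)
}

#' Fit the annotation-coefficient model by GEE
#'
#' Regresses `chisq - 1` on the LD-aggregated annotation design in closed
#' form, `alpha* = (D' V^{-1} D)^{-1} D' V^{-1} (s - 1)`, and computes a
#' robust sandwich covariance with LD blocks as independent clusters. The
#' fitted coefficients measure how strongly each annotation predicts SNP
#' effect-size variance; the intercept measures average per-SNP heritability.
#'
#' @param design a [build_design()] object (or a `gee_prep` from
#'   [gee_prepare()], in which case `working` is ignored).
#' @param stats a [summary_stats()] object or a bare numeric vector of
#'   chi-square statistics aligned with the design rows.
#' @param working `"ld"` (default) or `"independence"`; see [gee_prepare()].
#' @return Object of class `gee_fit` with elements `coefficients`
#'   (`alpha0` then annotation coefficients), `cov` (sandwich covariance),
#'   `wald`, `df` (number of annotation coefficients), `working`,
#'   `residuals` and `fitted`.
#' @export
gee_fit <- function(design, stats, working = c("ld", "independence")) {
  prep <- if (inherits(design, "gee_prep")) design
          else gee_prepare(design, match.arg(working))
  s <- if (inherits(stats, "summary_stats")) stats$chisq else as.numeric(stats)
  if (length(s) != nrow(prep$D)) stop("summary statistics (", length(s),
                                      ") do not match design rows (", nrow(prep$D), ")")
  sol <- gee_solve(prep, s)
  w <- wald_from(sol$alpha, sol$cov)
  structure(list(coefficients = sol$alpha, cov = sol$cov,
                 wald = w$wald, df = w$df, working = prep$working,
                 residuals = sol$residuals,
                 fitted = 1 + drop(prep$D %*% sol$alpha)),
            class = "gee_fit")
}

wald_from <- function(alpha, cov) {
  keep <- -1L  # drop the intercept; df = number of annotation coefficients
  a <- alpha[keep]
  Va <- cov[keep, keep, drop = FALSE]
  df <- length(a)
  W <- tryCatch(drop(crossprod(a, solve(Va, a))), error = function(e) NA_real_)
  if (!is.finite(W)) {
    # singular annotation sub-covariance: pseudo-inverse, reduced effective df
    e <- eigen(Va, symmetric = TRUE)
    pos <- e$values > 1e-12 * max(e$values, 0)
    if (!any(pos)) return(list(wald = 0, df = 0L))
    warning("singular Wald sub-covariance; using pseudo-inverse with effective df ",
            sum(pos))
    U <- e$vectors[, pos, drop = FALSE]
    W <- sum((crossprod(U, a))^2 / e$values[pos])
    df <- sum(pos)
  }
  list(wald = max(W, 0), df = as.integer(df))
}

#' Multivariate Wald statistic of a GEE fit
#'
#' `W = alpha' V(alpha)^{-1} alpha` over the annotation coefficients only
#' (intercept excluded); the degrees of freedom equal the number of
#' annotations fitted.
#'
#' @param fit a [gee_fit()] object.
#' @return List with `wald` and `df`.
#' @export
wald_statistic <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  list(wald = fit$wald, df = fit$df)
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE fit of annotation coefficients (working =", x$working, ")\n")
  se <- sqrt(diag(x$cov))
  print(round(cbind(estimate = x$coefficients, se = se), 6))
  cat(sprintf("Wald statistic: %.4f on %d df\n", x$wald, x$df))
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$cov

#' @export
residuals.gee_fit <- function(object, ...) object$residuals

#' @export
fitted.gee_fit <- function(object, ...) object$fitted

#' Per-tissue GEE fits and Wald statistics
#'
#' Fits the annotation-coefficient model once per tissue and returns the
#' per-tissue multivariate Wald statistics, in deterministic input order.
#' With `mode = "unimax"` each annotation is fitted separately (univariate)
#' and the larger Wald statistic is kept per tissue; with `mode = "uni"` all
#' (tissue, annotation) univariate statistics are returned.
#'
#' @param stats a [summary_stats()] object (or chi-square vector).
#' @param tissue_annotations named list of centered [annotation_matrix()]
#'   objects, one per tissue, sharing SNP order and annotation count.
#' @param ld an `ld_blocks` object.
#' @param n GWAS sample size (taken from `stats` when available).
#' @param working working covariance, see [gee_fit()].
#' @param mode `"joint"` (all annotations together), `"unimax"`, or `"uni"`.
#' @return List with `table` (data frame: tissue, annotation (uni mode),
#'   wald, df, and coefficient estimates with standard errors) and `fits`
#'   (list of `gee_fit` objects; for unimax, the winning univariate fit).
#'   Per-tissue failures are recorded as `NA` rows and the run continues.
#' @export
fit_all_tissues <- function(stats, tissue_annotations, ld, n = NULL,
                            working = c("ld", "independence"),
                            mode = c("joint", "unimax", "uni")) {
  working <- match.arg(working)
  mode <- match.arg(mode)
  if (is.null(n)) {
    if (!inherits(stats, "summary_stats")) stop("'n' required when 'stats' is a bare vector")
    n <- attr(stats, "n")
  }
  s <- if (inherits(stats, "summary_stats")) stats$chisq else as.numeric(stats)
  tissues <- names(tissue_annotations)
  if (is.null(tissues)) tissues <- paste0("tissue", seq_along(tissue_annotations))
  rows <- list(); fits <- list()
  for (t in seq_along(tissue_annotations)) {
    A <- tissue_annotations[[t]]
    res <- tryCatch({
      design <- build_design(ld, A, n = n, m = length(s))
      if (mode == "joint") {
        f <- gee_fit(design, s, working)
        list(rows = data.frame(tissue = tissues[t], annotation = NA_character_,
                               wald = f$wald, df = f$df,
                               stringsAsFactors = FALSE),
             fit = f)
      } else {
        c1 <- ncol(design$D)
        ufits <- lapply(2:c1, function(j) {
          gee_fit(gee_prepare(design, working, columns = c(1L, j)), s)
        })
        walds <- vapply(ufits, function(f) f$wald, 0)
        if (mode == "unimax") {
          k <- which.max(walds)
          list(rows = data.frame(tissue = tissues[t],
                                 annotation = A$labels[k],
                                 wald = walds[k], df = 1L,
                                 stringsAsFactors = FALSE),
               fit = ufits[[k]])
        } else {
          list(rows = data.frame(tissue = tissues[t], annotation = A$labels,
                                 wald = walds, df = 1L,
                                 stringsAsFactors = FALSE),
               fit = ufits)
        }
      }
    }, error = function(e) {
      warning("tissue ", tissues[t], " failed: ", conditionMessage(e))
      list(rows = data.frame(tissue = tissues[t], annotation = NA_character_,
                             wald = NA_real_, df = NA_integer_,
                             stringsAsFactors = FALSE),
           fit = NULL)
    })
    rows[[t]] <- res$rows
    fits[[tissues[t]]] <- res$fit
  }
  list(table = do.call(rbind, rows), fits = fits)
}
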