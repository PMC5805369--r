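# Main user-facing model fit: per-tissue GEE fits of the annotation
# coefficient model, mixture classification of the resulting Wald
# statistics, and downstream SNP-weight prediction.

#' Identify trait-relevant tissues from summary statistics
#'
#' The central fitting function. For each candidate tissue the per-SNP
#' effect-size variance is modelled as a linear function of that tissue's
#' annotations, `sigma2_j = alpha0 + C_j' alpha`, and the coefficients are
#' estimated from the marginal chi-square statistics by generalized
#' estimating equations with a block-diagonal LD structure. The per-tissue
#' multivariate Wald statistics `alpha' V(alpha)^{-1} alpha` are then
#' classified with a two-component noncentral chi-square mixture; the
#' posterior probability of the high-noncentrality component measures
#' trait-tissue relevance.
#'
#' @param stats a [summary_stats()] object (e.g. from [read_sumstats()] or
#'   [chisq_from_z()]).
#' @param annotations named list of per-tissue [annotation_matrix()]
#'   objects (uncentered ones are centered internally), all sharing SNP
#'   order and annotation count.
#' @param ld an `ld_blocks` object from [estimate_ld_blocks()], or `NULL`
#'   for the no-LD approximation ([identity_ld()]).
#' @param working GEE working covariance, `"ld"` or `"independence"`.
#' @param mode `"joint"` fits all annotations together (one Wald statistic
#'   per tissue); `"unimax"` fits one annotation at a time and keeps the
#'   larger statistic per tissue; `"uni"` classifies every
#'   (tissue, annotation) statistic.
#' @param standardize also scale annotation columns to unit SD before
#'   fitting.
#' @param threshold posterior-probability cutoff for calling tissues
#'   trait-relevant.
#' @return Object of class `tissue_scan`: list with `tissues` (data frame:
#'   tissue, annotation, wald, df, pp, relevant), `fits` (per-tissue
#'   [gee_fit()] objects), `mixture` (the [chisq_mixture()] fit), `top`
#'   (the argmax tissue, always reported), `annotations` (the centered
#'   annotation matrices, whose centering statistics are reused by
#'   [predict.tissue_scan()]), `mode` and `working`.
#' @examples
#' set.seed(7)
#' X <- simulate_genotypes(500, 400, ld = "ar1", block_size = 50)
#' annos <- simulate_tissue_annotations(400, n_tissues = 6)
#' A1 <- center_annotations(annos[[1]])
#' sim <- simulate_effects_phenotype(scale(X), A1, c(0.3, 0.5, 0.5), 0.7)
#' scan <- marginal_scan(X, sim$y)
#' fit <- tissue_scan(summary_stats(paste0("rs", 1:400), scan$chisq, 500),
#'                    annos, ld = NULL)
#' print(fit)
#' @export
tissue_scan <- function(stats, annotations, ld = NULL,
                        working = c("ld", "independence"),
                        mode = c("joint", "unimax", "uni"),
                        standardize = FALSE, threshold = 0.5) {
  working <- match.arg(working)
  mode <- match.arg(mode)
  s <- if (inherits(stats, "summary_stats")) stats$chisq else as.numeric(stats)
  if (is.null(ld)) ld <- identity_ld(length(s))
  annotations <- lapply(annotations, function(A) {
    if (!inherits(A, "annotation_matrix")) A <- annotation_matrix(A)
    A
  })
  # the identifiability requirement concerns the raw annotation coding:
  # after centering, a genome partition shows up as collinearity instead
  idc <- lapply(annotations, check_identifiability)
  bad <- !vapply(idc, `[[`, TRUE, "ok")
  if (any(bad)) {
    stop("annotations not identifiable against the intercept for tissue(s): ",
         paste(names(annotations)[bad], collapse = ", "))
  }
  annotations <- lapply(annotations, function(A) {
    if (!A$centered) A <- center_annotations(A, standardize = standardize)
    A
  })
  ft <- fit_all_tissues(stats, annotations, ld,
                        n = attr(stats, "n"), working = working, mode = mode)
  tab <- ft$table
  ok <- is.finite(tab$wald)
  df <- if (mode == "joint") length(annotations[[1L]]$labels) else 1L
  mix <- chisq_mixture(tab$wald[ok], df = df)
  tab$pp <- NA_real_
  tab$pp[ok] <- mix$pp
  tab$relevant <- tab$pp > threshold
  top <- tab$tissue[which.max(tab$pp)]
  structure(list(tissues = tab, fits = ft$fits, mixture = mix, top = top,
                 annotations = annotations, mode = mode, working = working,
                 threshold = threshold),
            class = "tissue_scan")
}

#' @export
print.tissue_scan <- function(x, ...) {
  cat(sprintf("Trait-relevant tissue scan (%s annotations, working = %s)\n",
              x$mode, x$working))
  tab <- x$tissues
  tab$wald <- round(tab$wald, 3)
  tab$pp <- round(tab$pp, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("Top tissue: %s; %d tissue(s) with PP > %.2f\n",
              x$top, sum(tab$relevant, na.rm = TRUE), x$threshold))
  invisible(x)
}

#' @export
summary.tissue_scan <- function(object, ...) {
  cat("Mixture fit over per-tissue Wald statistics:\n")
  print(object$mixture)
  cat("\n")
  print(object)
  top_fit <- object$fits[[object$top]]
  if (!is.null(top_fit) && inherits(top_fit, "gee_fit")) {
    cat("\nCoefficients of the top tissue:\n")
    print(top_fit)
  }
  invisible(object)
}

#' Annotation coefficient estimates per tissue
#'
#' @param object a [tissue_scan()] fit.
#' @param ... unused.
#' @return Matrix of coefficient estimates, tissues in rows (joint mode);
#'   for univariate modes a data frame of per-fit coefficients.
#' @export
coef.tissue_scan <- function(object, ...) {
  if (object$mode == "joint") {
    do.call(rbind, lapply(object$fits, function(f) {
      if (is.null(f)) rep(NA_real_, 1L + length(object$annotations[[1L]]$labels))
      else stats::coef(f)
    }))
  } else {
    object$tissues
  }
}

#' Posterior probabilities and relevance plot
#'
#' Barplot of the per-tissue posterior probabilities of trait relevance,
#' with the classification threshold drawn as a horizontal line.
#'
#' @param x a [tissue_scan()] fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.tissue_scan <- function(x, ...) {
  tab <- x$tissues[!duplicated(x$tissues$tissue), ]
  graphics::barplot(tab$pp, names.arg = tab$tissue, las = 2,
                    ylab = "posterior probability", ylim = c(0, 1), ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Predict SNP variances or weights from a tissue scan
#'
#' Applies the fitted coefficients of a tissue (by default the top
#' trait-relevant tissue) to new raw annotation values, reusing the
#' centering statistics of the fitting cohort, and optionally transforms
#' the variances into strictly positive SNP weights shrunk towards equal
#' weights by the tissue's posterior probability.
#'
#' @param object a [tissue_scan()] fit (joint mode).
#' @param newdata raw annotation values (SNPs x annotations) for the SNPs
#'   to weight; defaults to the fitting SNPs.
#' @param tissue tissue whose coefficients to use; defaults to the top
#'   tissue.
#' @param type `"variance"` for `sigma2_j`, `"weights"` for SKAT-ready
#'   weights.
#' @param ... unused.
#' @return Numeric vector (`type = "variance"`) or a [construct_weights()]
#'   object.
#' @export
predict.tissue_scan <- function(object, newdata = NULL, tissue = NULL,
                                type = c("variance", "weights"), ...) {
  type <- match.arg(type)
  if (object$mode != "joint") stop("prediction requires a joint-mode fit")
  if (is.null(tissue)) tissue <- object$top
  fit <- object$fits[[tissue]]
  if (is.null(fit)) stop("no fit available for tissue ", tissue)
  A <- object$annotations[[tissue]]
  sigma2 <- if (is.null(newdata)) {
    drop(A$values %*% stats::coef(fit))
  } else {
    snp_variances(newdata, stats::coef(fit), centering = A)
  }
  if (type == "variance") return(sigma2)
  pp <- object$tissues$pp[match(tissue, object$tissues$tissue)]
  construct_weights(sigma2, pp = pp)
}

#' Gene-set association tests weighted by a tissue scan
#'
#' Convenience wrapper running the weighted SNP-set test over a list of
#' gene sets with weights derived from the top trait-relevant tissue.
#'
#' @param gene_sets list from [assemble_gene_sets()].
#' @param genotypes test-cohort genotype matrix (individuals x SNPs,
#'   columns aligned with the SNP table used for assembly).
#' @param weights per-SNP weights aligned with the genotype columns
#'   (e.g. from [predict.tissue_scan()] with `type = "weights"`), or `NULL`
#'   for equal weights.
#' @param null a [skat_null_model()].
#' @return Data frame with one row per gene: `gene_id`, `chrom`, `n_snps`,
#'   `Q`, `pvalue`. The Bonferroni threshold `0.05 / n_genes` is reported
#'   via `message()`.
#' @export
gene_set_scan <- function(gene_sets, genotypes, weights = NULL, null) {
  if (is.null(weights)) weights <- rep(1, ncol(genotypes))
  w <- if (inherits(weights, "snp_weights")) weights$weights else weights
  rows <- lapply(gene_sets, function(gs) {
    res <- skat_test(genotypes[, gs$snp_indices, drop = FALSE],
                     w[gs$snp_indices], null, gene_id = gs$gene_id)
    data.frame(gene_id = gs$gene_id, chrom = gs$chrom,
               n_snps = res$n_snps, Q = res$Q, pvalue = res$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  message("Bonferroni threshold at 0.05 family-wise error: ",
          signif(0.05 / nrow(out), 3))
  out
}
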