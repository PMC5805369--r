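# Per-SNP annotation matrices: construction from peak tracks or tables,
# group averaging, centering/standardization, identifiability checks.

#' Construct a per-SNP annotation matrix
#'
#' Assembles an `m x (c+1)` annotation matrix whose first column is an
#' intercept of ones and whose remaining columns hold per-SNP annotation
#' values (binary occupancy indicators, group-averaged occupancies, chromatin
#' state posteriors, or any other discrete/continuous SNP-level covariate).
#'
#' @param C numeric matrix or data frame with `m` rows and `c` annotation
#'   columns (no intercept), or a numeric vector for a single annotation.
#' @param labels optional character vector of `c` annotation names; defaults
#'   to the column names of `C`.
#' @param tissue optional tissue label carried along for bookkeeping.
#' @return An object of class `annotation_matrix`: a list with elements
#'   `values` (the `m x (c+1)` matrix, intercept first), `labels`, `tissue`,
#'   `centered` (logical), and `center`/`scale` (the statistics applied by
#'   [center_annotations()], `NULL` until centering).
#' @seealso [center_annotations()], [check_identifiability()]
#' @export
annotation_matrix <- function(C, labels = NULL, tissue = NA_character_) {
  if (is.data.frame(C)) C <- as.matrix(C)
  if (is.null(dim(C))) C <- matrix(C, ncol = 1L)
  storage.mode(C) <- "double"
  if (anyNA(C)) stop("annotation values must not contain NA")
  if (is.null(labels)) {
    labels <- colnames(C)
    if (is.null(labels)) labels <- paste0("anno", seq_len(ncol(C)))
  }
  if (length(labels) != ncol(C)) stop("'labels' must name every annotation column")
  values <- cbind(intercept = 1, C)
  colnames(values) <- c("intercept", labels)
  structure(
    list(values = values, labels = labels, tissue = tissue,
         centered = FALSE, center = NULL, scale = NULL),
    class = "annotation_matrix"
  )
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("Annotation matrix: %d SNPs x %d annotation(s)%s%s\n",
              nrow(x$values), length(x$labels),
              if (x$centered) ", centered" else "",
              if (!is.na(x$tissue)) paste0(" [", x$tissue, "]") else ""))
  cat("  annotations:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.annotation_matrix <- function(x) dim(x$values)

#' Binary SNP/peak overlap annotation
#'
#' Marks each SNP with 1 if its position falls inside any peak interval and 0
#' otherwise. Peaks use 0-based half-open coordinates (the BED/broadPeak
#' convention); SNP positions are 1-based (the VCF convention). A SNP at
#' 1-based position `p` overlaps the interval `[start, end)` iff
#' `start <= p - 1 < end`.
#'
#' @param snps data frame with columns `snp_id`, `chrom`, `pos` (1-based).
#' @param peaks a `peak_track` from [read_broadpeak()], or a data frame with
#'   columns `chrom`, `start`, `end` in 0-based half-open coordinates.
#' @return Integer vector of length `nrow(snps)` with entries in `{0, 1}`,
#'   named by `snp_id`. SNPs on chromosomes absent from the peak track get 0,
#'   with a warning naming the unmatched chromosomes.
#' @export
binarize_overlap <- function(snps, peaks) {
  snps <- validate_snp_table(snps)
  iv <- peak_intervals(peaks)
  out <- integer(nrow(snps))
  names(out) <- snps$snp_id
  if (nrow(iv) == 0L) return(out)
  missing_chr <- setdiff(unique(snps$chrom), unique(iv$chrom))
  if (length(missing_chr) > 0L) {
    warning("no peaks on chromosome(s) ", paste(missing_chr, collapse = ", "),
            "; their SNPs are annotated 0")
  }
  # BED [start, end) -> 1-based closed [start+1, end]; SNP pos p overlaps iff
  # start+1 <= p <= end, i.e. start <= p-1 < end.
  pk <- GenomicRanges::GRanges(iv$chrom,
                               IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  sn <- GenomicRanges::GRanges(snps$chrom,
                               IRanges::IRanges(start = snps$pos, width = 1L))
  # suppress the seqlevel-mismatch chatter; unmatched chromosomes were
  # already reported above
  hits <- suppressWarnings(GenomicRanges::countOverlaps(sn, pk))
  out[] <- as.integer(hits > 0L)
  out
}

#' Average annotation columns across tissues
#'
#' Element-wise arithmetic mean of per-SNP annotation vectors, used to build
#' tissue-group level continuous annotations from per-tissue binary occupancy
#' indicators, or to average chromatin-state posterior probabilities across
#' the tissues of a group.
#'
#' @param columns a list of equal-length numeric vectors, or a matrix whose
#'   columns are the per-tissue vectors.
#' @return Numeric vector of element-wise means.
#' @export
group_average <- function(columns) {
  if (is.matrix(columns) || is.data.frame(columns)) {
    columns <- lapply(seq_len(ncol(columns)), function(j) as.numeric(columns[, j]))
  }
  if (!is.list(columns) || length(columns) == 0L) {
    stop("'columns' must be a non-empty list of vectors (or a matrix)")
  }
  len <- lengths(columns)
  if (length(unique(len)) != 1L) stop("all columns must have equal length")
  Reduce(`+`, lapply(columns, as.numeric)) / length(columns)
}

#' Center (optionally standardize) annotation columns
#'
#' Centers the annotation columns (all but the intercept) to mean zero across
#' SNPs, so that the variance intercept retains its SNP-heritability
#' interpretation. With `standardize = TRUE` columns are additionally scaled
#' to unit standard deviation.
#'
#' @param A an [annotation_matrix()] that has not been centered yet.
#' @param standardize logical; also scale annotation columns to unit SD.
#' @return The centered `annotation_matrix`, with `center` (and `scale`)
#'   recording the statistics applied so they can be reused on new SNP sets
#'   (e.g. when computing SNP weights in a testing cohort).
#' @export
center_annotations <- function(A, standardize = FALSE) {
  stopifnot(inherits(A, "annotation_matrix"))
  if (A$centered) stop("annotation matrix is already centered")
  V <- A$values
  cols <- seq_len(ncol(V))[-1L]
  mu <- colMeans(V[, cols, drop = FALSE])
  V[, cols] <- sweep(V[, cols, drop = FALSE], 2L, mu, `-`)
  sds <- apply(V[, cols, drop = FALSE], 2L, stats::sd)
  if (standardize) {
    if (any(sds == 0)) {
      stop("constant annotation column(s) cannot be standardized: ",
           paste(A$labels[sds == 0], collapse = ", "))
    }
    V[, cols] <- sweep(V[, cols, drop = FALSE], 2L, sds, `/`)
    A$scale <- sds
  } else if (any(sds == 0)) {
    warning("constant annotation column(s): ",
            paste(A$labels[sds == 0], collapse = ", "))
  }
  A$values <- V
  A$center <- mu
  A$centered <- TRUE
  A
}

#' Apply stored centering statistics to new annotation rows
#'
#' @param A a centered [annotation_matrix()] whose `center`/`scale` are to be
#'   reused.
#' @param C numeric matrix (or vector) of raw annotation values for new SNPs,
#'   columns matching `A$labels`.
#' @return Numeric matrix with intercept column, centered (and scaled) with
#'   the statistics stored in `A`.
#' @export
apply_centering <- function(A, C) {
  stopifnot(inherits(A, "annotation_matrix"), A$centered)
  if (is.null(dim(C))) C <- matrix(C, ncol = length(A$labels))
  if (ncol(C) != length(A$labels)) stop("annotation column mismatch")
  C <- sweep(C, 2L, A$center, `-`)
  if (!is.null(A$scale)) C <- sweep(C, 2L, A$scale, `/`)
  out <- cbind(intercept = 1, C)
  colnames(out) <- c("intercept", A$labels)
  out
}

#' Check annotation identifiability against the intercept
#'
#' The model carries an explicit variance intercept, so no linear combination
#' of the annotation columns may reproduce the vector of ones across SNPs
#' (e.g. two complementary indicators partitioning the genome are not
#' identifiable; drop one cell to obtain reference coding). The check
#' compares the numerical rank of `[1 | C]` with `rank(C) + 1`.
#'
#' @param A an [annotation_matrix()].
#' @param tol relative singular-value tolerance for the numerical rank.
#' @return A list with `ok` (logical), and when `ok` is `FALSE` a `witness`
#'   vector of combination coefficients `b` such that `C b` is (numerically)
#'   the vector of ones.
#' @export
check_identifiability <- function(A, tol = 1e-8) {
  stopifnot(inherits(A, "annotation_matrix"))
  V <- A$values
  C <- V[, -1L, drop = FALSE]
  full_rank <- num_rank(V, tol)
  c_rank <- num_rank(C, tol)
  ok <- full_rank == c_rank + 1L
  res <- list(ok = ok, witness = NULL)
  if (!ok) {
    ones <- rep(1, nrow(C))
    b <- tryCatch(stats::lsfit(C, ones, intercept = FALSE)$coefficients,
                  error = function(e) rep(NA_real_, ncol(C)))
    names(b) <- A$labels
    res$witness <- b
  }
  res
}

num_rank <- function(M, tol) {
  d <- svd(M, nu = 0L, nv = 0L)$d
  if (length(d) == 0L || d[1L] == 0) return(0L)
  sum(d > tol * d[1L])
}

validate_snp_table <- function(snps) {
  snps <- as.data.frame(snps)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(snps))) {
    stop("SNP table must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id in SNP table")
  if (any(snps$pos < 1)) stop("SNP positions must be 1-based (>= 1)")
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  ord <- order(snps$chrom, snps$pos)
  if (is.unsorted(ord)) snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  snps
}

peak_intervals <- function(peaks) {
  if (inherits(peaks, "peak_track")) return(peaks$intervals)
  pk <- as.data.frame(peaks)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(pk))) {
    stop("peak input must have columns ", paste(need, collapse = ", "))
  }
  if (any(pk$start >= pk$end)) stop("peak intervals must satisfy start < end")
  pk[need]
}
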