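# Readers and writers for the standard text formats, plus SNP-level quality
# control (missingness, MAF, Hardy-Weinberg, MHC exclusion).

#' Read a GWAS summary-statistics table
#'
#' Expects a tab-separated file with a header containing columns `SNP`,
#' `CHR`, `BP`, `N`, and `Z` and/or `CHISQ`. When both `Z` and `CHISQ` are
#' present, `Z` takes precedence and `CHISQ` is recomputed; disagreements
#' larger than 1e-6 are reported.
#'
#' @param path file path (plain or gzipped TSV).
#' @return A [summary_stats()] object with extra columns `chrom` and `pos`.
#' @export
read_sumstats <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("SNP", "CHR", "BP", "N")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("summary statistics missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!any(c("Z", "CHISQ") %in% names(tab))) {
    stop("summary statistics need a Z or CHISQ column")
  }
  if (anyDuplicated(tab$SNP)) {
    stop("duplicate SNP id at line ",
         which(duplicated(tab$SNP))[1L] + 1L)
  }
  if ("Z" %in% names(tab)) {
    z <- as.numeric(tab$Z)
    chisq <- z^2
    if ("CHISQ" %in% names(tab)) {
      diff <- abs(chisq - as.numeric(tab$CHISQ))
      nbad <- sum(diff > 1e-6, na.rm = TRUE)
      if (nbad > 0) message(nbad, " SNP(s) with CHISQ inconsistent with Z^2; Z used")
    }
  } else {
    chisq <- as.numeric(tab$CHISQ)
  }
  if (anyNA(chisq)) {
    stop("non-numeric association statistic at line ", which(is.na(chisq))[1L] + 1L)
  }
  n <- stats::median(as.numeric(tab$N))
  out <- summary_stats(tab$SNP, chisq, n)
  out$chrom <- as.character(tab$CHR)
  out$pos <- as.integer(tab$BP)
  out
}

#' Read a per-SNP annotation table
#'
#' TSV with header `snp_id` followed by one column per annotation; one row
#' per SNP.
#'
#' @param path file path.
#' @param tissue optional tissue label.
#' @return An uncentered [annotation_matrix()]; SNP ids are kept as row
#'   names of `$values`.
#' @export
read_annotation_table <- function(path, tissue = NA_character_) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1L] != "snp_id") stop("first column must be 'snp_id'")
  if (ncol(tab) < 2L) stop("annotation table has no annotation columns")
  if (anyDuplicated(tab$snp_id)) {
    stop("duplicate snp_id at line ", which(duplicated(tab$snp_id))[1L] + 1L)
  }
  C <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(C)) {
    bad <- which(!vapply(tab[-1L], is.numeric, TRUE))[1L]
    stop("non-numeric annotation column: ", names(tab)[-1L][bad])
  }
  A <- annotation_matrix(C, labels = names(tab)[-1L], tissue = tissue)
  rownames(A$values) <- tab$snp_id
  A
}

#' Read a broadPeak/BED peak track
#'
#' Only the first three columns (chrom, start, end; 0-based half-open) are
#' used; gzipped files are accepted; overlapping intervals are merged.
#'
#' @param path file path.
#' @param tissue,mark optional labels.
#' @return Object of class `peak_track`: list with `intervals` (data frame
#'   chrom/start/end, merged), `tissue`, `mark`.
#' @export
read_broadpeak <- function(path, tissue = NA_character_, mark = NA_character_) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("peak file needs at least chrom/start/end columns")
  iv <- data.frame(chrom = as.character(tab[[1L]]),
                   start = as.integer(tab[[2L]]),
                   end = as.integer(tab[[3L]]),
                   stringsAsFactors = FALSE)
  if (any(iv$start >= iv$end)) {
    stop("invalid interval (start >= end) at line ",
         which(iv$start >= iv$end)[1L])
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(start = iv$start + 1L, end = iv$end)))
  merged <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr) - 1L,
                       end = GenomicRanges::end(gr),
                       stringsAsFactors = FALSE)
  structure(list(intervals = merged, tissue = tissue, mark = mark),
            class = "peak_track")
}

#' @export
print.peak_track <- function(x, ...) {
  cat(sprintf("Peak track: %d merged interval(s)%s%s\n", nrow(x$intervals),
              if (!is.na(x$tissue)) paste0(" tissue=", x$tissue) else "",
              if (!is.na(x$mark)) paste0(" mark=", x$mark) else ""))
  invisible(x)
}

#' Read a genotype matrix
#'
#' Plain TSV (individuals in rows, SNPs in columns, header of SNP ids,
#' optional first column of sample ids) or a VCF (GT field converted to
#' dosage of the alternate allele; multi-allelic records are skipped with a
#' warning; requires the `vcfR` package).
#'
#' @param path file path; format chosen by extension (`.vcf`/`.vcf.gz` vs
#'   anything else).
#' @return Numeric matrix, individuals x SNPs, with SNP ids as column names
#'   and (when available) sample ids as row names. For VCF input, SNP
#'   positions are attached as attributes `"chrom"` and `"pos"`.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the 'vcfR' package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- vcfR::getALT(v)
    multi <- grepl(",", alt)
    if (any(multi)) {
      warning("skipping ", sum(multi), " multi-allelic record(s)")
      v <- v[!multi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.numeric(strsplit(g, "[/|]")[[1L]]) > 0)
    })
    G <- t(dos)
    attr(G, "chrom") <- as.character(vcfR::getCHROM(v))
    attr(G, "pos") <- as.integer(vcfR::getPOS(v))
    return(G)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.numeric(tab[[1L]])) {
    ids <- tab[[1L]]
    tab <- tab[, -1L, drop = FALSE]
  } else ids <- NULL
  G <- as.matrix(tab)
  if (!is.numeric(G)) stop("non-numeric genotype values in ", path)
  if (!is.null(ids)) rownames(G) <- ids
  G
}

#' Read a gene coordinate table
#'
#' TSV with header `gene_id`, `chrom`, `start`, `end` and optional `strand`.
#'
#' @param path file path.
#' @return Data frame of gene coordinates (1-based inclusive).
#' @export
read_genes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab
}

#' Write a table as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality-control configuration
#'
#' @param max_missing maximum per-SNP missingness.
#' @param min_maf minimum minor allele frequency.
#' @param min_hwe_p minimum Hardy-Weinberg exact-test p-value.
#' @param exclude_mhc drop SNPs in the MHC region (chr6, 25-34 Mb,
#'   inclusive on both ends).
#' @return List of class `qc_config`.
#' @export
qc_config <- function(max_missing = 0.05, min_maf = 0.05,
                      min_hwe_p = 1e-4, exclude_mhc = TRUE) {
  stopifnot(max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 0.5,
            min_hwe_p >= 0, min_hwe_p <= 1)
  structure(list(max_missing = max_missing, min_maf = min_maf,
                 min_hwe_p = min_hwe_p, exclude_mhc = exclude_mhc),
            class = "qc_config")
}

#' SNP quality control
#'
#' Applies, in fixed order, filters on missingness, minor allele frequency,
#' Hardy-Weinberg equilibrium (exact test on observed genotype counts) and
#' MHC membership (chr6:25,000,000-34,000,000, bounds inclusive). Each
#' removed SNP is attributed to the first rule it fails.
#'
#' @param genotypes numeric matrix (individuals x SNPs), dosages 0/1/2 with
#'   `NA` for missing.
#' @param snps SNP table (`snp_id`, `chrom`, `pos`) aligned with the
#'   genotype columns; optional when `exclude_mhc` is off.
#' @param cfg a [qc_config()].
#' @return List with `keep` (logical vector), `genotypes` and `snps`
#'   (filtered), and `report` (counts removed per rule; counts sum to
#'   input minus survivors).
#' @export
qc_filter <- function(genotypes, snps = NULL, cfg = qc_config()) {
  G <- as.matrix(genotypes)
  m <- ncol(G)
  if (!is.null(snps)) {
    snps <- as.data.frame(snps)
    if (nrow(snps) != m) stop("SNP table rows must match genotype columns")
  } else if (cfg$exclude_mhc) {
    stop("MHC exclusion requires a SNP table with chrom/pos")
  }
  fail <- rep(NA_character_, m)
  missingness <- colMeans(is.na(G))
  fail[is.na(fail) & missingness > cfg$max_missing] <- "missingness"
  freq <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  fail[is.na(fail) & (is.na(maf) | maf < cfg$min_maf)] <- "maf"
  hwe_p <- vapply(seq_len(m), function(j) {
    if (!is.na(fail[j])) return(1)  # already removed by an earlier rule
    g <- G[, j]
    hwe_exact_p(sum(g == 1, na.rm = TRUE),
                sum(g == 0, na.rm = TRUE),
                sum(g == 2, na.rm = TRUE))
  }, 0)
  fail[is.na(fail) & hwe_p < cfg$min_hwe_p] <- "hwe"
  if (cfg$exclude_mhc) {
    chrom <- sub("^chr", "", as.character(snps$chrom))
    in_mhc <- chrom == "6" & snps$pos >= 25e6 & snps$pos <= 34e6
    fail[is.na(fail) & in_mhc] <- "mhc"
  }
  keep <- is.na(fail)
  if (!any(keep)) warning("no SNPs survive quality control")
  report <- c(input = m,
              missingness = sum(fail == "missingness", na.rm = TRUE),
              maf = sum(fail == "maf", na.rm = TRUE),
              hwe = sum(fail == "hwe", na.rm = TRUE),
              mhc = sum(fail == "mhc", na.rm = TRUE),
              survivors = sum(keep))
  list(keep = keep,
       genotypes = G[, keep, drop = FALSE],
       snps = if (!is.null(snps)) snps[keep, , drop = FALSE],
       report = report)
}

#' Hardy-Weinberg exact test
#'
#' Exact (conditional on allele counts) two-sided p-value for deviation
#' from Hardy-Weinberg proportions, computed by enumerating heterozygote
#' counts and summing probabilities not exceeding that of the observed
#' configuration.
#'
#' @param n_het,n_hom_ref,n_hom_alt observed genotype counts.
#' @return The exact p-value (1 for monomorphic SNPs).
#' @export
hwe_exact_p <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  if (n == 0L) return(1)
  n_rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0L) return(1)
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  # log-probability of each heterozygote count given allele counts
  lp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) %/% 2L
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) -
      lgamma(2 * n + 1)
  }, 0)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  if (is.na(obs)) return(0)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}
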