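# End-to-end simulation designs: (1) power to identify the trait-relevant
# tissue with joint vs univariate annotation modelling; (2) power of
# annotation-weighted SNP-set tests built from training-cohort fits.

#' Configuration for the tissue-identification simulation design
#'
#' Defaults follow the study conditions of the scaled design: 2,000
#' individuals and 2,000 SNPs with block-wise LD, ten candidate tissues with
#' two correlated binary annotations each, a variance intercept of 0.1 and
#' residual variance 0.9 (implied SNP heritability 0.1), and a simulated
#' reference panel of 500 individuals for LD estimation.
#'
#' @param n,m GWAS sample size and SNP count.
#' @param n_ref reference-panel size for LD estimation.
#' @param n_tissues number of candidate tissues.
#' @param occupancy per-mark annotation occupancies.
#' @param cross_tissue_corr cross-tissue annotation correlation.
#' @param alpha0 variance intercept.
#' @param sigma_e2 residual variance.
#' @param rho,geno_block AR(1) copula correlation and LD block size for the
#'   simulated genotypes.
#' @param ld_block_size SNP count per block in the block-diagonal LD
#'   approximation used for fitting.
#' @param working GEE working covariance.
#' @return A list of class `design1_config`.
#' @export
design1_config <- function(n = 2000L, m = 2000L, n_ref = 500L,
                           n_tissues = 10L, occupancy = c(0.18, 0.11),
                           cross_tissue_corr = 0.7,
                           alpha0 = 0.1, sigma_e2 = 0.9,
                           rho = 0.5, geno_block = 100L,
                           ld_block_size = 100L,
                           working = c("ld", "independence")) {
  structure(list(n = n, m = m, n_ref = n_ref, n_tissues = n_tissues,
                 occupancy = occupancy, cross_tissue_corr = cross_tissue_corr,
                 alpha0 = alpha0, sigma_e2 = sigma_e2, rho = rho,
                 geno_block = geno_block, ld_block_size = ld_block_size,
                 working = match.arg(working)),
            class = "design1_config")
}

#' The annotation-coefficient grid of the tissue-identification design
#'
#' @param values coefficient values over which each of the two annotation
#'   coefficients varies.
#' @param both_nonzero keep only settings where both coefficients are
#'   nonzero.
#' @return Two-column matrix of `(alpha1, alpha2)` settings.
#' @export
design1_grid <- function(values = c(-0.1, 0, 0.05, 0.1, 0.25, 0.5),
                         both_nonzero = FALSE) {
  g <- as.matrix(expand.grid(alpha1 = values, alpha2 = values))
  if (both_nonzero) g <- g[g[, 1] != 0 & g[, 2] != 0, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Run the tissue-identification simulation design
#'
#' Simulates genotypes, a reference panel and correlated tissue annotations
#' once; then, for every `(alpha1, alpha2)` setting and replicate, draws a
#' trait-relevant tissue, effect sizes and phenotype, computes the marginal
#' chi-square scan, fits the annotation model per tissue (jointly and/or one
#' annotation at a time), classifies tissues with the noncentral chi-square
#' mixture, and evaluates power to detect the trait-relevant tissue at the
#' requested FDR levels.
#'
#' @param config a [design1_config()].
#' @param alphas matrix of `(alpha1, alpha2)` settings (rows); defaults to
#'   the full 36-setting grid.
#' @param n_reps replicates per setting.
#' @param methods subset of `"smart"` (joint), `"unimax"`, `"uni"`.
#' @param fdr_levels FDR levels for the power evaluation.
#' @param seed master seed; all randomness flows from it.
#' @return List with `power` (data frame: alpha1, alpha2, method,
#'   fdr_level, power), `estimates` (data frame of per-replicate joint-fit
#'   coefficient estimates for the true tissue), and `pp` (per-setting,
#'   per-method posterior-probability arrays with the truth vector).
#' @export
run_design1 <- function(config = design1_config(),
                        alphas = design1_grid(),
                        n_reps = 100L,
                        methods = c("smart", "unimax"),
                        fdr_levels = c(0.05, 0.1, 0.2),
                        seed = 1L) {
  methods <- match.arg(methods, c("smart", "unimax", "uni"), several.ok = TRUE)
  set.seed(seed)
  cf <- config
  X <- simulate_genotypes(cf$n, cf$m, ld = "ar1", rho = cf$rho,
                          block_size = cf$geno_block)
  Xref <- simulate_genotypes(cf$n_ref, cf$m, ld = "ar1", rho = cf$rho,
                             block_size = cf$geno_block,
                             maf = attr(X, "maf"))
  X <- scale(X)
  bad <- !is.finite(colSums(X))
  if (any(bad)) X[, bad] <- 0  # monomorphic draws carry no signal
  annos <- simulate_tissue_annotations(cf$m, cf$n_tissues, cf$occupancy,
                                       cf$cross_tissue_corr)
  annos <- lapply(annos, center_annotations)
  ld <- estimate_ld_blocks(Xref, block_size = cf$ld_block_size)
  preps <- lapply(annos, function(A) {
    design <- build_design(ld, A, n = cf$n, m = cf$m)
    list(joint = gee_prepare(design, cf$working),
         uni = lapply(seq_along(A$labels) + 1L, function(j) {
           gee_prepare(design, cf$working, columns = c(1L, j))
         }))
  })
  n_t <- cf$n_tissues
  c_anno <- length(cf$occupancy)
  power_rows <- list()
  est_rows <- list()
  pp_out <- list()
  for (a in seq_len(nrow(alphas))) {
    alpha_star <- c(cf$alpha0, alphas[a, 1], alphas[a, 2])
    truth <- integer(n_reps)
    pp_arr <- lapply(methods, function(mm) matrix(NA_real_, n_reps, n_t))
    names(pp_arr) <- methods
    for (r in seq_len(n_reps)) {
      t_star <- sample.int(n_t, 1L)
      truth[r] <- t_star
      sim <- simulate_effects_phenotype(X, annos[[t_star]], alpha_star,
                                        cf$sigma_e2)
      s <- scan_standardized(X, sim$y)
      wald_joint <- numeric(n_t)
      wald_uni <- matrix(0, n_t, c_anno)
      for (t in seq_len(n_t)) {
        pj <- preps[[t]]
        if ("smart" %in% methods) {
          sol <- gee_solve(pj$joint, s)
          wald_joint[t] <- wald_from(sol$alpha, sol$cov)$wald
          if (t == t_star) {
            est_rows[[length(est_rows) + 1L]] <- data.frame(
              alpha1 = alphas[a, 1], alpha2 = alphas[a, 2], rep = r,
              alpha0_hat = sol$alpha[1L], alpha1_hat = sol$alpha[2L],
              alpha2_hat = sol$alpha[3L])
          }
        }
        if (any(c("unimax", "uni") %in% methods)) {
          for (j in seq_len(c_anno)) {
            solu <- gee_solve(pj$uni[[j]], s)
            wald_uni[t, j] <- wald_from(solu$alpha, solu$cov)$wald
          }
        }
      }
      if ("smart" %in% methods) {
        pp_arr$smart[r, ] <- chisq_mixture(wald_joint, df = c_anno)$pp
      }
      if ("unimax" %in% methods) {
        wmax <- apply(wald_uni, 1L, max)
        pp_arr$unimax[r, ] <- chisq_mixture(wmax, df = 1)$pp
      }
      if ("uni" %in% methods) {
        ppu <- chisq_mixture(as.vector(wald_uni), df = 1)$pp
        pp_arr$uni[r, ] <- apply(matrix(ppu, n_t, c_anno), 1L, max)
      }
    }
    for (mm in methods) {
      pw <- evaluate_power_at_fdr(pp_arr[[mm]], truth, fdr_levels)
      power_rows[[length(power_rows) + 1L]] <- data.frame(
        alpha1 = alphas[a, 1], alpha2 = alphas[a, 2], method = mm,
        fdr_level = fdr_levels, power = unname(pw))
    }
    pp_out[[a]] <- c(pp_arr, list(truth = truth,
                                  alpha = unname(alphas[a, ])))
  }
  list(power = do.call(rbind, power_rows),
       estimates = if (length(est_rows)) do.call(rbind, est_rows) else NULL,
       pp = pp_out, seed = seed, config = cf)
}

#' Configuration for the weighted SNP-set simulation design
#'
#' Defaults follow the stated design: 10,000 SNPs in 100 blocks of 100, 10
#' non-adjacent causal blocks with 20% causal SNPs each (200 causal SNPs in
#' total), `alpha0 = 0.5`, residual variance 0.5, and a 7,000/3,000
#' train/test split of 10,000 individuals.
#'
#' @param n total individuals; `n_train` of them are used to fit the
#'   annotation model, the rest form the test set for the SNP-set test.
#' @param m,n_blocks number of SNPs and blocks (`m / n_blocks` SNPs per
#'   block).
#' @param n_causal_blocks,causal_frac causal blocks, and causal fraction of
#'   SNPs within a causal block.
#' @param alpha0,sigma_e2 variance intercept and residual variance.
#' @param n_train training-set size.
#' @param n_ref reference-panel size for LD estimation in training.
#' @param n_tissues candidate tissues.
#' @param rho AR(1) copula correlation of the simulated genotype blocks.
#' @param elevated_mean mean of the elevated annotation distribution.
#' @param working GEE working covariance for the training fit.
#' @return A list of class `design2_config`.
#' @export
design2_config <- function(n = 10000L, m = 10000L, n_blocks = 100L,
                           n_causal_blocks = 10L, causal_frac = 0.2,
                           alpha0 = 0.5, sigma_e2 = 0.5,
                           n_train = 7000L, n_ref = 500L, n_tissues = 10L,
                           rho = 0.5, elevated_mean = 10,
                           working = c("ld", "independence")) {
  if (m %% n_blocks != 0L) stop("m must be a multiple of n_blocks")
  structure(list(n = n, m = m, n_blocks = n_blocks,
                 block_snps = m %/% n_blocks,
                 n_causal_blocks = n_causal_blocks, causal_frac = causal_frac,
                 alpha0 = alpha0, sigma_e2 = sigma_e2,
                 n_train = n_train, n_ref = n_ref, n_tissues = n_tissues,
                 rho = rho, elevated_mean = elevated_mean,
                 working = match.arg(working)),
            class = "design2_config")
}

# Draw one design-2 replicate: causal structure, annotations for every
# tissue (each tissue's annotations are elevated on its own causal-like SNP
# set; only the relevant tissue's set is the truly causal one), effects and
# phenotype. Returns everything needed by the replicate consumers.
design2_replicate <- function(cf, X, alpha12, proportions,
                              tissues_needed = 1L) {
  bs <- cf$block_snps
  blocks <- lapply(seq_len(cf$n_blocks), function(b) ((b - 1L) * bs + 1L):(b * bs))
  causal_blocks <- sample_nonadjacent_blocks(cf$n_blocks, cf$n_causal_blocks)
  n_causal_per <- round(cf$causal_frac * bs)
  causal <- unlist(lapply(causal_blocks, function(b) {
    sort(sample(blocks[[b]], n_causal_per))
  }))
  t_star <- sample.int(cf$n_tissues, 1L)
  annos <- vector("list", tissues_needed)
  for (t in seq_len(tissues_needed)) {
    idx <- if (t == t_star || tissues_needed == 1L) causal else {
      cb <- sample_nonadjacent_blocks(cf$n_blocks, cf$n_causal_blocks)
      unlist(lapply(cb, function(b) sort(sample(blocks[[b]], n_causal_per))))
    }
    ca <- simulate_causal_annotations(cf$m, idx,
                                      group_proportions = proportions,
                                      elevated_mean = cf$elevated_mean)
    annos[[t]] <- center_annotations(annotation_matrix(ca$C))
  }
  names(annos) <- paste0("tissue", seq_len(tissues_needed))
  relevant <- annos[[min(t_star, tissues_needed)]]
  alpha_star <- c(cf$alpha0, alpha12)
  sim <- simulate_effects_phenotype(X, relevant, alpha_star, cf$sigma_e2,
                                    causal = causal)
  list(blocks = blocks, causal_blocks = causal_blocks, causal = causal,
       t_star = min(t_star, tissues_needed), annos = annos,
       relevant = relevant, alpha_star = alpha_star,
       beta = sim$beta, y = sim$y, sigma2 = sim$sigma2)
}

#' Run the weighted SNP-set simulation design
#'
#' For each setting (annotation coefficients x causal-group proportions) and
#' replicate: simulates causal blocks, causality-correlated annotations,
#' effects and phenotypes on a shared genotype matrix; splits individuals
#' into training and test sets; constructs per-SNP weights (equal weights,
#' oracle weights from the true coefficients of the true tissue, and
#' optionally weights estimated by the joint or max-univariate training-set
#' fit); and runs the weighted SNP-set test on the causal blocks of the test
#' set, reporting power at the significance threshold.
#'
#' @param config a [design2_config()].
#' @param alphas list of `(alpha1, alpha2)` vectors.
#' @param proportions list of causal-group proportion triplets.
#' @param n_reps replicates per setting.
#' @param methods subset of `"equal"`, `"oracle"`, `"smart"`, `"unimax"`.
#' @param sig_threshold significance threshold for declaring a causal block
#'   detected.
#' @param seed master seed.
#' @return List with `power` (data frame: alpha1, alpha2, prop3, method,
#'   power over causal blocks pooled across replicates) and `detail`
#'   (per-replicate detection counts).
#' @export
run_design2 <- function(config = design2_config(),
                        alphas = list(c(0.4, 0.4), c(0.4, 0)),
                        proportions = list(c(1/2, 1/2, 0),
                                           c(1/3, 1/3, 1/3),
                                           c(0, 0, 1)),
                        n_reps = 100L,
                        methods = c("equal", "oracle"),
                        sig_threshold = 1e-4,
                        seed = 1L) {
  methods <- match.arg(methods, c("equal", "oracle", "smart", "unimax"),
                       several.ok = TRUE)
  fit_methods <- intersect(methods, c("smart", "unimax"))
  set.seed(seed)
  cf <- config
  X <- simulate_genotypes(cf$n, cf$m, ld = "ar1", rho = cf$rho,
                          block_size = cf$block_snps)
  Xs <- scale(X)
  bad <- !is.finite(colSums(Xs))
  if (any(bad)) Xs[, bad] <- 0
  ref_prep <- NULL
  if (length(fit_methods) > 0L) {
    Xref <- simulate_genotypes(cf$n_ref, cf$m, ld = "ar1", rho = cf$rho,
                               block_size = cf$block_snps,
                               maf = attr(X, "maf"))
    ref_prep <- estimate_ld_blocks(Xref, block_size = cf$block_snps)
  }
  power_rows <- list()
  detail <- list()
  for (a in seq_along(alphas)) {
    for (p in seq_along(proportions)) {
      hits <- stats::setNames(numeric(length(methods)), methods)
      total <- 0L
      for (r in seq_len(n_reps)) {
        rep_dat <- design2_replicate(cf, Xs, alphas[[a]], proportions[[p]],
                                     tissues_needed = if (length(fit_methods)) cf$n_tissues else 1L)
        test_idx <- sample.int(cf$n, cf$n - cf$n_train)
        train_idx <- setdiff(seq_len(cf$n), test_idx)
        null <- skat_null_model(rep_dat$y[test_idx])
        weights <- list()
        if ("equal" %in% methods) weights$equal <- rep(1, cf$m)
        if ("oracle" %in% methods) {
          s2 <- drop(rep_dat$relevant$values %*% rep_dat$alpha_star)
          weights$oracle <- construct_weights(s2, pp = 1)$weights
        }
        if (length(fit_methods) > 0L) {
          s_train <- scan_standardized(Xs[train_idx, , drop = FALSE],
                                       rep_dat$y[train_idx])
          for (mm in fit_methods) {
            mode <- if (mm == "smart") "joint" else "unimax"
            ft <- fit_all_tissues(s_train, rep_dat$annos, ref_prep,
                                  n = length(train_idx), working = cf$working,
                                  mode = mode)
            mix <- chisq_mixture(ft$table$wald,
                                 df = if (mm == "smart") 2 else 1)
            top <- which.max(mix$pp)
            fit_top <- ft$fits[[top]]
            A_top <- rep_dat$annos[[top]]
            if (mm == "smart") {
              s2 <- drop(A_top$values %*% stats::coef(fit_top))
            } else {
              lab <- ft$table$annotation[top]
              j <- match(lab, A_top$labels)
              s2 <- drop(A_top$values[, c(1L, 1L + j)] %*% stats::coef(fit_top))
            }
            weights[[mm]] <- construct_weights(s2, pp = mix$pp[top])$weights
          }
        }
        for (b in rep_dat$causal_blocks) {
          ix <- rep_dat$blocks[[b]]
          G <- X[test_idx, ix, drop = FALSE]
          for (mm in methods) {
            res <- skat_test(G, weights[[mm]][ix], null)
            hits[mm] <- hits[mm] + (res$pvalue < sig_threshold)
          }
          total <- total + 1L
        }
      }
      for (mm in methods) {
        power_rows[[length(power_rows) + 1L]] <- data.frame(
          alpha1 = alphas[[a]][1], alpha2 = alphas[[a]][2],
          prop3 = proportions[[p]][3], method = mm,
          power = hits[mm] / total)
      }
      detail[[length(detail) + 1L]] <- list(alpha = alphas[[a]],
                                            proportions = proportions[[p]],
                                            hits = hits, total = total)
    }
  }
  list(power = do.call(rbind, power_rows), detail = detail,
       seed = seed, config = cf)
}
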