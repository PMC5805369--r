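test_that("genotype simulation: frequencies, determinism, LD limits", {
  X1 <- simulate_genotypes(400, 30, seed = 51)
  X2 <- simulate_genotypes(400, 30, seed = 51)
  expect_identical(X1, X2)
  expect_true(all(X1 %in% 0:2))
  # single-SNP empirical frequency within a binomial CI of the drawn MAF
  X <- simulate_genotypes(5000, 1, seed = 52)
  f <- attr(X, "maf")
  phat <- mean(X) / 2
  expect_lt(abs(phat - f), 3 * sqrt(f * (1 - f) / (2 * 5000)))
  # rho = 0 AR(1) behaves like independent draws
  Xa <- simulate_genotypes(3000, 40, ld = "ar1", rho = 0, block_size = 20,
                           maf = rep(0.3, 40), seed = 53)
  r <- cor(Xa)
  expect_lt(max(abs(r[upper.tri(r)])), 0.08)
  # nonzero rho induces within-block correlation
  Xb <- simulate_genotypes(3000, 2, ld = "ar1", rho = 0.8, block_size = 2,
                           maf = rep(0.3, 2), seed = 54)
  expect_gt(cor(Xb)[1, 2], 0.5)
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)), "maf_range")
})

test_that("tissue annotations hit the requested occupancy and correlation", {
  annos <- simulate_tissue_annotations(20000, n_tissues = 4,
                                       occupancy = c(0.18, 0.11),
                                       cross_tissue_corr = 0.7, seed = 55)
  occ <- colMeans(annos[[1]]$values[, -1])
  expect_equal(unname(occ), c(0.18, 0.11), tolerance = 0.03)
  c12 <- cor(annos[[1]]$values[, 2], annos[[2]]$values[, 2])
  expect_equal(c12, 0.7, tolerance = 0.08)
  # zero target correlation gives near-independent tissues
  a0 <- simulate_tissue_annotations(20000, n_tissues = 2,
                                    cross_tissue_corr = 0, seed = 56)
  expect_lt(abs(cor(a0[[1]]$values[, 2], a0[[2]]$values[, 2])), 0.05)
  # realized correlation is monotone in the parameter
  cors <- vapply(c(0.2, 0.5, 0.9), function(ct) {
    a <- simulate_tissue_annotations(20000, n_tissues = 2,
                                     cross_tissue_corr = ct, seed = 57)
    cor(a[[1]]$values[, 2], a[[2]]$values[, 2])
  }, 0)
  expect_true(all(diff(cors) > 0))
})

test_that("causal annotations implement the three-group elevation scheme", {
  m <- 3000
  causal <- sort(sample.int(m, 200))
  set.seed(58)
  # proportions (0, 0, 1): both annotations elevated at every causal SNP
  s_all <- simulate_causal_annotations(m, causal, c(0, 0, 1))
  expect_true(all(s_all$groups == 3L))
  expect_gt(min(s_all$C[causal, 1]), 5)
  expect_gt(min(s_all$C[causal, 2]), 5)
  expect_gt(cor(s_all$C[causal, 1], s_all$C[causal, 2]), 0.5)
  # proportions (1/2, 1/2, 0): each annotation elevated on a disjoint half
  s_half <- simulate_causal_annotations(m, causal, c(1 / 2, 1 / 2, 0))
  expect_equal(sum(s_half$groups == 1L), 100)
  g1 <- causal[s_half$groups == 1L]
  g2 <- causal[s_half$groups == 2L]
  expect_gt(min(s_half$C[g2, 1]), 5)  # anno1 elevated on group 2
  expect_lt(max(s_half$C[g1, 1]), 5)  # ... not on group 1
  expect_gt(min(s_half$C[g1, 2]), 5)  # anno2 elevated on group 1
  # non-causal SNPs are standard normal
  noncausal <- setdiff(seq_len(m), causal)
  expect_equal(mean(s_all$C[noncausal, 1]), 0, tolerance = 0.08)
  expect_equal(sd(s_all$C[noncausal, 1]), 1, tolerance = 0.08)
  expect_error(simulate_causal_annotations(m, causal, c(0.5, 0.6, 0)), "summing")
})

test_that("effect simulation respects the variance model and heritability", {
  set.seed(59)
  m <- 500; n <- 300
  X <- scale(simulate_genotypes(n, m))
  A <- center_annotations(annotation_matrix(cbind(a = rbinom(m, 1, 0.2))))
  # E[sum beta^2] = alpha0 under centered annotations
  tot <- replicate(200, {
    sim <- simulate_effects_phenotype(X, A, c(0.1, 0.3), 0.9)
    sum(sim$beta^2)
  })
  expect_equal(mean(tot), 0.1, tolerance = 3 * sd(tot) / sqrt(200) + 0.01)
  # alpha = 0: pure noise
  sim0 <- simulate_effects_phenotype(X, A, c(0, 0), 1)
  expect_true(all(sim0$beta == 0))
  # degenerate design warning when everything is clamped
  expect_warning(simulate_effects_phenotype(X, A, c(-1, 0), 1), "clamped")
  expect_equal(implied_heritability(0.1, 0.9), 0.1)
})

test_that("marginal scan matches a per-SNP lm oracle", {
  set.seed(60)
  n <- 120
  X <- simulate_genotypes(n, 6)
  y <- 0.4 * X[, 2] + rnorm(n)
  scan <- marginal_scan(X, y)
  for (j in 1:6) {
    tval <- summary(lm(y ~ X[, j]))$coefficients[2, "t value"]
    expect_equal(scan$z[j], tval, tolerance = 1e-8)
    expect_equal(scan$chisq[j], tval^2, tolerance = 1e-8)
  }
  # duplicated SNP columns give identical statistics
  scan2 <- marginal_scan(cbind(X[, 1], X[, 1]), y)
  expect_equal(scan2$chisq[1], scan2$chisq[2])
  # independent phenotype: mean chi-square about 1
  set.seed(61)
  Xn <- simulate_genotypes(500, 400)
  scan_null <- marginal_scan(Xn, rnorm(500))
  expect_equal(mean(scan_null$chisq), 1, tolerance = 0.15)
  # zero-variance SNP yields NA with a message
  expect_message(sc <- marginal_scan(cbind(X[, 1], rep(2, n)), y), "zero-variance")
  expect_true(is.na(sc$z[2]))
})

test_that("per-block PVE decomposes the genetic variance", {
  set.seed(62)
  n <- 500; m <- 200
  X <- scale(simulate_genotypes(n, m))
  blocks <- split(seq_len(m), rep(1:10, each = 20))
  beta <- numeric(m); beta[c(5, 25, 45)] <- 0.15
  y <- drop(X %*% beta) + rnorm(n, 0, 0.5)
  pve <- per_block_pve(beta, X, blocks, y)
  expect_equal(pve[4:10], rep(0, 7), ignore_attr = TRUE)
  expect_true(all(pve[1:3] > 0))
  # with independent blocks the PVEs add up to the total genetic share
  total <- var(drop(X %*% beta)) / var(y)
  expect_equal(sum(pve), total, tolerance = 0.05)
})

test_that("power-at-FDR matches a brute-force enumeration oracle", {
  # perfect separation: power 1 at every level
  pp <- matrix(0, 20, 5)
  truth <- sample.int(5, 20, replace = TRUE)
  pp[cbind(1:20, truth)] <- 1
  expect_equal(unname(evaluate_power_at_fdr(pp, truth)), rep(1, 3))
  # random posteriors: compare against direct enumeration over all cutoffs
  set.seed(63)
  pp2 <- matrix(runif(20 * 5), 20, 5)
  truth2 <- sample.int(5, 20, replace = TRUE)
  got <- evaluate_power_at_fdr(pp2, truth2, fdr_levels = c(0.1, 0.3, 0.5))
  lab <- as.vector(t(`[<-`(matrix(FALSE, 20, 5), cbind(1:20, truth2), TRUE)))
  vals <- as.vector(t(pp2))
  ord <- order(-vals)
  brute <- vapply(c(0.1, 0.3, 0.5), function(t) {
    best <- 0
    tp <- 0; fp <- 0
    for (k in seq_along(ord)) {
      if (lab[ord[k]]) tp <- tp + 1 else fp <- fp + 1
      if (fp / (fp + tp) <= t) best <- tp
    }
    best / 20
  }, 0)
  expect_equal(unname(got), brute)
  # relaxing the FDR level never decreases power
  many <- evaluate_power_at_fdr(pp2, truth2, fdr_levels = seq(0.05, 0.9, 0.05))
  expect_true(all(diff(many) >= 0))
})

test_that("non-adjacent block sampling respects the constraint", {
  set.seed(64)
  for (i in 1:20) {
    sel <- sample_nonadjacent_blocks(100, 10)
    expect_length(sel, 10)
    expect_true(all(diff(sel) > 1))
  }
  expect_error(sample_nonadjacent_blocks(5, 4), "non-adjacent")
})

test_that("design drivers are deterministic given the master seed", {
  cf <- design1_config(n = 300, m = 200, n_ref = 100, n_tissues = 4,
                       geno_block = 20L, ld_block_size = 20L)
  al <- matrix(c(0.3, 0.3), 1)
  r1 <- run_design1(cf, alphas = al, n_reps = 5, seed = 77)
  r2 <- run_design1(cf, alphas = al, n_reps = 5, seed = 77)
  expect_identical(r1$power, r2$power)
  expect_identical(r1$estimates, r2$estimates)
  cf2 <- design2_config(n = 400, m = 400, n_blocks = 10, n_causal_blocks = 3,
                        n_train = 280, n_tissues = 3)
  d1 <- run_design2(cf2, alphas = list(c(0.4, 0.4)),
                    proportions = list(c(0, 0, 1)), n_reps = 3,
                    methods = c("equal", "oracle"), seed = 78)
  d2 <- run_design2(cf2, alphas = list(c(0.4, 0.4)),
                    proportions = list(c(0, 0, 1)), n_reps = 3,
                    methods = c("equal", "oracle"), seed = 78)
  expect_identical(d1$power, d2$power)
})

test_that("design-2 defaults give 200 causal SNPs and elevated causal variance", {
  cf <- design2_config()
  expect_equal(cf$n_causal_blocks * round(cf$causal_frac * cf$block_snps), 200)
  # a replicate at reduced n keeps the causal bookkeeping
  set.seed(79)
  cfs <- design2_config(n = 500, m = 2000, n_blocks = 20, n_causal_blocks = 4,
                        n_train = 350, n_tissues = 2)
  X <- scale(simulate_genotypes(cfs$n, cfs$m, ld = "ar1", block_size = cfs$block_snps))
  rep_dat <- tissuescan:::design2_replicate(cfs, X, c(0.4, 0.4), c(1/3, 1/3, 1/3))
  expect_length(rep_dat$causal, 4 * round(0.2 * 100))
  expect_true(all(diff(rep_dat$causal_blocks) > 1))
  # causal SNPs have larger model variance than non-causal ones
  expect_gt(mean(rep_dat$sigma2[rep_dat$causal]), 1)
  expect_equal(sum(rep_dat$sigma2[-rep_dat$causal]), 0)
})
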