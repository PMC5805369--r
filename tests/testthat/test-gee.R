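test_that("z-scores convert to chi-squares, dropping missing values", {
  expect_message(ss <- chisq_from_z(c("a", "b", "c", "d"),
                                    c(0, -2, 1.96, NA), n = 100),
                 "dropping 1")
  expect_equal(ss$chisq, c(0, 4, 3.8416))
  expect_identical(attr(ss, "m"), 3L)
  expect_error(summary_stats("a", -1, 10), "nonnegative")
})

test_that("block LD estimation matches a direct Pearson oracle", {
  # printed 3-SNP fixture, small enough to check by hand
  G <- matrix(c(0, 1, 2, 2, 1, 0, 1, 1,
                0, 1, 1, 2, 0, 0, 1, 2,
                2, 0, 1, 0, 1, 2, 0, 1), ncol = 3)
  ld <- estimate_ld_blocks(G, block_size = 3L, adjust = FALSE)
  expect_equal(ld$corr[[1]], unname(cor(G)), tolerance = 1e-12)
  # duplicated genotype column is in perfect LD with its twin
  ld2 <- estimate_ld_blocks(cbind(G[, 1], G[, 1]), block_size = 2L, adjust = FALSE)
  expect_equal(ld2$corr[[1]][1, 2], 1)
  # monomorphic SNP becomes an identity row, LD score 1
  expect_warning(ld3 <- estimate_ld_blocks(cbind(G[, 1], rep(1, 8)),
                                           block_size = 2L),
                 "monomorphic")
  expect_equal(ld3$corr[[1]][2, ], c(0, 1))
  # the r2 adjustment shrinks off-diagonal squared correlations
  ld4 <- estimate_ld_blocks(G, block_size = 3L, adjust = TRUE)
  r2_adj <- tissuescan:::block_r2(ld4, 1)
  r2_raw <- cor(G)^2
  expect_true(all(r2_adj[upper.tri(r2_adj)] <= r2_raw[upper.tri(r2_raw)]))
  expect_equal(diag(r2_adj), rep(1, 3))
})

test_that("design rows aggregate annotations over LD, scaled by n/m", {
  sys <- toy_system()
  # identity LD: d_j = (n/m) A_j, LD scores all 1
  expect_equal(sys$design$D, (sys$n / sys$m) * sys$A$values)
  expect_equal(sys$design$ld_scores, rep(1, sys$m))
  # 2-SNP block with r = 0.5: d_1 = (n/m) (A_1 + 0.25 A_2)
  A2 <- center_annotations(annotation_matrix(cbind(x = c(2, -1))))
  ld2 <- structure(list(blocks = list(1:2),
                        corr = list(matrix(c(1, .5, .5, 1), 2)),
                        n_ref = Inf, adjust = FALSE, m = 2L,
                        monomorphic = integer(0)),
                   class = "ld_blocks")
  d2 <- build_design(ld2, A2, n = 10, m = 2)
  expect_equal(d2$D[1, ], (10 / 2) * (A2$values[1, ] + 0.25 * A2$values[2, ]))
  expect_equal(d2$ld_scores, rep(1.25, 2))
  # intercept-only annotations: d_j = (n/m) * ld score
  A0 <- annotation_matrix(matrix(numeric(2), ncol = 1))
  A0 <- suppressWarnings(center_annotations(A0))
  expect_equal(build_design(ld2, A0, n = 10, m = 2)$D[, 1], (10 / 2) * rep(1.25, 2))
  expect_error(build_design(sys$ld, A2, n = 10), "do not match")
})

test_that("GEE with independence working and identity LD is exactly OLS", {
  sys <- toy_system(m = 50)
  f <- gee_fit(sys$design, sys$s, working = "independence")
  ols <- qr.solve(sys$design$D, sys$s - 1)
  expect_equal(unname(coef(f)), unname(ols), tolerance = 1e-12)
  expect_equal(f$df, 2L)
  # a flat response of 1 gives exactly zero coefficients
  f0 <- gee_fit(sys$design, rep(1, sys$m), working = "independence")
  expect_equal(unname(coef(f0)), rep(0, 3), tolerance = 1e-12)
  expect_equal(f0$wald, 0)
})

test_that("GEE errors are informative", {
  sys <- toy_system()
  A_coll <- annotation_matrix(cbind(a = sys$A$values[, 2], b = sys$A$values[, 2]))
  A_coll$centered <- TRUE  # columns already centered
  d_coll <- build_design(sys$ld, A_coll, n = sys$n, m = sys$m)
  expect_error(gee_fit(d_coll, sys$s), "collinear")
  A1 <- center_annotations(annotation_matrix(cbind(x = c(1, 0), y = c(0, 2))))
  expect_error(gee_fit(build_design(identity_ld(2), A1, n = 10, m = 2),
                       c(1, 2)),
               "fewer SNPs")
})

test_that("Wald statistic: quadratic form over annotation coefficients only", {
  # printed 2x2 case: alpha = (1, 0), V = diag(1, 4) -> W = 1
  w <- tissuescan:::wald_from(c(9, 1, 0), diag(c(1, 1, 4)))
  expect_equal(w$wald, 1)
  expect_equal(w$df, 2L)
  # univariate identity: W = (alpha1 / se)^2
  sys <- toy_system(m = 80)
  f <- gee_fit(gee_prepare(sys$design, "independence", columns = c(1L, 2L)), sys$s)
  expect_equal(f$wald, (coef(f)[2] / sqrt(vcov(f)[2, 2]))^2,
               ignore_attr = TRUE)
  expect_equal(wald_statistic(f)$df, 1L)
})

test_that("Wald statistic is invariant to rescaling an annotation column", {
  sys <- toy_system(m = 100, seed = 9)
  f1 <- gee_fit(sys$design, sys$s, working = "independence")
  A_scaled <- sys$A
  A_scaled$values[, 2] <- 7 * A_scaled$values[, 2]
  d2 <- build_design(sys$ld, A_scaled, n = sys$n, m = sys$m)
  f2 <- gee_fit(d2, sys$s, working = "independence")
  expect_equal(f2$wald, f1$wald, tolerance = 1e-8)
  expect_equal(coef(f2)[2] * 7, coef(f1)[2], ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("null simulation: coefficients centered at zero within Monte-Carlo error", {
  set.seed(21)
  m <- 400; n <- 300
  A <- center_annotations(annotation_matrix(cbind(a = rbinom(m, 1, .2),
                                                  b = rnorm(m))))
  design <- build_design(identity_ld(m, block_size = 50L), A, n = n, m = m)
  prep <- gee_prepare(design, "independence")
  est <- t(replicate(150, tissuescan:::gee_solve(prep, rchisq(m, df = 1))$alpha))
  mc_se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est)) < 4 * mc_se))
})

test_that("per-tissue scans are order-equivariant and handle shared inputs", {
  sys <- toy_system(m = 90, seed = 4)
  annos <- list(t1 = sys$A, t2 = sys$A, t3 = sys$A)
  ft <- fit_all_tissues(sys$s, annos, sys$ld, n = sys$n, working = "independence")
  expect_equal(ft$table$wald, rep(ft$table$wald[1], 3))
  # permuting tissues permutes rows only
  ft2 <- fit_all_tissues(sys$s, annos[c(2, 3, 1)], sys$ld, n = sys$n,
                         working = "independence")
  expect_equal(sort(ft2$table$tissue), sort(ft$table$tissue))
  expect_equal(ft2$table$wald, ft$table$wald)
  # unimax keeps the larger of the univariate statistics
  fu <- fit_all_tissues(sys$s, annos[1], sys$ld, n = sys$n,
                        working = "independence", mode = "unimax")
  f1 <- gee_fit(gee_prepare(sys$design, "independence", columns = c(1L, 2L)), sys$s)
  f2 <- gee_fit(gee_prepare(sys$design, "independence", columns = c(1L, 3L)), sys$s)
  expect_equal(fu$table$wald, max(f1$wald, f2$wald))
})
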