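test_that("SNP variances are the annotation dot products", {
  expect_equal(snp_variances(matrix(c(1, -1), 1), c(0.1, 0.2, 0.05)), 0.25)
  # intercept-only coefficients give a flat variance
  expect_equal(snp_variances(matrix(rnorm(10), 5), c(0.3, 0, 0)), rep(0.3, 5))
  expect_error(snp_variances(matrix(1, 1, 3), c(0.1, 0.2)), "do not match")
  # centered annotations reproduce mean sigma2 = alpha0 + (mean A - genome mean) alpha
  A <- center_annotations(annotation_matrix(cbind(x = c(0, 0, 1, 1, 1, 0))))
  alpha <- c(0.2, 0.4)
  gene_rows <- matrix(c(1, 1, 0), ncol = 1)  # raw values for 3 SNPs
  s2 <- snp_variances(gene_rows, alpha, centering = A)
  expect_equal(mean(s2), 0.2 + (mean(gene_rows) - 0.5) * 0.4)
})

test_that("weight construction follows the shift-and-average rule", {
  # pp = 0: equal weights regardless of variances
  w0 <- construct_weights(c(0.3, 0.1, 0.5), pp = 0)
  expect_equal(w0$weights, rep(1, 3))
  # pp = 1: shifted variances
  w1 <- construct_weights(c(0.3, 0.1, 0.5), pp = 1)
  expect_equal(w1$weights, c(0.2, 0, 0.4) + 1e-15)
  # constant variances carry no signal
  wc <- construct_weights(rep(0.4, 5), pp = 0.7)
  expect_equal(wc$weights, rep(0.7 * 1e-15 + 0.3, 5))
  expect_true(all(w1$weights > 0))
  expect_error(construct_weights(1:3, pp = 1.2), "\\[0, 1\\]")
})

test_that("weights degrade continuously to equal weights as pp -> 0", {
  s2 <- c(0.9, 0.2, 0.5, 0.1)
  pps <- c(0.5, 0.1, 0.01, 0.001)
  dev <- vapply(pps, function(p) {
    max(abs(construct_weights(s2, p)$weights - 1))
  }, 0)
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[length(dev)], 0.002)
})

test_that("null models: quantitative residuals and binary fitted means", {
  y <- c(3, 5, 7, 9)
  nm <- skat_null_model(y)
  expect_equal(nm$residuals, y - mean(y))
  yb <- c(0, 0, 1, 1, 1)
  nb <- skat_null_model(yb, family = "binary")
  expect_equal(nb$fitted, rep(0.6, 5), tolerance = 1e-6)
  # adding a covariate cannot increase the residual sum of squares
  set.seed(31)
  y2 <- rnorm(50)
  x <- rnorm(50)
  rss0 <- sum(skat_null_model(y2)$residuals^2)
  rss1 <- sum(skat_null_model(y2, covariates = x)$residuals^2)
  expect_lte(rss1, rss0)
  expect_error(skat_null_model(c(0, 1, 2), family = "binary"), "0/1")
})

test_that("single-SNP weighted test equals the marginal score test", {
  set.seed(32)
  n <- 250
  g <- rbinom(n, 2, 0.3)
  y <- 0.1 * g + rnorm(n)
  nm <- skat_null_model(y)
  res <- skat_test(matrix(g, ncol = 1), 1, nm)
  gc <- g - mean(g)
  yc <- y - mean(y)
  z2 <- sum(gc * yc)^2 / (nm$sigma2 * sum(gc^2))
  expect_equal(res$pvalue, pchisq(z2, df = 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("degenerate genotype blocks and zero weights give Q = 0, p = 1", {
  nm <- skat_null_model(rnorm(20))
  res <- skat_test(matrix(1, 20, 3), c(1, 1, 1), nm)
  expect_equal(res$Q, 0)
  expect_equal(res$pvalue, 1)
  res0 <- skat_test(matrix(rbinom(60, 2, .4), 20, 3), c(0, 0, 0), nm)
  expect_equal(res0$Q, 0)
  expect_equal(res0$pvalue, 1)
})

test_that("Q is invariant to phenotype shifts in the quantitative case", {
  set.seed(33)
  G <- matrix(rbinom(40 * 5, 2, 0.3), 40, 5)
  y <- rnorm(40)
  r1 <- skat_test(G, rep(1, 5), skat_null_model(y))
  r2 <- skat_test(G, rep(1, 5), skat_null_model(y + 100))
  expect_equal(r1$Q, r2$Q, tolerance = 1e-8)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-8)
})

test_that("the mixture-of-chi-squares tail matches simulation", {
  set.seed(34)
  lam <- c(3, 1, 0.5)
  draws <- colSums(lam * matrix(rchisq(3 * 40000, 1), 3))
  for (q in c(2, 6, 12)) {
    p_imhof <- tissuescan:::mixture_chisq_tail(q, lam)
    expect_equal(p_imhof$p, mean(draws > q), tolerance = 0.02)
  }
  # single eigenvalue: exact chi-square tail
  p1 <- tissuescan:::mixture_chisq_tail(5, 2)
  expect_equal(p1$p, pchisq(2.5, 1, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("binary-trait test is calibrated on a small null simulation", {
  set.seed(35)
  n <- 400
  G <- matrix(rbinom(n * 8, 2, 0.25), n, 8)
  pv <- replicate(400, {
    y <- rbinom(n, 1, 0.4)
    skat_test(G, rep(1, 8), skat_null_model(y, family = "binary"))$pvalue
  })
  expect_gt(mean(pv < 0.05), 0.02)
  expect_lt(mean(pv < 0.05), 0.09)
})

test_that("gene sets follow the 10 kb window and minimum-SNP rules", {
  snps <- snp_table(c(4999L, 5000L, 5001L, seq(20000L, 20900L, by = 100L),
                      40000L))
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      start = c(15000L, 15000L, 100000L),
                      end = c(16000L, 16000L, 100500L),
                      stringsAsFactors = FALSE)
  # gA at window [5000, 26000]: SNP at exactly 10 kb upstream included
  suppressMessages({
    gs <- assemble_gene_sets(genes[1, ], snps, min_snps = 12L)
  })
  expect_length(gs, 1)
  expect_true("rs2" %in% gs[[1]]$snp_ids)   # pos 5000 inclusive
  expect_false("rs1" %in% gs[[1]]$snp_ids)  # pos 4999 outside
  expect_equal(length(gs[[1]]$snp_ids), 12)
  # a 9-SNP gene is excluded at min_snps = 10
  suppressMessages({
    gs9 <- assemble_gene_sets(data.frame(gene_id = "g9", chrom = "chr1",
                                         start = 20000L, end = 20800L),
                              snps, window = 0L, min_snps = 10L)
  })
  expect_length(gs9, 0)
  # brute-force membership oracle on the full table
  suppressMessages(gs_all <- assemble_gene_sets(genes, snps, min_snps = 1L))
  for (g in gs_all) {
    i <- match(g$gene_id, genes$gene_id)
    manual <- snps$snp_id[snps$pos >= genes$start[i] - 10000 &
                            snps$pos <= genes$end[i] + 10000]
    expect_identical(g$snp_ids, manual)
  }
  expect_warning(suppressMessages(
    assemble_gene_sets(rbind(genes, data.frame(gene_id = "bad", chrom = "chr1",
                                               start = 50L, end = 10L)),
                       snps, min_snps = 1L)),
    "malformed")
})
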