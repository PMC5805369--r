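# Shared fixtures, built in code.

snp_table <- function(pos, chrom = "chr1") {
  data.frame(snp_id = paste0("rs", seq_along(pos)), chrom = chrom, pos = pos,
             stringsAsFactors = FALSE)
}

# Small two-annotation matrix with known structure.
toy_annotation <- function(m = 40, seed = 1) {
  set.seed(seed)
  annotation_matrix(cbind(a1 = rbinom(m, 1, 0.3), a2 = rnorm(m)))
}

# A tiny fitted system: identity LD, centered annotations, chi-squares.
toy_system <- function(m = 60, n = 200, seed = 2) {
  set.seed(seed)
  A <- center_annotations(toy_annotation(m, seed = seed))
  ld <- identity_ld(m, block_size = 10L)
  design <- build_design(ld, A, n = n, m = m)
  s <- stats::rchisq(m, df = 1)
  list(A = A, ld = ld, design = design, s = s, n = n, m = m)
}
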