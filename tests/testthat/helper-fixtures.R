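# Small fixtures built in code.

# hand-specifiable VCF: sites as a data frame, genotypes as a character
# matrix, optional depth
toy_vcf <- function(chrom, pos, ref, alt, qual, gt, dp = NULL) {
  sites <- tibble::tibble(chrom = chrom, pos = pos,
                          id = paste0("v", seq_along(pos)),
                          ref = ref, alt = alt, qual = qual)
  if (is.null(colnames(gt))) colnames(gt) <- paste0("s", seq_len(ncol(gt)))
  new_vcf(sites, gt, dp, colnames(gt))
}

# phased VCF from a haplotype matrix (2 rows per sample)
hap_vcf <- function(m, pos = seq_len(ncol(m)), chrom = "chr1", qual = 50) {
  n <- nrow(m) / 2
  gt <- matrix(unlist(lapply(seq_len(n), function(i) {
    paste0(m[2 * i - 1, ], "|", m[2 * i, ])
  })), ncol = n)
  colnames(gt) <- paste0("s", seq_len(n))
  toy_vcf(chrom = rep(chrom, ncol(m)), pos = pos,
          ref = rep("A", ncol(m)), alt = rep("G", ncol(m)),
          qual = rep(qual, ncol(m)), gt = gt,
          dp = matrix(30, ncol(m), n))
}

random_hap_matrix <- function(n_hap, n_sites, p = NULL) {
  if (is.null(p)) p <- runif(n_sites, 0.1, 0.9)
  matrix(rbinom(n_hap * n_sites, 1, rep(p, each = n_hap)), n_hap, n_sites)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
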