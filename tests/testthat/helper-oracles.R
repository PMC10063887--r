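# Independent brute-force oracles: direct transcriptions of the defining
# formulas, kept free of any package internals they are used to check.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# canonical k-mer multiset by plain substring enumeration
oracle_kmer_counts <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    s <- toupper(s)
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      rc <- oracle_revcomp(km)
      out <- c(out, if (km < rc) km else rc)
    }
  }
  table(out)
}

oracle_exact_jaccard <- function(seq1, seq2, k) {
  k1 <- names(oracle_kmer_counts(seq1, k))
  k2 <- names(oracle_kmer_counts(seq2, k))
  length(intersect(k1, k2)) / length(union(k1, k2))
}

# per-site pi by explicit enumeration of allele pairs
oracle_site_pi <- function(alleles) {
  n <- length(alleles)
  diff <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diff <- diff + (alleles[i] != alleles[j])
  diff / choose(n, 2)
}

# Tajima's D by direct formula transcription; khat from explicit pairwise
# row comparison
oracle_tajima_d <- function(m) {
  n <- nrow(m)
  cnt <- apply(m, 2, sum)
  S <- sum(cnt > 0 & cnt < n)
  khat <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    khat <- khat + sum(m[i, ] != m[j, ])
  khat <- khat / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  if (S == 0) return(list(S = 0, theta_pi = 0, theta_w = 0, D = NA_real_))
  list(S = S, theta_pi = khat, theta_w = S / a1,
       D = (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)))
}

# Weir & Cockerham (1984) per-site estimator, written out long-hand from
# the published component definitions (dosage matrix: samples x 1 site)
oracle_wc_fst_site <- function(dos, pop) {
  pops <- unique(pop)
  r <- length(pops)
  n_i <- p_i <- h_i <- numeric(r)
  for (k in seq_len(r)) {
    d <- dos[pop == pops[k]]
    d <- d[!is.na(d)]
    n_i[k] <- length(d)
    p_i[k] <- sum(d) / (2 * length(d))
    h_i[k] <- sum(d == 1) / length(d)
  }
  nbar <- sum(n_i) / r
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       fst = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

# EHH at site x from focal among carrier rows: exhaustive distinct
# extended-haplotype enumeration
oracle_ehh_at <- function(m, focal, rows, x) {
  span <- if (x >= focal) focal:x else x:focal
  words <- apply(m[rows, span, drop = FALSE], 1, paste, collapse = "")
  cnt <- table(words)
  sum(choose(cnt, 2)) / choose(length(rows), 2)
}

# all-pairs interval overlap (0-based half-open)
oracle_overlap_pairs <- function(a, b, min_bp = 1) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_bp)
      out <- rbind(out, data.frame(name_a = a$name[i], name_b = b$name[j],
                                   overlap_bp = ov))
  }
  out
}
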