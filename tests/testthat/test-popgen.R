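test_that("per-site pi: two differing haploid-coded alleles give 1, monomorphic 0", {
  v <- toy_vcf(chrom = rep("chr1", 2), pos = 1:2, ref = c("A", "A"),
               alt = c("G", "G"), qual = c(50, 50),
               gt = rbind(c("0|0", "1|1"), c("0|0", "0|0")))
  sp <- site_pi(v)
  # site 1: alleles 0,0,1,1 -> pi = 2*2*2/(4*3) = 2/3; site 2 monomorphic
  expect_equal(sp$pi, c(2 / 3, 0))
  # exact n=2: one 0 and one 1 allele
  v2 <- toy_vcf(chrom = "chr1", pos = 1L, ref = "A", alt = "G", qual = 50,
                gt = matrix("0|1", 1, 1))
  expect_equal(site_pi(v2)$pi, 1)
})

test_that("per-site pi equals the pairwise enumeration oracle on random 20-haplotype sites", {
  set.seed(41)
  for (i in 1:20) {
    alleles <- rbinom(20, 1, runif(1, 0.1, 0.9))
    m <- matrix(alleles, nrow = 20, ncol = 1)
    v <- hap_vcf(m)
    expect_equal(site_pi(v)$pi, oracle_site_pi(alleles), tolerance = 1e-12)
  }
})

test_that("windowed pi sums per-site values exactly", {
  set.seed(42)
  m <- random_hap_matrix(10, 50)
  v <- hap_vcf(m, pos = sort(sample.int(3e5, 50)))
  sp <- site_pi(v)
  wp <- windowed_pi(v, window_size = 1e5)
  expect_equal(sum(wp$pi_sum), sum(sp$pi), tolerance = 1e-12)
  expect_equal(wp$pi_bp, wp$pi_sum / 1e5)
})

test_that("Tajima's D is 0 for n = 2 whenever sites segregate", {
  m <- rbind(c(0, 1, 0, 1), c(1, 0, 0, 0))
  st <- tajima_stats(m)
  expect_equal(st$D, 0, tolerance = 1e-12)
})

test_that("Tajima's D matches the independent transcription oracle to 1e-10", {
  set.seed(43)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    S <- sample(2:50, 1)
    m <- random_hap_matrix(n, S)
    got <- tajima_stats(m)
    want <- oracle_tajima_d(m)
    if (want$S == 0) {
      expect_true(is.na(got$D))
    } else {
      expect_equal(got$theta_pi, want$theta_pi, tolerance = 1e-10)
      expect_equal(got$theta_w, want$theta_w, tolerance = 1e-10)
      expect_equal(got$D, want$D, tolerance = 1e-10)
    }
  }
})

test_that("windows without segregating sites are flagged NA", {
  m <- matrix(0L, 6, 3)
  m[, 1] <- c(1, 1, 0, 0, 0, 0)
  hs <- new_hap_set(m, tibble::tibble(chrom = "chr1",
                                      pos = c(10L, 20L, 150010L)),
                    tibble::tibble(sample = paste0("s", 1:3)),
                    rep(paste0("s", 1:3), each = 2))
  td <- tajimas_d(hs, window_size = 1e5)
  expect_true(is.na(td$tajima_d[td$start == 100000]))
  expect_false(is.na(td$tajima_d[td$start == 0]))
})

test_that("Weir-Cockerham Fst approaches 1 at a fixed difference and <= 0 for identical pops", {
  n <- 50
  gt_fixed <- matrix(c(rep("0|0", n), rep("1|1", n)), nrow = 1)
  v <- toy_vcf(chrom = "chr1", pos = 1L, ref = "A", alt = "G", qual = 50,
               gt = gt_fixed)
  pops <- tibble::tibble(sample = paste0("s", 1:(2 * n)),
                         population = rep(c("p1", "p2"), each = n))
  f <- wc_fst(v, pops)
  expect_gt(f$fst, 0.98)
  gt_same <- matrix(rep(c("0|1", "0|0"), n), nrow = 1)
  v2 <- toy_vcf(chrom = "chr1", pos = 1L, ref = "A", alt = "G", qual = 50,
                gt = gt_same)
  f2 <- wc_fst(v2, pops)
  expect_lte(f2$fst, 0)
  expect_lte(f2$a, 0) # no among-population variance component
  expect_lt(abs(f2$a), 0.01)
})

test_that("Fst components equal the long-hand oracle and respect symmetries", {
  set.seed(44)
  for (i in 1:25) {
    n <- 12
    dos <- matrix(rbinom(n, 2, runif(1, 0.2, 0.8)), ncol = 1)
    pop <- rep(c("x", "y"), each = n / 2)
    gt <- matrix(c("0|0", "0|1", "1|1")[dos + 1], nrow = 1)
    v <- toy_vcf(chrom = "chr1", pos = 1L, ref = "A", alt = "G", qual = 50,
                 gt = gt)
    pops <- tibble::tibble(sample = paste0("s", 1:n), population = pop)
    got <- wc_fst(v, pops)
    want <- oracle_wc_fst_site(dos[, 1], pop)
    expect_equal(got$a, want$a, tolerance = 1e-10)
    expect_equal(got$b, want$b, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
    # permutation invariance and label-swap symmetry
    perm <- sample(n)
    v_perm <- toy_vcf(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                      qual = 50, gt = gt[, perm, drop = FALSE])
    pops_perm <- tibble::tibble(sample = colnames(v_perm$gt),
                                population = pop[perm])
    expect_equal(wc_fst(v_perm, pops_perm)$fst, got$fst, tolerance = 1e-12)
    pops_swap <- tibble::tibble(sample = pops$sample,
                                population = c(x = "y", y = "x")[pop])
    expect_equal(wc_fst(v, pops_swap)$fst, got$fst, tolerance = 1e-12)
  }
})

test_that("Balding-Nichols panels recover their divergence parameter", {
  fsts <- vapply(1:3, function(s) {
    cfg <- sim_config(seed = s, n_populations = 2, pop_sizes = c(30, 30),
                      divergence = 0.15, n_sites = 2000, chrom_length = 1e6)
    hp <- simulate_haplotypes(simulate_frequencies(cfg), cfg)
    wc_fst_overall(wc_fst(hp$vcf, hp$hap$samples))
  }, double(1))
  expect_lt(abs(mean(fsts) - 0.15), 0.02)
})

test_that("F = 0 keeps 95% of per-site Fst estimates below 0.05", {
  cfg <- sim_config(seed = 45, n_populations = 2, pop_sizes = c(50, 50),
                    divergence = 0, n_sites = 1500, chrom_length = 1e6)
  hp <- simulate_haplotypes(simulate_frequencies(cfg), cfg)
  f <- wc_fst(hp$vcf, hp$hap$samples)
  expect_gte(mean(f$fst < 0.05, na.rm = TRUE), 0.95)
})

test_that("r2 is 1 for a duplicated site and matches hand algebra on 4 haplotypes", {
  m <- rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0))
  hs <- new_hap_set(m, tibble::tibble(chrom = "chr1", pos = c(100L, 101L)),
                    tibble::tibble(sample = c("a", "b")),
                    c("a", "a", "b", "b"))
  ld <- ld_decay(hs, maf = 0.01, bin_width = 10)
  expect_equal(ld$mean_r2, 1)
  # hand case: haplotypes (0,0),(0,1),(1,0),(1,1) -> D = 0 -> r2 = 0
  m2 <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  hs2 <- new_hap_set(m2, tibble::tibble(chrom = "chr1", pos = c(1L, 500L)),
                     tibble::tibble(sample = c("a", "b")),
                     c("a", "a", "b", "b"))
  ld2 <- ld_decay(hs2, maf = 0.01, bin_width = 1000)
  expect_equal(ld2$mean_r2, 0)
  # D^2/(p1 q1 p2 q2) on an associated table: (0,0)x2, (1,1)x2
  m3 <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  hs3 <- new_hap_set(m3, tibble::tibble(chrom = "chr1", pos = c(1L, 500L)),
                     tibble::tibble(sample = c("a", "b")),
                     c("a", "a", "b", "b"))
  # p1 = p2 = 0.5, p11 = 0.5, D = 0.25, r2 = 0.0625/0.0625 = 1
  expect_equal(ld_decay(hs3, bin_width = 1000)$mean_r2, 1)
})

test_that("unlinked sites show r2 near the 1/n sampling floor", {
  set.seed(46)
  n <- 100
  m <- random_hap_matrix(n, 200, p = runif(200, 0.2, 0.8))
  hs <- new_hap_set(m, tibble::tibble(chrom = "chr1",
                                      pos = sort(sample.int(1e6, 200))),
                    tibble::tibble(sample = paste0("s", 1:(n / 2))),
                    rep(paste0("s", 1:(n / 2)), each = 2))
  ld <- ld_decay(hs, maf = 0.05)
  overall <- sum(ld$mean_r2 * ld$n_pairs) / sum(ld$n_pairs)
  expect_lt(abs(overall - 1 / n), 0.5 / n)
})

test_that("composite classifier flags extreme-D, low-Fst windows", {
  tw <- tibble::tibble(chrom = "chr1",
                       start = as.integer(seq(0, 19e5, 1e5)),
                       end = as.integer(seq(1e5, 20e5, 1e5)),
                       tajima_d = c(3, -3, rep(0.1, 18)))
  fw <- tibble::tibble(chrom = tw$chrom, start = tw$start, end = tw$end,
                       fst = c(0.01, 0.5, 0.02, rep(0.3, 17)))
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          start = 50L, end = 500L)
  cc <- composite_selection(tw, fw, genes = genes)
  expect_equal(cc$tajima_class[1], "positive_extreme")
  expect_equal(cc$tajima_class[2], "negative_extreme")
  expect_equal(cc$fst_class[1], "significantly_low")
  expect_equal(cc$label[1], "purifying_expansion")
  expect_equal(cc$label[2], "neutral") # extreme D but Fst not low
  expect_true(cc$genic[1])
  expect_false(any(cc$genic[-1]))
  expect_true(all(cc$label[4:20] == "neutral"))
})

test_that("a simulated sweep depresses Tajima's D in the swept window", {
  hits <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = 100 + s, n_populations = 1, pop_sizes = 50,
                      divergence = 0, chrom_length = 1e6, n_sites = 2000,
                      spectrum = "neutral",
                      sweep_specs = data.frame(population = "bicolor",
                                               chrom = "chr1", pos = 5e5,
                                               strength = 0.9),
                      sweep_width = 5e4)
    hp <- simulate_haplotypes(simulate_frequencies(cfg), cfg)
    td <- tajimas_d(hp$hap, window_size = 5e4)
    lo <- quantile(td$tajima_d, 0.1, na.rm = TRUE)
    swept <- td$tajima_d[td$start == 475000 | td$start == 500000]
    any(swept <= lo)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
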