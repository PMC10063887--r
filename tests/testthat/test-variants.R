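# 4-site toy: one failure per filter criterion plus one clean site
filter_toy <- function() {
  gt <- rbind(c("0/1", "0/1", "0/1", "0/0"),  # clean
              c("0/0", "0/0", "0/0", "0/1"),  # MAF 0.125 but QUAL 19
              c("0/1", "0/0", "0/1", "0/0"),  # mean DP 1 < 2
              c("0/0", "0/0", "0/0", "0/0"))  # monomorphic: MAF 0
  dp <- rbind(rep(10, 4), rep(10, 4), rep(1, 4), rep(10, 4))
  toy_vcf(chrom = rep("chr1", 4), pos = c(100L, 200L, 300L, 400L),
          ref = rep("A", 4), alt = rep("G", 4),
          qual = c(50, 19, 50, 50), gt = gt, dp = dp)
}

test_that("each filter criterion drops its failing site, leaving the clean one", {
  v <- filter_toy()
  f <- filter_sites(v)
  expect_equal(nrow(f$sites), 1)
  expect_equal(f$sites$pos, 100L)
  log <- attr(f, "drop_log")
  expect_equal(log$reason[log$pos == 200], "qual")
  expect_equal(log$reason[log$pos == 300], "mean_dp")
  expect_equal(log$reason[log$pos == 400], "maf")
})

test_that("filter boundaries are inclusive (>=) and QUAL 19 fails minQ 20", {
  # MAF exactly 0.01 kept, 0.005 dropped (1000 alleles)
  n <- 500
  gt <- rbind(c(rep("0/1", 10), rep("0/0", n - 10)), # MAF 0.01
              c(rep("0/1", 5), rep("0/0", n - 5)))   # MAF 0.005
  dp <- matrix(10, 2, n)
  v <- toy_vcf(chrom = rep("chr1", 2), pos = c(1L, 2L),
               ref = rep("A", 2), alt = rep("G", 2),
               qual = c(20, 20), gt = gt, dp = dp)
  f <- filter_sites(v)
  expect_equal(f$sites$pos, 1L)
  # QUAL exactly 20 passes (first site above); 19 fails
  v2 <- filter_toy()
  expect_false(200L %in% filter_sites(v2)$sites$pos)
})

test_that("filtering is idempotent", {
  f1 <- filter_sites(filter_toy())
  f2 <- filter_sites(f1)
  expect_identical(f1$sites, f2$sites)
  expect_identical(f1$gt, f2$gt)
  expect_equal(nrow(attr(f2, "drop_log")), 0)
})

test_that("ts/tv classification matches the canonical pairings", {
  gt <- matrix("0/1", 3, 2)
  v <- toy_vcf(chrom = rep("chr1", 3), pos = 1:3,
               ref = c("A", "C", "A"), alt = c("G", "T", "C"),
               qual = rep(50, 3), gt = gt)
  r <- tstv(v)
  expect_equal(r$transitions, 2)
  expect_equal(r$transversions, 1)
  expect_equal(r$ratio, 2)
  # all-transition input: infinity sentinel
  v2 <- toy_vcf(chrom = "chr1", pos = 1L, ref = "C", alt = "T",
                qual = 50, gt = matrix("0/1", 1, 2))
  expect_equal(tstv(v2)$ratio, Inf)
})

test_that("ts/tv on a random panel matches an independent tally", {
  set.seed(31)
  n <- 1000
  ref <- sample(c("A", "C", "G", "T"), n, TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  v <- toy_vcf(chrom = rep("chr1", n), pos = seq_len(n), ref = ref, alt = alt,
               qual = rep(50, n), gt = matrix("0/1", n, 2))
  r <- tstv(v)
  want_ts <- sum((ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
                   (ref == "C" & alt == "T") | (ref == "T" & alt == "C"))
  expect_equal(r$transitions, want_ts)
  expect_equal(r$transversions, n - want_ts)
})

test_that("MAF spectrum uses half-open bins and excludes monomorphic sites", {
  # 3 alt alleles of 20 -> MAF 0.15 -> (0.1, 0.2]
  gt <- rbind(c(rep("0/1", 3), rep("0/0", 7)),
              rep("0/0", 10),                  # monomorphic
              c(rep("1/1", 2), rep("0/0", 8)), # MAF 0.2 -> (0.1,0.2]
              c("0/1", rep("0/0", 9)))         # MAF 0.05 -> (0,0.1]
  v <- toy_vcf(chrom = rep("chr1", 4), pos = 1:4, ref = rep("A", 4),
               alt = rep("G", 4), qual = rep(50, 4), gt = gt)
  sp <- maf_spectrum(v)
  expect_equal(sp$n_sites, c(1L, 2L, 0L))
  expect_equal(sum(sp$n_sites), 3) # polymorphic sites only
})

test_that("race-specific SNPs and their confidence tiers follow carrier support", {
  n_a <- 15; n_b <- 15
  groups <- tibble::tibble(sample = paste0("s", 1:(n_a + n_b)),
                           group = rep(c("A", "B"), c(n_a, n_b)))
  gt <- rbind(c(rep("0/1", 12), rep("0/0", 3), rep("0/0", n_b)), # 12 carriers, A only
              c(rep("0/1", 2), rep("0/0", 13), rep("0/0", n_b)), # 2 carriers, A only
              c(rep("0/1", 6), rep("0/0", 9), rep("0/0", n_b)),  # 6 carriers, A only
              c(rep("0/1", 3), rep("0/0", 12), c("0/1", rep("0/0", n_b - 1))))
  v <- toy_vcf(chrom = rep("chr1", 4), pos = 1:4, ref = rep("A", 4),
               alt = rep("G", 4), qual = rep(50, 4), gt = gt)
  rs <- race_specific_snps(v, groups)
  expect_equal(nrow(rs), 3) # site 4 spans two groups
  expect_equal(rs$tier[rs$pos == 1], "high")  # > 10 carriers
  expect_equal(rs$tier[rs$pos == 2], "low")   # < 5 carriers
  expect_equal(rs$tier[rs$pos == 3], "mid")
  expect_true(all(rs$group == "A"))
})

# one plus-strand and one minus-strand single-CDS gene on a tiny contig
effect_fixture <- function() {
  # + gene CDS: ATG GGA TAT TGG TAA at 1-based 11..25
  plus_cds <- "ATGGGATATTGGTAA"
  # - gene: CDS on minus strand at 1-based 41..55; genomic = revcomp(CDS)
  minus_cds <- "ATGCCTTACTGGTAG"
  genome <- paste0(strrep("C", 10), plus_cds, strrep("C", 15),
                   revcomp(minus_cds), strrep("C", 10))
  ref <- c(chr1 = genome)
  genes <- tibble::tibble(
    gene_id = c("gplus", "gminus"), chrom = "chr1",
    start = c(10L, 40L), end = c(25L, 55L), strand = c("+", "-"),
    cds = list(tibble::tibble(start = 10L, end = 25L, phase = 0L),
               tibble::tibble(start = 40L, end = 55L, phase = 0L)))
  list(ref = ref, genes = genes)
}

test_that("codon rewrites classify effects on the plus strand", {
  fx <- effect_fixture()
  # GGA->GGG synonymous (pos 16 A->G); TAT->TAA stop gained (pos 19 T->A);
  # ATG->ATA start lost (pos 13 G->A); intergenic at pos 5
  v <- toy_vcf(chrom = rep("chr1", 4), pos = c(16L, 19L, 13L, 5L),
               ref = c("A", "T", "G", "C"), alt = c("G", "A", "A", "T"),
               qual = rep(50, 4), gt = matrix("0/1", 4, 2))
  eff <- annotate_effects(v, fx$ref, fx$genes)
  expect_equal(eff$effect[eff$pos == 16], "synonymous")
  expect_equal(eff$impact[eff$pos == 16], "low")
  expect_equal(eff$effect[eff$pos == 19], "stop_gained")
  expect_equal(eff$impact[eff$pos == 19], "high")
  expect_equal(eff$effect[eff$pos == 13], "start_lost")
  expect_equal(eff$effect[eff$pos == 5], "intergenic")
  expect_equal(eff$impact[eff$pos == 5], "modifier")
  expect_equal(sum(attr(eff, "impact_tally")$n_snps), nrow(eff))
})

test_that("minus-strand annotation matches the equivalent plus-strand change", {
  fx <- effect_fixture()
  # minus CDS codon2 CCT -> CCC (synonymous): genomic base is the
  # complement at the mirrored position. CDS pos 6 (T) sits at genomic
  # 41-based offset: CDS i maps to genomic pos 55 - i + 1 = 50
  v <- toy_vcf(chrom = "chr1", pos = 50L, ref = "A", alt = "G",
               qual = 50, gt = matrix("0/1", 1, 2))
  eff <- annotate_effects(v, fx$ref, fx$genes)
  expect_equal(eff$effect, "synonymous") # CCT -> CCC on the minus strand
  # stop lost: minus CDS TAG (codon 5, CDS pos 13..15); genomic pos 43..41
  # change CDS pos 15 G->T (TAG->TAT): genomic pos 41, ref C, alt A
  v2 <- toy_vcf(chrom = "chr1", pos = 41L, ref = "C", alt = "A",
                qual = 50, gt = matrix("0/1", 1, 2))
  eff2 <- annotate_effects(v2, fx$ref, fx$genes)
  expect_equal(eff2$effect, "stop_lost")
  expect_equal(eff2$impact, "high")
})

test_that("ka/ks ratio and glance summarize the annotation", {
  fx <- effect_fixture()
  v <- toy_vcf(chrom = rep("chr1", 2), pos = c(16L, 20L),
               ref = c("A", "T"), alt = c("G", "C"),
               qual = rep(50, 2), gt = matrix("0/1", 2, 2))
  eff <- annotate_effects(v, fx$ref, fx$genes) # TGG->CGG non-synonymous
  g <- glance(eff)
  expect_equal(g$n_synonymous, 1)
  expect_equal(g$n_non_synonymous, 1)
  expect_equal(g$ka_ks, 1)
})
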