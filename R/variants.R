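#' Per-site summaries used by the filters
#'
#' @param vcf A `race_vcf`.
#' @return Tibble with `chrom`, `pos`, `maf` (minor-allele frequency over
#'   non-missing alleles), `mean_dp` (mean depth over non-missing
#'   samples), `qual`.
#' @export
site_summaries <- function(vcf) {
  dos <- vcf_dosage(vcf)
  n_alleles <- 2 * rowSums(!is.na(dos))
  alt_f <- rowSums(dos, na.rm = TRUE) / pmax(n_alleles, 1)
  maf <- pmin(alt_f, 1 - alt_f)
  mean_dp <- rowMeans(vcf$dp, na.rm = TRUE)
  tibble::tibble(chrom = vcf$sites$chrom, pos = vcf$sites$pos, maf = maf,
                 mean_dp = ifelse(is.nan(mean_dp), NA_real_, mean_dp),
                 qual = vcf$sites$qual)
}

#' Filter sites on MAF, mean depth and quality
#'
#' A site is kept iff `MAF >= maf` AND mean depth over non-missing
#' samples `>= min_mean_dp` AND `QUAL >= min_q` — the standard
#' hard-filter combination (defaults `maf 0.01 min-meanDP 2 minQ 20`)
#' with vcftools-style inclusive (`>=`) boundaries. The operation is
#' idempotent: filtering a filtered set changes nothing.
#'
#' @param vcf A `race_vcf`.
#' @param maf Minimum minor-allele frequency.
#' @param min_mean_dp Minimum mean per-sample depth.
#' @param min_q Minimum site QUAL.
#' @return Filtered `race_vcf`; attribute `drop_log` is a tibble
#'   (`chrom`, `pos`, `reason`) recording the first failing criterion per
#'   dropped site, in the order maf, depth, quality.
#' @export
filter_sites <- function(vcf, maf = 0.01, min_mean_dp = 2, min_q = 20) {
  ss <- site_summaries(vcf)
  fail_maf <- ss$maf < maf
  fail_dp <- is.na(ss$mean_dp) | ss$mean_dp < min_mean_dp
  fail_q <- is.na(ss$qual) | ss$qual < min_q
  reason <- dplyr::case_when(fail_maf ~ "maf",
                             fail_dp ~ "mean_dp",
                             fail_q ~ "qual",
                             TRUE ~ NA_character_)
  keep <- is.na(reason)
  out <- new_vcf(vcf$sites[keep, ], vcf$gt[keep, , drop = FALSE],
                 vcf$dp[keep, , drop = FALSE], vcf$samples)
  attr(out, "drop_log") <- tibble::tibble(chrom = ss$chrom[!keep],
                                          pos = ss$pos[!keep],
                                          reason = reason[!keep])
  out
}

#' Transition/transversion ratio
#'
#' A<->G and C<->T substitutions are transitions; the four other pairings
#' are transversions.
#'
#' @param vcf A `race_vcf` of biallelic SNPs.
#' @return Named list with `transitions`, `transversions`, `ratio`
#'   (`Inf` when there are no transversions).
#' @export
tstv <- function(vcf) {
  s <- vcf$sites
  snp <- nchar(s$ref) == 1 & nchar(s$alt) == 1 &
    s$ref %in% c("A", "C", "G", "T") & s$alt %in% c("A", "C", "G", "T")
  pair <- paste(pmin(s$ref[snp], s$alt[snp]), pmax(s$ref[snp], s$alt[snp]))
  ts <- sum(pair %in% c("A G", "C T"))
  tv <- sum(snp) - ts
  list(transitions = ts, transversions = tv,
       ratio = if (tv == 0) Inf else ts / tv)
}

#' Minor-allele-frequency spectrum
#'
#' MAF is computed over non-missing alleles (optionally within a sample
#' subset) and binned into the half-open classes (0, 0.1], (0.1, 0.2],
#' (0.2, 0.5]; monomorphic sites are excluded, so counts sum to the
#' number of polymorphic sites.
#'
#' @param vcf A `race_vcf`.
#' @param samples Optional character vector restricting the computation.
#' @return Tibble with `bin`, `n_sites`.
#' @export
maf_spectrum <- function(vcf, samples = NULL) {
  dos <- vcf_dosage(vcf)
  if (!is.null(samples)) dos <- dos[, samples, drop = FALSE]
  n_alleles <- 2 * rowSums(!is.na(dos))
  alt_f <- rowSums(dos, na.rm = TRUE) / pmax(n_alleles, 1)
  maf <- pmin(alt_f, 1 - alt_f)
  maf <- maf[maf > 0]
  bin <- cut(maf, breaks = c(0, 0.1, 0.2, 0.5),
             labels = c("(0,0.1]", "(0.1,0.2]", "(0.2,0.5]"))
  out <- tibble::tibble(bin = factor(c("(0,0.1]", "(0.1,0.2]", "(0.2,0.5]"),
                                     levels = levels(bin)))
  dplyr::left_join(out, dplyr::count(tibble::tibble(bin = bin), .data$bin,
                                     name = "n_sites"),
                   by = "bin") |>
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L))
}

#' Group-specific (race-specific) SNPs
#'
#' A site is specific to a group iff every carrier of its minor allele
#' belongs to that group. Confidence tiers follow carrier support:
#' `high` with more than 10 carrier accessions, `low` with fewer than 5,
#' `mid` otherwise.
#'
#' @param vcf A `race_vcf`.
#' @param groups Tibble with `sample`, `group` (>= 2 groups).
#' @return Tibble with `chrom`, `pos`, `group`, `carriers`, `tier`.
#' @export
race_specific_snps <- function(vcf, groups) {
  stopifnot(dplyr::n_distinct(groups$group) >= 2)
  dos <- vcf_dosage(vcf)[, groups$sample, drop = FALSE]
  grp <- groups$group
  n_alleles <- 2 * rowSums(!is.na(dos))
  alt_f <- rowSums(dos, na.rm = TRUE) / pmax(n_alleles, 1)
  minor_is_alt <- alt_f <= 0.5
  purrr::map_dfr(seq_len(nrow(dos)), function(i) {
    d <- dos[i, ]
    carrier <- if (minor_is_alt[i]) !is.na(d) & d > 0 else !is.na(d) & d < 2
    if (!any(carrier)) return(NULL)
    g <- unique(grp[carrier])
    if (length(g) != 1) return(NULL)
    nc <- sum(carrier)
    tibble::tibble(chrom = vcf$sites$chrom[i], pos = vcf$sites$pos[i],
                   group = g, carriers = nc,
                   tier = if (nc > 10) "high" else if (nc < 5) "low" else "mid")
  })
}

#' Codon-level SNP effect annotation
#'
#' A minimal effect annotator: each biallelic SNP is classified as
#' `synonymous`, `non_synonymous`, `start_lost`, `stop_gained`,
#' `stop_lost` (inside CDS, by rewriting the codon with the alternate
#' allele, respecting strand and phase), `intronic` (inside a gene but
#' outside CDS) or `intergenic`. Impact follows the usual mapping:
#' high = start/stop changes, moderate = non-synonymous,
#' low = synonymous, modifier = non-coding.
#'
#' @param vcf A `race_vcf` of SNPs.
#' @param reference Named character vector of reference sequences.
#' @param genes Gene-model tibble ([read_gene_models()] layout).
#' @return Tibble of class `effect_calls` with `chrom`, `pos`, `ref`,
#'   `alt`, `gene_id`, `effect`, `impact`; attributes `ka_ks`
#'   (non-synonymous / synonymous count ratio), `impact_tally` and
#'   `skipped` (sites flagged for reference inconsistencies).
#' @export
annotate_effects <- function(vcf, reference, genes) {
  skipped <- tibble::tibble(chrom = character(), pos = integer(),
                            reason = character())
  rows <- purrr::map_dfr(seq_len(nrow(vcf$sites)), function(i) {
    s <- vcf$sites[i, ]
    if (nchar(s$ref) != 1 || nchar(s$alt) != 1) return(NULL)
    g <- genes[genes$chrom == s$chrom & genes$start < s$pos &
                 genes$end >= s$pos, ]
    if (nrow(g) == 0)
      return(tibble::tibble(chrom = s$chrom, pos = s$pos, ref = s$ref,
                            alt = s$alt, gene_id = NA_character_,
                            effect = "intergenic", impact = "modifier"))
    g <- g[1, ]
    cls <- classify_cds_variant(s, g, reference)
    if (is.null(cls)) {
      skipped <<- dplyr::bind_rows(skipped, tibble::tibble(
        chrom = s$chrom, pos = s$pos, reason = "reference_inconsistent"))
      return(NULL)
    }
    tibble::tibble(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                   gene_id = g$gene_id, effect = cls$effect,
                   impact = cls$impact)
  })
  n_syn <- sum(rows$effect == "synonymous")
  n_non <- sum(rows$effect == "non_synonymous")
  attr(rows, "ka_ks") <- if (n_syn > 0) n_non / n_syn else NA_real_
  attr(rows, "impact_tally") <- dplyr::count(rows, .data$impact,
                                             name = "n_snps")
  attr(rows, "skipped") <- skipped
  class(rows) <- c("effect_calls", class(rows))
  rows
}

# classify one SNP against one gene model; NULL flags an inconsistent or
# untranslatable reference CDS
classify_cds_variant <- function(s, g, reference) {
  cds <- g$cds[[1]]
  in_cds <- any(cds$start < s$pos & cds$end >= s$pos)
  if (!in_cds)
    return(list(effect = "intronic", impact = "modifier"))
  cds <- cds[order(cds$start), ]
  coords <- unlist(purrr::map2(cds$start, cds$end, ~ seq(.x + 1L, .y)))
  refseq <- strsplit(reference[[g$chrom]], "")[[1]]
  base_at <- refseq[coords]
  if (base_at[match(s$pos, coords)] != s$ref) return(NULL)
  minus <- g$strand == "-"
  if (minus) {
    coords <- rev(coords)
    base_at <- strsplit(cpp_revcomp(paste(base_at, collapse = "")), "")[[1]]
  }
  phase <- if (minus) cds$phase[nrow(cds)] else cds$phase[1]
  if (phase > 0) {
    coords <- coords[-seq_len(phase)]
    base_at <- base_at[-seq_len(phase)]
  }
  cpos <- match(s$pos, coords)
  codon_i <- (cpos - 1) %/% 3
  if ((codon_i + 1) * 3 > length(base_at)) return(NULL)
  codon <- base_at[codon_i * 3 + 1:3]
  alt_base <- if (minus) cpp_revcomp(s$alt) else s$alt
  codon_alt <- codon
  codon_alt[cpos - codon_i * 3] <- alt_base
  code <- Biostrings::GENETIC_CODE
  aa_ref <- code[[paste(codon, collapse = "")]]
  aa_alt <- code[[paste(codon_alt, collapse = "")]]
  if (is.null(aa_ref) || is.null(aa_alt)) return(NULL)
  # internal stop in the reference frame: flag and skip
  n_codons <- length(base_at) %/% 3
  if (codon_i > 0 && codon_i < n_codons - 1) {
    first_codons <- vapply(seq_len(codon_i), function(j)
      paste(base_at[(j - 1) * 3 + 1:3], collapse = ""), character(1))
    if (any(code[first_codons] == "*")) return(NULL)
  }
  effect <- if (codon_i == 0 && paste(codon, collapse = "") == "ATG" &&
                paste(codon_alt, collapse = "") != "ATG") "start_lost"
  else if (aa_ref != "*" && aa_alt == "*") "stop_gained"
  else if (aa_ref == "*" && aa_alt != "*") "stop_lost"
  else if (aa_ref == aa_alt) "synonymous"
  else "non_synonymous"
  impact <- switch(effect,
                   start_lost = , stop_gained = , stop_lost = "high",
                   non_synonymous = "moderate",
                   synonymous = "low")
  list(effect = effect, impact = impact)
}

#' @export
glance.effect_calls <- function(x, ...) {
  tibble::tibble(
    n_annotated = nrow(x),
    n_synonymous = sum(x$effect == "synonymous"),
    n_non_synonymous = sum(x$effect == "non_synonymous"),
    ka_ks = attr(x, "ka_ks"),
    n_high = sum(x$impact == "high"),
    n_skipped = nrow(attr(x, "skipped"))
  )
}
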