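#' Extended haplotype homozygosity from a focal site
#'
#' Among the `n_c` carriers of the chosen allele at the focal site,
#' `EHH(x)` is the probability that two randomly drawn carriers are
#' identical over the whole stretch from the focal site out to site `x`:
#' `sum_h C(n_h, 2) / C(n_c, 2)` over distinct extended haplotypes `h`.
#' EHH is 1 at the focal site and monotone non-increasing moving away.
#'
#' @param hap A `hap_set` or 0/1 haplotype matrix.
#' @param focal Focal site index (column).
#' @param allele `"derived"` (1) or `"ancestral"` (0); ignored when
#'   `carriers` is given.
#' @param carriers Optional explicit haplotype (row) indices.
#' @return Tibble with `site`, `pos`, `ehh`, `focal` (logical); `ehh` is
#'   all-NA when there are fewer than 2 carriers (site undefined).
#' @export
ehh <- function(hap, focal, allele = c("derived", "ancestral"),
                carriers = NULL) {
  allele <- match.arg(allele)
  m <- if (inherits(hap, "hap_set")) hap$haplotypes else hap
  pos <- if (inherits(hap, "hap_set")) hap$sites$pos else seq_len(ncol(m))
  if (is.null(carriers))
    carriers <- which(m[, focal] == (if (allele == "derived") 1L else 0L))
  e <- cpp_ehh(m, as.integer(focal), as.integer(carriers))
  tibble::tibble(site = seq_len(ncol(m)), pos = pos, ehh = e,
                 focal = seq_len(ncol(m)) == focal)
}

#' Integrated EHH (iHH)
#'
#' Trapezoid-rule area under the EHH decay curve over bp distance,
#' accumulated outward from the focal site on each side and truncated at
#' the first site where EHH drops below `cutoff` (the segment reaching
#' that site is included); the two sides are summed.
#'
#' @param ehh_tbl An [ehh()] tibble (`pos`, `ehh`, `focal`).
#' @param cutoff EHH truncation threshold (default 0.05).
#' @return iHH in bp x homozygosity units (NA when EHH is undefined).
#' @export
ihh <- function(ehh_tbl, cutoff = 0.05) {
  if (all(is.na(ehh_tbl$ehh))) return(NA_real_)
  fi <- which(ehh_tbl$focal)
  total <- 0
  for (idx in list(rev(seq_len(fi)), seq(fi, nrow(ehh_tbl)))) {
    e <- ehh_tbl$ehh[idx]
    p <- ehh_tbl$pos[idx]
    if (length(idx) < 2) next
    for (j in 2:length(idx)) {
      total <- total + abs(p[j] - p[j - 1]) * (e[j] + e[j - 1]) / 2
      if (e[j] < cutoff) break
    }
  }
  total
}

# iHH for a carrier set, short-circuiting the curve computation
ihh_for <- function(m, pos, focal, carriers, cutoff) {
  if (length(carriers) < 2) return(NA_real_)
  e <- cpp_ehh(m, as.integer(focal), as.integer(carriers), cutoff)
  ihh(tibble::tibble(pos = pos, ehh = e,
                     focal = seq_along(pos) == focal), cutoff)
}

#' iHS scan
#'
#' For each site with minor allele frequency `>= min_maf`, the raw score
#' is `ln(iHH_A / iHH_D)` (ancestral over derived carriers; 0 is coded
#' ancestral, so polarity must be supplied by the caller's coding — the
#' simulator provides truth polarity, reference-as-ancestral otherwise).
#' Raw scores are standardized within derived-allele-frequency bins
#' (`n_bins` equal-width bins; bins holding fewer than `min_bin` sites
#' are merged with their neighbor) and `p = 2 Phi(-|z|)`.
#'
#' @param hap A `hap_set` (one population) or 0/1 matrix.
#' @param min_maf Minimum focal minor-allele frequency.
#' @param cutoff EHH truncation threshold for iHH.
#' @param n_bins Number of frequency bins for standardization.
#' @param min_bin Minimum sites per bin before merging.
#' @return Tibble of class `scan_scores` with `site`, `chrom`, `pos`,
#'   `daf`, `ihh_a`, `ihh_d`, `raw`, `score` (standardized), `p_value`.
#'   Sites with undefined or zero iHH on either allele are excluded
#'   (flagged in attribute `excluded`).
#' @export
ihs <- function(hap, min_maf = 0.05, cutoff = 0.05, n_bins = 50,
                min_bin = 10) {
  m <- if (inherits(hap, "hap_set")) hap$haplotypes else hap
  sites <- if (inherits(hap, "hap_set")) hap$sites else
    tibble::tibble(chrom = "chr1", pos = seq_len(ncol(m)))
  daf <- colMeans(m)
  # EHH extension never crosses a chromosome boundary
  res <- purrr::map_dfr(unique(sites$chrom), function(ch) {
    cols <- which(sites$chrom == ch)
    mc <- m[, cols, drop = FALSE]
    pc <- as.numeric(sites$pos[cols])
    use <- which(pmin(daf[cols], 1 - daf[cols]) >= min_maf)
    ia <- id <- rep(NA_real_, length(use))
    for (u in seq_along(use)) {
      j <- use[u]
      ia[u] <- cpp_ihh(mc, j, which(mc[, j] == 0L), pc, cutoff)
      id[u] <- cpp_ihh(mc, j, which(mc[, j] == 1L), pc, cutoff)
    }
    tibble::tibble(site = cols[use], chrom = ch, pos = sites$pos[cols[use]],
                   daf = daf[cols[use]], ihh_a = ia, ihh_d = id)
  })
  bad <- is.na(res$ihh_a) | is.na(res$ihh_d) | res$ihh_a == 0 | res$ihh_d == 0
  excluded <- res[bad, ]
  res <- res[!bad, ]
  res$raw <- log(res$ihh_a / res$ihh_d)
  res$bin <- freq_bins(res$daf, n_bins, min_bin)
  res <- dplyr::mutate(dplyr::group_by(res, .data$bin),
                       score = (.data$raw - mean(.data$raw)) /
                         sd(.data$raw),
                       .keep = "all")
  res <- dplyr::ungroup(res)
  res$p_value <- 2 * pnorm(-abs(res$score))
  attr(res, "method") <- "iHS"
  attr(res, "excluded") <- excluded
  class(res) <- c("scan_scores", class(res))
  res
}

# equal-width frequency bins on [0,1]; bins with < min_bin members are
# merged into their left (else right) neighbor until all are full enough
freq_bins <- function(f, n_bins, min_bin) {
  b <- pmin(floor(f * n_bins), n_bins - 1)
  repeat {
    tab <- table(b)
    small <- names(tab)[tab < min_bin]
    if (length(small) == 0 || length(tab) == 1) break
    s <- as.numeric(small[1])
    others <- setdiff(as.numeric(names(tab)), s)
    nearest <- others[which.min(abs(others - s))]
    b[b == s] <- nearest
  }
  b
}

#' XP-EHH scan
#'
#' Cross-population test: per shared site,
#' `raw = ln(iHH_pop1 / iHH_pop2)` where each iHH integrates the
#' all-haplotype EHH of one population; scores are standardized
#' genome-wide. Positive values mean longer extended haplotypes (a sweep
#' signal) in `pop1`; swapping the populations negates the scores
#' exactly.
#'
#' @param hap1,hap2 `hap_set`s (or matrices) on the same sites.
#' @param cutoff EHH truncation threshold.
#' @return Tibble of class `scan_scores` with `site`, `chrom`, `pos`,
#'   `ihh1`, `ihh2`, `raw`, `score`, `p_value`.
#' @export
xpehh <- function(hap1, hap2, cutoff = 0.05) {
  m1 <- if (inherits(hap1, "hap_set")) hap1$haplotypes else hap1
  m2 <- if (inherits(hap2, "hap_set")) hap2$haplotypes else hap2
  stopifnot(ncol(m1) == ncol(m2))
  sites <- if (inherits(hap1, "hap_set")) hap1$sites else
    tibble::tibble(chrom = "chr1", pos = seq_len(ncol(m1)))
  res <- purrr::map_dfr(unique(sites$chrom), function(ch) {
    cols <- which(sites$chrom == ch)
    mc1 <- m1[, cols, drop = FALSE]
    mc2 <- m2[, cols, drop = FALSE]
    pc <- as.numeric(sites$pos[cols])
    i1 <- i2 <- rep(NA_real_, length(cols))
    for (j in seq_along(cols)) {
      i1[j] <- cpp_ihh(mc1, j, seq_len(nrow(mc1)), pc, cutoff)
      i2[j] <- cpp_ihh(mc2, j, seq_len(nrow(mc2)), pc, cutoff)
    }
    tibble::tibble(site = cols, chrom = ch, pos = sites$pos[cols],
                   ihh1 = i1, ihh2 = i2)
  })
  bad <- is.na(res$ihh1) | is.na(res$ihh2) | res$ihh1 == 0 | res$ihh2 == 0
  excluded <- res[bad, ]
  res <- res[!bad, ]
  res$raw <- log(res$ihh1 / res$ihh2)
  res$score <- (res$raw - mean(res$raw)) / sd(res$raw)
  res$p_value <- 2 * pnorm(-abs(res$score))
  attr(res, "method") <- "XP-EHH"
  attr(res, "excluded") <- excluded
  class(res) <- c("scan_scores", class(res))
  res
}

#' Multiple-testing correction for scan scores
#'
#' Benjamini-Hochberg step-up (default) or Bonferroni family-wise
#' correction; the chosen procedure is recorded in the result's
#' `correction` attribute.
#'
#' @param scores A `scan_scores` tibble (needs `p_value`), or any tibble
#'   with a `p_value` column.
#' @param method `"BH"` or `"bonferroni"`.
#' @param alpha Significance level for the `significant` flag.
#' @return Input with `q_value` and `significant` columns added.
#' @export
scan_significance <- function(scores, method = c("BH", "bonferroni"),
                              alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(all(scores$p_value >= 0 & scores$p_value <= 1, na.rm = TRUE))
  scores$q_value <- p.adjust(scores$p_value, method = method)
  scores$significant <- !is.na(scores$q_value) & scores$q_value <= alpha
  attr(scores, "correction") <- method
  attr(scores, "alpha") <- alpha
  scores
}

#' Build sweep regions from significant scan sites
#'
#' Significant sites on the same chromosome within `merge_gap` bp of each
#' other are merged into one region (0-based half-open, spanning the
#' outermost significant sites). Genes are partitioned into those
#' overlapping the region and those within `near` bp of either flank.
#'
#' @param scores A [scan_significance()] result.
#' @param merge_gap Maximum gap in bp between significant sites in one
#'   region.
#' @param genes Optional gene-model tibble.
#' @param near Flanking distance in bp for `genes_near`.
#' @return Tibble with `chrom`, `start`, `end`, `n_sites`, `peak_score`,
#'   `genes_within`, `genes_near` (list-columns of gene ids).
#' @export
sweep_regions <- function(scores, merge_gap = 1e4, genes = NULL,
                          near = 5000) {
  if (!"significant" %in% names(scores))
    stop("run scan_significance() first")
  sig <- dplyr::arrange(dplyr::filter(scores, .data$significant),
                        .data$chrom, .data$pos)
  if (nrow(sig) == 0)
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_sites = integer(),
                          peak_score = double(), genes_within = list(),
                          genes_near = list()))
  sig <- dplyr::group_by(sig, .data$chrom)
  sig <- dplyr::mutate(sig, new_region = c(TRUE, diff(.data$pos) > merge_gap))
  sig <- dplyr::ungroup(sig)
  sig$region <- cumsum(sig$new_region)
  out <- dplyr::summarise(
    dplyr::group_by(sig, .data$region),
    chrom = .data$chrom[1],
    start = as.integer(min(.data$pos) - 1L),
    end = as.integer(max(.data$pos)),
    n_sites = dplyr::n(),
    peak_score = .data$score[which.max(abs(.data$score))],
    .groups = "drop")[, -1]
  out$genes_within <- vector("list", nrow(out))
  out$genes_near <- vector("list", nrow(out))
  if (!is.null(genes) && nrow(genes) > 0) {
    for (i in seq_len(nrow(out))) {
      g <- genes[genes$chrom == out$chrom[i], ]
      within <- g$start < out$end[i] & g$end > out$start[i]
      dist <- ifelse(g$start >= out$end[i], g$start - out$end[i],
                     ifelse(g$end <= out$start[i], out$start[i] - g$end, 0))
      near_flag <- !within & dist > 0 & dist <= near
      # abutting genes (dist 0, no overlap) count as near
      near_flag <- near_flag | (!within & dist == 0)
      out$genes_within[[i]] <- g$gene_id[within]
      out$genes_near[[i]] <- g$gene_id[near_flag]
    }
  }
  out
}
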