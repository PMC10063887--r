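#' Per-site nucleotide diversity
#'
#' The unbiased pairwise-difference form: with n non-missing alleles of
#' which `c_ref` are reference and `c_alt` alternate,
#' `pi = 2 c_ref c_alt / (n (n - 1))`. Windowed per-bp values are the sum
#' of per-site values divided by window length.
#'
#' @param vcf A `race_vcf`.
#' @param samples Optional sample subset.
#' @return Tibble with `chrom`, `pos`, `n_alleles`, `pi`.
#' @export
site_pi <- function(vcf, samples = NULL) {
  dos <- vcf_dosage(vcf)
  if (!is.null(samples)) dos <- dos[, samples, drop = FALSE]
  n <- 2 * rowSums(!is.na(dos))
  c_alt <- rowSums(dos, na.rm = TRUE)
  if (any(n < 2)) stop("site_pi() needs >= 2 non-missing alleles per site")
  pi <- 2 * c_alt * (n - c_alt) / (n * (n - 1))
  tibble::tibble(chrom = vcf$sites$chrom, pos = vcf$sites$pos,
                 n_alleles = n, pi = pi)
}

#' @rdname site_pi
#' @param window_size Window width in bp (non-overlapping).
#' @return `windowed_pi()`: tibble with `chrom`, `start`, `end` (0-based
#'   half-open), `n_sites`, `pi_sum`, `pi_bp` (per-bp diversity).
#' @export
windowed_pi <- function(vcf, window_size = 1e5, samples = NULL) {
  sp <- site_pi(vcf, samples)
  sp$start <- as.integer(((sp$pos - 1) %/% window_size) * window_size)
  out <- dplyr::summarise(dplyr::group_by(sp, .data$chrom, .data$start),
                          n_sites = dplyr::n(), pi_sum = sum(.data$pi),
                          .groups = "drop")
  dplyr::mutate(out, end = as.integer(.data$start + window_size),
                pi_bp = .data$pi_sum / window_size, .after = "start")
}

# Tajima (1989) normalizing constants for sample size n (haplotypes)
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D and window diversity statistics from haplotypes
#'
#' For each window: S segregating sites, theta_pi (mean pairwise
#' differences), theta_W = S / a1, and
#' `D = (theta_pi - theta_W) / sqrt(e1 S + e2 S (S - 1))` with the full
#' set of normalizing constants. Windows with S = 0 get `NA` (flagged,
#' excluded from scans).
#'
#' @param hap A `hap_set` (or 0/1 matrix via `tajima_stats()`).
#' @param window_size Window width in bp.
#' @return Tibble with `chrom`, `start`, `end`, `n_haplotypes`, `S`,
#'   `theta_pi`, `theta_w`, `tajima_d`.
#' @export
tajimas_d <- function(hap, window_size = 1e5) {
  stopifnot(inherits(hap, "hap_set"))
  sites <- hap$sites
  w <- as.integer(((sites$pos - 1) %/% window_size) * window_size)
  idx <- split(seq_len(nrow(sites)), list(sites$chrom, w), drop = TRUE)
  purrr::map_dfr(idx, function(ii) {
    st <- tajima_stats(hap$haplotypes[, ii, drop = FALSE])
    tibble::tibble(chrom = sites$chrom[ii[1]],
                   start = as.integer(((sites$pos[ii[1]] - 1) %/% window_size) *
                                        window_size),
                   n_haplotypes = nrow(hap$haplotypes),
                   S = st$S, theta_pi = st$theta_pi, theta_w = st$theta_w,
                   tajima_d = st$D)
  }) |>
    dplyr::mutate(end = as.integer(.data$start + window_size),
                  .after = "start") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' @rdname tajimas_d
#' @param m 0/1 haplotype matrix (haplotypes x sites) for one window.
#' @return `tajima_stats()`: list with `S`, `theta_pi`, `theta_w`, `D`.
#' @export
tajima_stats <- function(m) {
  n <- nrow(m)
  stopifnot(n >= 2)
  cnt <- colSums(m)
  seg <- cnt > 0 & cnt < n
  S <- sum(seg)
  theta_pi <- sum(2 * cnt[seg] * (n - cnt[seg])) / (n * (n - 1))
  k <- tajima_constants(n)
  theta_w <- S / k$a1
  D <- if (S == 0) NA_real_ else {
    num <- theta_pi - theta_w
    den <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
    # n = 2 degenerates to 0/0: the numerator is identically 0 there
    if (den == 0) (if (abs(num) < 1e-12) 0 else NA_real_) else num / den
  }
  list(S = S, theta_pi = theta_pi, theta_w = theta_w, D = D)
}

#' Per-site Weir-Cockerham Fst
#'
#' The two-level (population / individual) variance-components estimator
#' of Weir & Cockerham (1984), computed per site from per-population
#' sample sizes, allele frequencies and observed heterozygosities.
#' Negative estimates are reported as-is.
#'
#' @param vcf A `race_vcf`.
#' @param populations Tibble with `sample`, `population` (>= 2
#'   populations, each needing >= 2 non-missing diploids at a site for
#'   that site to be estimated).
#' @return Tibble with `chrom`, `pos`, `a`, `b`, `c`, `fst`
#'   (`a / (a + b + c)`, NA where the denominator is 0 or preconditions
#'   fail).
#' @export
wc_fst <- function(vcf, populations) {
  dos <- vcf_dosage(vcf)[, populations$sample, drop = FALSE]
  pop_idx <- split(seq_along(populations$sample), populations$population)
  r <- length(pop_idx)
  stopifnot(r >= 2)
  S <- nrow(dos)
  n_i <- p_i <- h_i <- matrix(0, S, r)
  for (k in seq_len(r)) {
    sub <- dos[, pop_idx[[k]], drop = FALSE]
    n_i[, k] <- rowSums(!is.na(sub))
    p_i[, k] <- rowSums(sub, na.rm = TRUE) / (2 * n_i[, k])
    h_i[, k] <- rowSums(sub == 1, na.rm = TRUE) / n_i[, k]
  }
  valid <- rowSums(n_i >= 2) == r
  nbar <- rowMeans(n_i)
  nc <- (r * nbar - rowSums(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n_i * p_i) / (r * nbar)
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- ifelse(denom == 0, NA_real_, a / denom)
  a[!valid] <- b[!valid] <- cc[!valid] <- fst[!valid] <- NA_real_
  dplyr::bind_cols(vcf$sites[, c("chrom", "pos")],
                   tibble::tibble(a = a, b = b, c = cc, fst = fst))
}

#' @rdname wc_fst
#' @param fst_tbl A per-site [wc_fst()] tibble.
#' @param window_size Window width in bp.
#' @return `wc_fst_windows()`: windowed ratio-of-sums Fst
#'   (`sum(a) / sum(a + b + c)` over sites in the window).
#' @export
wc_fst_windows <- function(fst_tbl, window_size = 1e5) {
  x <- dplyr::filter(fst_tbl, !is.na(.data$a))
  x$start <- as.integer(((x$pos - 1) %/% window_size) * window_size)
  dplyr::summarise(dplyr::group_by(x, .data$chrom, .data$start),
                   n_sites = dplyr::n(),
                   fst = sum(.data$a) / sum(.data$a + .data$b + .data$c),
                   .groups = "drop") |>
    dplyr::mutate(end = as.integer(.data$start + window_size),
                  .after = "start")
}

#' Ratio-of-sums Fst over all sites
#'
#' @param fst_tbl A per-site [wc_fst()] tibble.
#' @return Single number: `sum(a) / sum(a + b + c)` over estimable sites.
#' @export
wc_fst_overall <- function(fst_tbl) {
  x <- dplyr::filter(fst_tbl, !is.na(.data$a))
  sum(x$a) / sum(x$a + x$b + x$c)
}

#' LD decay: distance-binned mean r-squared
#'
#' r-squared is computed for all site pairs within `max_dist` on the same
#' chromosome, on haplotypes when the input is phased (a `hap_set`) and
#' on genotype dosages (Rogers-Huff style) for a `race_vcf`; the basis is
#' recorded in the `basis` attribute. No monotone smoothing is applied.
#'
#' @param x A `hap_set` or `race_vcf`.
#' @param maf Minimum minor-allele frequency for included sites.
#' @param max_dist Maximum pair distance in bp.
#' @param bin_width Distance bin width in bp.
#' @return Tibble with `dist_bin` (bin start), `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(x, maf = 0.01, max_dist = 2e6, bin_width = 5e4) {
  if (inherits(x, "hap_set")) {
    m <- x$haplotypes
    sites <- x$sites
    basis <- "haplotype"
  } else {
    m <- t(vcf_dosage(x))
    sites <- x$sites
    basis <- "dosage"
  }
  f <- colMeans(m, na.rm = TRUE) / (if (basis == "dosage") 2 else 1)
  keep <- pmin(f, 1 - f) >= maf
  m <- m[, keep, drop = FALSE]
  sites <- sites[keep, ]
  out <- purrr::map_dfr(unique(sites$chrom), function(ch) {
    ii <- which(sites$chrom == ch)
    if (length(ii) < 2) return(NULL)
    r2 <- suppressWarnings(cor(m[, ii, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    dist <- abs(outer(sites$pos[ii], sites$pos[ii], "-"))
    up <- upper.tri(r2)
    ok <- up & dist <= max_dist & !is.na(r2)
    tibble::tibble(dist = dist[ok], r2 = r2[ok])
  })
  out$dist_bin <- (out$dist %/% bin_width) * bin_width
  res <- dplyr::summarise(dplyr::group_by(out, .data$dist_bin),
                          mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
                          .groups = "drop")
  attr(res, "basis") <- basis
  res
}

#' Composite Tajima's-D x Fst selection classification
#'
#' Windows are classified by empirical quantiles: `tajima_class` is
#' `positive_extreme` / `negative_extreme` for the upper / lower
#' `d_tail` fraction of Tajima's D, else `neutral`; `fst_class` is
#' `significantly_low` for the bottom `fst_tail` fraction of windowed
#' Fst. Extreme-D windows that also sit in the low-Fst tail are labelled
#' `purifying_expansion` (the recent-population-expansion signature);
#' the raw D sign is retained so callers can alias labels as they see
#' fit. A `genic` flag marks windows intersecting any gene.
#'
#' @param tajima_windows A [tajimas_d()] tibble.
#' @param fst_windows A [wc_fst_windows()] tibble on the same windowing.
#' @param d_tail,fst_tail Tail fractions (defaults 0.05).
#' @param genes Optional gene-model tibble for the genic flag.
#' @return Tibble with window coordinates, `tajima_d`, `fst`,
#'   `tajima_class`, `fst_class`, `label`, `genic`.
#' @export
composite_selection <- function(tajima_windows, fst_windows,
                                d_tail = 0.05, fst_tail = 0.05,
                                genes = NULL) {
  x <- dplyr::inner_join(
    tajima_windows[, c("chrom", "start", "end", "tajima_d")],
    fst_windows[, c("chrom", "start", "end", "fst")],
    by = c("chrom", "start", "end"))
  d_lo <- quantile(x$tajima_d, d_tail, na.rm = TRUE)
  d_hi <- quantile(x$tajima_d, 1 - d_tail, na.rm = TRUE)
  f_lo <- quantile(x$fst, fst_tail, na.rm = TRUE)
  x <- dplyr::mutate(
    x,
    tajima_class = dplyr::case_when(
      is.na(.data$tajima_d) ~ NA_character_,
      .data$tajima_d >= d_hi ~ "positive_extreme",
      .data$tajima_d <= d_lo ~ "negative_extreme",
      TRUE ~ "neutral"),
    fst_class = dplyr::if_else(!is.na(.data$fst) & .data$fst <= f_lo,
                               "significantly_low", "other"),
    label = dplyr::if_else(
      !is.na(.data$tajima_class) & .data$tajima_class != "neutral" &
        .data$fst_class == "significantly_low",
      "purifying_expansion", "neutral"))
  x$genic <- FALSE
  if (!is.null(genes) && nrow(genes) > 0) {
    for (i in seq_len(nrow(x))) {
      x$genic[i] <- any(genes$chrom == x$chrom[i] &
                          genes$start < x$end[i] & genes$end > x$start[i])
    }
  }
  x
}
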