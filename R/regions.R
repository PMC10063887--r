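#' All overlapping interval pairs between two sets
#'
#' Intervals are 0-based half-open tibbles (`chrom`, `start`, `end`,
#' `name`); a pair is reported when it shares at least `min_bp` bases.
#' Matching is delegated to [IRanges::findOverlaps()]; output order and
#' content equal the all-pairs definition.
#'
#' @param a,b Interval tibbles.
#' @param min_bp Minimum shared bases (default 1).
#' @return Tibble with `chrom`, `name_a`, `name_b`, `start_a`, `end_a`,
#'   `start_b`, `end_b`, `overlap_bp`.
#' @export
interval_overlap <- function(a, b, min_bp = 1) {
  a <- normalize_intervals(a)
  b <- normalize_intervals(b)
  purrr::map_dfr(intersect(unique(a$chrom), unique(b$chrom)), function(ch) {
    ac <- a[a$chrom == ch, ]
    bc <- b[b$chrom == ch, ]
    ra <- IRanges::IRanges(ac$start + 1L, ac$end)
    rb <- IRanges::IRanges(bc$start + 1L, bc$end)
    h <- IRanges::findOverlaps(ra, rb, minoverlap = min_bp)
    i <- S4Vectors::queryHits(h)
    j <- S4Vectors::subjectHits(h)
    ov <- pmin(ac$end[i], bc$end[j]) - pmax(ac$start[i], bc$start[j])
    tibble::tibble(chrom = ch, name_a = ac$name[i], name_b = bc$name[j],
                   start_a = ac$start[i], end_a = ac$end[i],
                   start_b = bc$start[j], end_b = bc$end[j],
                   overlap_bp = ov)
  })
}

normalize_intervals <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)),
            all(x$start < x$end))
  if (!"name" %in% names(x))
    x$name <- paste0("iv", seq_len(nrow(x)))
  tibble::as_tibble(x)
}

#' Multi-set region sharing (Venn) tallies
#'
#' Regions from the named sets are clustered by reciprocal overlap: two
#' regions from different sets belong to the same cluster when their
#' shared bases are at least `reciprocal_frac` of BOTH lengths
#' (transitively closed). Each cluster is assigned the subset of sets it
#' spans; tallies partition the clusters.
#'
#' @param sets Named list (>= 2) of interval tibbles.
#' @param reciprocal_frac Reciprocal-overlap fraction defining "the same
#'   region" (default 0.5).
#' @return Tibble with `subset` (comma-joined set names), `n_sets`,
#'   `n_clusters`; attribute `clusters` holds per-region assignments.
#' @export
venn_tally <- function(sets, reciprocal_frac = 0.5) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  regions <- purrr::map_dfr(names(sets), function(nm) {
    x <- normalize_intervals(sets[[nm]])
    dplyr::mutate(x, set = nm)
  })
  n <- nrow(regions)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ch in unique(regions$chrom)) {
    ii <- which(regions$chrom == ch)
    if (length(ii) < 2) next
    for (x in seq_along(ii)) {
      for (y in seq_len(x - 1)) {
        i <- ii[x]; j <- ii[y]
        if (regions$set[i] == regions$set[j]) next
        ov <- min(regions$end[i], regions$end[j]) -
          max(regions$start[i], regions$start[j])
        if (ov <= 0) next
        li <- regions$end[i] - regions$start[i]
        lj <- regions$end[j] - regions$start[j]
        if (ov >= reciprocal_frac * li && ov >= reciprocal_frac * lj) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  regions$cluster <- vapply(seq_len(n), find, integer(1))
  clus <- dplyr::summarise(
    dplyr::group_by(regions, .data$cluster),
    subset = paste(sort(unique(.data$set)), collapse = ","),
    n_sets = dplyr::n_distinct(.data$set), .groups = "drop")
  out <- dplyr::count(clus, .data$subset, .data$n_sets, name = "n_clusters")
  attr(out, "clusters") <- regions
  out
}
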