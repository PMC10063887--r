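#' Place k-mers on a reference by exact canonical lookup
#'
#' Every reference position whose canonical k-mer equals a query k-mer is
#' a hit (multi-mapping k-mers hit all their loci); per-base depth is the
#' number of hit k-mers overlapping each base. Exact lookup replaces
#' mismatch-tolerant read mapping: at the k-mer sizes used here spurious
#' matches are negligible and the procedure is deterministic.
#'
#' @param kmers Character vector of k-mers (canonicalized internally) or a
#'   [count_kmers()] tibble.
#' @param reference Named character vector of reference sequences.
#' @param k K-mer length; inferred from the k-mers when NULL.
#' @return Object of class `kmer_placement`: list with `hits` (tibble
#'   `chrom`, `pos` 1-based start, `kmer`), `depth` (named list of
#'   per-base integer vectors) and `k`.
#' @export
place_kmers <- function(kmers, reference, k = NULL) {
  if (is.data.frame(kmers)) {
    k <- attr(kmers, "k")
    kmers <- kmers$kmer
  }
  if (is.null(k)) k <- unique(nchar(kmers))
  if (length(unique(nchar(kmers))) > 1)
    stop("k-mers of mixed length")
  if (length(kmers) > 0 && any(nchar(kmers) != k))
    stop("k-mer length does not match k")
  canon <- unique(pmin(kmers, cpp_revcomp(kmers)))
  hits <- purrr::map_dfr(names(reference), function(ch) {
    pk <- cpp_seq_kmers(reference[[ch]], as.integer(k))
    at <- which(!is.na(pk) & pk %in% canon)
    tibble::tibble(chrom = ch, pos = at, kmer = pk[at])
  })
  depth <- lapply(names(reference), function(ch) {
    L <- nchar(reference[[ch]])
    d <- integer(L + 1L)
    h <- hits[hits$chrom == ch, ]
    if (nrow(h) > 0) {
      add <- tabulate(h$pos, nbins = L + 1L)
      sub <- tabulate(pmin(h$pos + k, L + 1L), nbins = L + 1L)
      d <- cumsum(add - sub)
    } else d <- integer(L)
    d[seq_len(L)]
  })
  names(depth) <- names(reference)
  structure(list(hits = hits, depth = depth, k = as.integer(k)),
            class = "kmer_placement")
}

#' Per-gene k-mer coverage
#'
#' For each gene model: `supporting_kmers` is the number of distinct
#' k-mers whose hit interval intersects the gene, `horizontal` the
#' fraction of gene bases covered by at least one k-mer, and `vertical`
#' the mean k-mer depth over gene bases.
#'
#' @param placement A [place_kmers()] result.
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `start`, `end`,
#'   0-based half-open).
#' @return Tibble with `gene_id`, `supporting_kmers`, `horizontal`,
#'   `vertical`.
#' @export
gene_coverage <- function(placement, genes) {
  stopifnot(inherits(placement, "kmer_placement"))
  k <- placement$k
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    d <- placement$depth[[g$chrom]]
    if (is.null(d))
      return(tibble::tibble(gene_id = g$gene_id, supporting_kmers = 0L,
                            horizontal = 0, vertical = 0))
    span <- seq(g$start + 1L, g$end) # 1-based bases of the gene
    h <- placement$hits[placement$hits$chrom == g$chrom, ]
    # hit interval [pos, pos + k - 1] intersects (start, end]
    sup <- dplyr::n_distinct(h$kmer[h$pos + k - 1L > g$start & h$pos <= g$end])
    tibble::tibble(gene_id = g$gene_id,
                   supporting_kmers = sup,
                   horizontal = mean(d[span] > 0),
                   vertical = mean(d[span]))
  })
}

#' Call gene presence/absence
#'
#' A gene is called present when supported by at least `min_support`
#' distinct k-mers; an optional horizontal-coverage floor can be added as
#' a secondary filter (off by default).
#'
#' @param coverages A [gene_coverage()] tibble (optionally with a `sample`
#'   column when stacked over samples).
#' @param min_support Minimum distinct supporting k-mers (default 3).
#' @param min_horizontal Optional minimum covered-base fraction.
#' @return Input tibble with a logical `present` column.
#' @export
call_pav <- function(coverages, min_support = 3, min_horizontal = NULL) {
  stopifnot(min_support >= 1)
  out <- dplyr::mutate(coverages,
                       present = .data$supporting_kmers >= min_support)
  if (!is.null(min_horizontal))
    out$present <- out$present & out$horizontal >= min_horizontal
  out
}

#' PAV calling across a panel of samples
#'
#' Runs [place_kmers()], [gene_coverage()] and [call_pav()] for each
#' sample's k-mer table against one annotated reference.
#'
#' @param kmer_tables Named list of [count_kmers()] tibbles, one per
#'   sample.
#' @param reference Named character vector of reference sequences.
#' @param genes Gene-model tibble.
#' @param min_support,min_horizontal Passed to [call_pav()].
#' @return Tibble with `sample`, `gene_id`, `supporting_kmers`,
#'   `horizontal`, `vertical`, `present`.
#' @export
pav_call_panel <- function(kmer_tables, reference, genes,
                           min_support = 3, min_horizontal = NULL) {
  stopifnot(!is.null(names(kmer_tables)))
  purrr::map_dfr(names(kmer_tables), function(sm) {
    pl <- place_kmers(kmer_tables[[sm]], reference)
    cv <- gene_coverage(pl, genes)
    cv <- call_pav(cv, min_support, min_horizontal)
    dplyr::mutate(cv, sample = sm, .before = 1)
  })
}

#' Gene x sample presence matrix and per-group summaries
#'
#' @param pav A [pav_call_panel()] tibble.
#' @return Wide tibble: one row per gene, one 0/1 column per sample.
#' @export
pav_matrix <- function(pav) {
  tidyr::pivot_wider(
    dplyr::mutate(pav[, c("gene_id", "sample", "present")],
                  present = as.integer(.data$present)),
    names_from = "sample", values_from = "present")
}

#' @rdname pav_matrix
#' @param groups Tibble with `sample`, `group`.
#' @return `pav_summary()`: list with `group_unique` (genes present only
#'   in samples of one group) and `common_all` (genes present in every
#'   sample).
#' @export
pav_summary <- function(pav, groups) {
  x <- dplyr::left_join(pav, groups, by = "sample")
  by_gene <- dplyr::summarise(
    dplyr::group_by(x, .data$gene_id),
    groups_present = list(sort(unique(.data$group[.data$present]))),
    all_present = all(.data$present), .groups = "drop")
  uniq <- dplyr::filter(by_gene,
                        lengths(.data$groups_present) == 1)
  group_unique <- tibble::tibble(
    group = purrr::map_chr(uniq$groups_present, 1),
    gene_id = uniq$gene_id)
  list(group_unique = dplyr::arrange(group_unique, .data$group, .data$gene_id),
       common_all = by_gene$gene_id[by_gene$all_present])
}
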