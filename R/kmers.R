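#' Count canonical k-mers
#'
#' Every k-length window over {A,C,G,T} contributes its canonical form
#' (the lexicographic minimum of the k-mer and its reverse complement);
#' windows containing any other character contribute nothing. k must be
#' odd so no k-mer equals its own reverse complement. k-mers seen fewer
#' than `min_count` times are dropped — the standard guard against
#' k-mers that appear only once and are likely sequencing errors.
#'
#' @param x Sequences: character vector (named or not), a reads tibble
#'   with a `seq` column, or a FASTA/FASTQ file path.
#' @param k Odd k-mer length, `0 < k <= 255`.
#' @param min_count Minimum abundance to retain (default 1 = keep all).
#' @return Tibble with `kmer`, `count`, sorted by k-mer; attribute `k`.
#' @export
count_kmers <- function(x, k, min_count = 1) {
  check_k(k)
  stopifnot(min_count >= 1)
  seqs <- as_sequences(x)
  if (length(seqs) == 0) {
    out <- tibble::tibble(kmer = character(), count = integer())
  } else {
    cnt <- cpp_kmer_counts(seqs, as.integer(k))
    cnt <- cnt[cnt >= min_count]
    out <- tibble::tibble(kmer = names(cnt), count = as.integer(cnt))
    out <- dplyr::arrange(out, .data$kmer)
  }
  attr(out, "k") <- as.integer(k)
  out
}

check_k <- function(k) {
  if (k <= 0 || k > 255) stop("k must be in (0, 255]")
  if (k %% 2 == 0)
    stop("k must be odd: even k admits palindromic k-mers equal to their ",
         "own reverse complement, making canonicalization ambiguous")
  invisible(k)
}

# normalize the accepted sequence inputs to a character vector
as_sequences <- function(x) {
  if (is.character(x) && length(x) == 1 && nchar(x) < 2048 &&
      file.exists(x)) {
    first <- readr::read_lines(x, n_max = 1)
    return(if (startsWith(first, "@")) read_fastq(x)$seq else
             unname(read_fasta(x)))
  }
  if (is.data.frame(x)) return(x$seq)
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  as.character(x)
}

#' Reverse complement
#' @param seqs Character vector of DNA sequences.
#' @return Character vector of reverse complements (non-ACGT become N).
#' @export
revcomp <- function(seqs) cpp_revcomp(seqs)

#' Abundance histogram of a k-mer count table
#'
#' @param counts A [count_kmers()] tibble.
#' @return Tibble with `abundance`, `n_kmers`; the weighted sum
#'   `sum(abundance * n_kmers)` equals the total k-mer occurrences.
#' @export
abundance_histogram <- function(counts) {
  if (nrow(counts) == 0)
    return(tibble::tibble(abundance = integer(), n_kmers = integer()))
  dplyr::count(counts, abundance = .data$count, name = "n_kmers")
}

#' Choose a k-mer size from a grid
#'
#' For each candidate k the number of distinct canonical k-mers with
#' abundance `>= min_count` is counted (a proxy for the "genomic" k-mer
#' count a histogram-model fit would estimate); the k maximizing it wins,
#' with ties broken toward the smaller k.
#'
#' @param x Sequences (as in [count_kmers()]).
#' @param k_grid Odd candidate k values.
#' @param min_count Abundance floor.
#' @return Tibble with `k`, `distinct_kmers`, `best` (logical); the
#'   winning k is also in attribute `best_k`.
#' @export
choose_k <- function(x, k_grid, min_count = 1) {
  stopifnot(length(k_grid) > 0)
  purrr::walk(k_grid, check_k)
  seqs <- as_sequences(x)
  tab <- purrr::map_dfr(sort(k_grid), function(k) {
    tibble::tibble(k = k, distinct_kmers = nrow(count_kmers(seqs, k, min_count)))
  })
  best <- tab$k[which.max(tab$distinct_kmers)] # first max = smallest k on ties
  tab$best <- tab$k == best
  attr(tab, "best_k") <- best
  tab
}

# seed constant folded into the k-mer hash; fixed so sketches are
# reproducible across runs and platforms
MINHASH_SEED <- 42

#' Bottom-s MinHash sketch of a k-mer set
#'
#' Hashes every distinct canonical k-mer with a fixed keyed 64-bit hash
#' (FNV-1a with splitmix64 finalization, seed constant 42) and keeps the
#' `s` smallest hash values. Hashes are stored as 16-character hex strings
#' whose lexicographic order equals numeric order.
#'
#' @param x Sequences (as in [count_kmers()]) or a [count_kmers()] tibble.
#' @param k Odd k-mer length (taken from the table when `x` is one).
#' @param s Sketch size (>= 1).
#' @return Object of class `minhash_sketch`: list with `k`, `s`, `hashes`
#'   (sorted, possibly shorter than `s` — flagged via the `underfull`
#'   field when the input has fewer distinct k-mers).
#' @export
kmer_sketch <- function(x, k = 31, s = 1000) {
  stopifnot(s >= 1)
  if (is.data.frame(x) && "kmer" %in% names(x)) {
    k <- attr(x, "k")
    kmers <- x$kmer
  } else {
    check_k(k)
    kmers <- count_kmers(x, k)$kmer
  }
  h <- sort(unique(cpp_hash64(kmers, MINHASH_SEED)))
  hashes <- utils::head(h, s)
  structure(list(k = as.integer(k), s = as.integer(s), hashes = hashes,
                 underfull = length(hashes) < s),
            class = "minhash_sketch")
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat("<minhash_sketch> k=", x$k, " s=", x$s, " (", length(x$hashes),
      " hashes", if (x$underfull) ", underfull" else "", ")\n", sep = "")
  invisible(x)
}

#' Mash distance between two sketches
#'
#' The Jaccard index is estimated on the merged bottom-s sketch:
#' `j = |shared| / |merged|`, and the distance is
#' `D = -(1/k) * ln(2j / (1 + j))`, the Mash point estimate of per-base
#' divergence. `j = 0` gives `D = 1` (capped by convention); identical
#' inputs give `j = 1`, `D = 0`.
#'
#' @param a,b `minhash_sketch` objects with equal `k`.
#' @return Named list with `jaccard` and `distance`.
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$k != b$k) stop("sketches have different k (", a$k, " vs ", b$k, ")")
  s <- min(a$s, b$s)
  merged <- utils::head(sort(unique(c(a$hashes, b$hashes))), s)
  shared <- sum(merged %in% a$hashes & merged %in% b$hashes)
  j <- if (length(merged) == 0) 0 else shared / length(merged)
  d <- if (j == 0) 1 else max(0, -log(2 * j / (1 + j)) / a$k)
  list(jaccard = j, distance = d)
}

#' All-pairs Mash distances
#'
#' @param sketches Named list of `minhash_sketch` objects.
#' @return Tibble with `sample1`, `sample2`, `jaccard`, `distance` for
#'   every unordered pair.
#' @export
mash_distance_matrix <- function(sketches) {
  nm <- names(sketches)
  stopifnot(!is.null(nm))
  pairs <- utils::combn(nm, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    d <- mash_distance(sketches[[pairs[1, i]]], sketches[[pairs[2, i]]])
    tibble::tibble(sample1 = pairs[1, i], sample2 = pairs[2, i],
                   jaccard = d$jaccard, distance = d$distance)
  })
}

#' N-way k-mer sharing decomposition
#'
#' Assigns every distinct k-mer in the union of the input tables its exact
#' membership subset and tallies k-mers per subset cardinality (present in
#' all samples, in all-but-one, ..., sample-unique) — the generalization
#' of "common k-mers present in all races" style summaries.
#'
#' @param tables Named list of [count_kmers()] tibbles at the same k.
#' @return Object of class `kmer_sharing`: list with `membership` (tibble
#'   `kmer`, `n_samples`, `members` comma-joined), `tally` (tibble
#'   `cardinality`, `n_kmers`, `fraction`) and `sample_unique` (tibble
#'   `sample`, `n_unique`). Tallies partition the union.
#' @export
sharing_decomposition <- function(tables) {
  nm <- names(tables)
  stopifnot(!is.null(nm), length(tables) >= 1)
  ks <- unique(vapply(tables, function(t) attr(t, "k"), integer(1)))
  if (length(ks) != 1) stop("all tables must share one k")
  long <- purrr::map_dfr(nm, function(n) {
    tibble::tibble(kmer = tables[[n]]$kmer, sample = n)
  })
  membership <- dplyr::summarise(
    dplyr::group_by(long, .data$kmer),
    n_samples = dplyr::n_distinct(.data$sample),
    members = paste(sort(unique(.data$sample)), collapse = ","),
    .groups = "drop")
  tally <- dplyr::count(membership, cardinality = .data$n_samples,
                        name = "n_kmers")
  tally$fraction <- tally$n_kmers / nrow(membership)
  uniq <- dplyr::filter(membership, .data$n_samples == 1)
  sample_unique <- dplyr::count(uniq, sample = .data$members, name = "n_unique")
  sample_unique <- dplyr::left_join(tibble::tibble(sample = nm), sample_unique,
                                    by = "sample")
  sample_unique$n_unique[is.na(sample_unique$n_unique)] <- 0L
  structure(list(membership = membership, tally = tally,
                 sample_unique = sample_unique, k = ks),
            class = "kmer_sharing")
}

#' @export
print.kmer_sharing <- function(x, ...) {
  cat("<kmer_sharing> ", nrow(x$membership), " distinct k-mers (k=", x$k,
      ")\n", sep = "")
  print(x$tally)
  invisible(x)
}

#' Group-specific k-mers
#'
#' A k-mer is specific to a group iff every sample containing it belongs
#' to that group; k-mers seen in samples of two or more groups belong to
#' no group's set.
#'
#' @param profile A [sharing_decomposition()] result.
#' @param groups Tibble with `sample`, `group` covering every sample.
#' @return Tibble with `group`, `kmer`.
#' @export
group_specific_kmers <- function(profile, groups) {
  stopifnot(inherits(profile, "kmer_sharing"),
            all(c("sample", "group") %in% names(groups)))
  lookup <- stats::setNames(groups$group, groups$sample)
  mem <- profile$membership
  grp <- purrr::map_chr(strsplit(mem$members, ",", fixed = TRUE), function(s) {
    if (any(!s %in% names(lookup))) stop("unmapped sample: ",
                                         paste(setdiff(s, names(lookup)),
                                               collapse = ", "))
    g <- unique(unname(lookup[s]))
    if (length(g) == 1) g else NA_character_
  })
  out <- tibble::tibble(group = grp, kmer = mem$kmer)
  dplyr::arrange(dplyr::filter(out, !is.na(.data$group)),
                 .data$group, .data$kmer)
}
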