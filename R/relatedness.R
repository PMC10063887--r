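#' Allele-sharing SNP distance matrix
#'
#' Pairwise distance `1 - IBS`, where IBS between two diploid genotypes
#' with alt dosages `d1`, `d2` is `1 - |d1 - d2| / 2`, averaged over the
#' sites where both samples are non-missing. Identical samples get 0,
#' opposite homozygotes everywhere get 1.
#'
#' @param vcf A `race_vcf` (>= 2 samples).
#' @return Symmetric numeric matrix with zero diagonal, sample names as
#'   dimnames.
#' @export
snp_distance <- function(vcf) {
  dos <- vcf_dosage(vcf)
  n <- ncol(dos)
  stopifnot(n >= 2)
  d <- matrix(0, n, n, dimnames = list(colnames(dos), colnames(dos)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(dos[, i]) & !is.na(dos[, j])
      d[i, j] <- d[j, i] <-
        if (!any(ok)) NA_real_ else mean(abs(dos[ok, i] - dos[ok, j]) / 2)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration via [ape::nj()]; any negative branch length
#' is then clamped to 0 with its (negative) length transferred to the
#' sibling branch, preserving the path length through the parent node.
#'
#' @param d Symmetric distance matrix (n >= 3) or `dist`.
#' @return An [ape::phylo] tree (unrooted, with branch lengths).
#' @export
nj_tree <- function(d) {
  if (!inherits(d, "dist")) {
    stopifnot(isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    d <- stats::as.dist(d)
  }
  stopifnot(attr(d, "Size") >= 3)
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sib) > 0)
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr
}

#' Bootstrap support for the NJ tree
#'
#' Sites (matrix columns) are resampled with replacement `n_reps` times,
#' the distance matrix and NJ tree are rebuilt for each replicate, and
#' bipartition recovery of the original tree's internal edges is counted
#' with [ape::prop.clades()].
#'
#' @param vcf A `race_vcf`.
#' @param n_reps Number of bootstrap replicates (> 0).
#' @param seed RNG seed.
#' @return List with `tree` (the full-data NJ tree) and `support`
#'   (tibble `node`, `support` in percent for each internal node).
#' @export
bootstrap_support <- function(vcf, n_reps = 1000, seed = 1) {
  if (n_reps <= 0) stop("n_reps must be positive")
  set.seed(seed)
  tree <- nj_tree(snp_distance(vcf))
  S <- nrow(vcf$sites)
  stopifnot(S >= 1)
  boots <- lapply(seq_len(n_reps), function(r) {
    idx <- sample.int(S, S, replace = TRUE)
    sub <- new_vcf(vcf$sites[idx, ], vcf$gt[idx, , drop = FALSE],
                   vcf$dp[idx, , drop = FALSE], vcf$samples)
    nj_tree(snp_distance(sub))
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  n_tip <- length(tree$tip.label)
  list(tree = tree,
       support = tibble::tibble(node = n_tip + seq_along(counts),
                                support = 100 * counts / n_reps))
}

#' Principal coordinates analysis
#'
#' Classical (Gower) metric scaling of a distance matrix: double-centered
#' matrix eigendecomposition via [stats::cmdscale()], axes ordered by
#' eigenvalue. All eigenvalues (including negative ones) are reported.
#'
#' @param d Symmetric distance matrix or `dist`.
#' @param n_axes Number of axes to return (`< n`).
#' @return List of class `pcoa_result` with `points` (tibble `sample`,
#'   `axis1`, ...), `eigenvalues` and `rel_eig` (relative to the positive
#'   eigenvalue total).
#' @export
pcoa <- function(d, n_axes = 2) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  stopifnot(n_axes < n)
  # cmdscale warns when fewer than n_axes eigenvalues are positive; those
  # axes are zero-padded below, so the warning is expected for degenerate
  # inputs
  fit <- suppressWarnings(cmdscale(d, k = n_axes, eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts)) || ncol(pts) < n_axes) {
    # degenerate input (e.g. all-zero distances): pad with zero axes
    pts <- cbind(pts, matrix(0, n, n_axes - if (is.null(dim(pts))) 0 else ncol(pts)))
  }
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  labels <- attr(d, "Labels")
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  pos <- sum(fit$eig[fit$eig > 0])
  structure(list(
    points = dplyr::bind_cols(tibble::tibble(sample = labels),
                              tibble::as_tibble(pts)),
    eigenvalues = fit$eig,
    rel_eig = if (pos > 0) fit$eig / pos else rep(0, length(fit$eig))
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("<pcoa_result> ", nrow(x$points), " samples, ",
      ncol(x$points) - 1, " axes\n", sep = "")
  print(utils::head(x$points, 5))
  invisible(x)
}

#' @export
tidy.pcoa_result <- function(x, ...) x$points

#' @export
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(n = nrow(x$points),
                 n_negative_eig = sum(x$eigenvalues < 0),
                 prop_axis1 = x$rel_eig[1],
                 prop_axis2 = if (length(x$rel_eig) > 1) x$rel_eig[2] else NA_real_)
}
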