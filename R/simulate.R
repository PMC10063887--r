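#' Configuration for the synthetic race-panel simulator
#'
#' Defines a structured panel in the style of a multi-race crop diversity
#' study: several labelled subpopulations with tunable pairwise divergence
#' (Balding-Nichols model), per-population diversity, hard selective
#' sweeps at chosen loci, whole-gene deletions creating presence-absence
#' variation (PAV) and group-specific k-mers, and sequencing reads with
#' error.
#'
#' All randomness flows from `seed`: each stage sets its RNG state to
#' `seed` plus a fixed documented offset (frequencies +101, haplotypes
#' +102, genomes +103, reads +104), so the same configuration always
#' reproduces byte-identical output.
#'
#' @param seed Master seed (integer).
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_populations Number of populations (<= 5 get the classical
#'   sorghum race names bicolor/caudatum/durra/guinea/kafir by default).
#' @param pop_sizes Diploid sample count per population.
#' @param divergence Balding-Nichols F per population, each in `[0, 1)`;
#'   the expected pairwise Weir-Cockerham Fst between populations i and j
#'   is approximately `(F_i + F_j) / 2`. F = 0 means no drift.
#' @param fst_targets Optional symmetric zero-diagonal matrix of pairwise
#'   Fst targets; when supplied, per-population F values are solved from
#'   it by least squares and override `divergence`.
#' @param theta Expected per-bp nucleotide diversity; used to size the
#'   variant count when `n_sites` is NULL.
#' @param n_sites Variant sites per chromosome (overrides `theta` sizing).
#' @param spectrum Site-frequency spectrum model: `"balding_nichols"`
#'   (structured panel; ancestral frequencies Uniform(0.05, 0.95)) or
#'   `"neutral"` (derived-allele counts drawn proportional to 1/i, the
#'   fixed-S neutral spectrum, for which E\[theta_pi\] = E\[theta_W\]).
#' @param sweep_specs Tibble with `population`, `chrom`, `pos`,
#'   `strength` in `[0, 1]` (fraction of target-population haplotypes
#'   carrying the forced core haplotype).
#' @param sweep_width Width in bp of the window over which the core
#'   haplotype is forced around each sweep position.
#' @param pav_specs Tibble with `gene_id` and `absent_in` (list-column of
#'   population names lacking the gene).
#' @param pav_buffer Flanking bases excised together with a deleted gene
#'   (default 50). Real deletions do not respect gene boundaries, and the
#'   buffer guarantees that the deletion junction cannot create chance
#'   k-mer homology with the gene's reference copy, keeping the PAV truth
#'   tables unambiguous.
#' @param n_genes Number of gene models placed on each chromosome.
#' @param gene_length Gene length in bp (multiple of 3; single-CDS genes).
#' @param read_length,coverage,error_rate Read simulation parameters.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 1L,
                       chrom_length = 1e6,
                       n_populations = 5L,
                       pop_sizes = rep(20L, n_populations),
                       divergence = rep(0.1, n_populations),
                       fst_targets = NULL,
                       theta = 0.001,
                       n_sites = NULL,
                       spectrum = c("balding_nichols", "neutral"),
                       sweep_specs = NULL,
                       sweep_width = 1e5,
                       pav_specs = NULL,
                       pav_buffer = 50L,
                       n_genes = 0L,
                       gene_length = 300L,
                       read_length = 100L,
                       coverage = 10,
                       error_rate = 0) {
  spectrum <- match.arg(spectrum)
  pop_names <- if (n_populations <= 5) {
    c("bicolor", "caudatum", "durra", "guinea", "kafir")[seq_len(n_populations)]
  } else paste0("pop", seq_len(n_populations))
  if (!is.null(fst_targets)) {
    stopifnot(is.matrix(fst_targets),
              nrow(fst_targets) == n_populations,
              isTRUE(all.equal(fst_targets, t(fst_targets))),
              all(diag(fst_targets) == 0))
    divergence <- solve_divergence(fst_targets)
  }
  if (length(divergence) == 1) divergence <- rep(divergence, n_populations)
  stopifnot(length(pop_sizes) == n_populations,
            length(divergence) == n_populations,
            all(divergence >= 0), theta > 0, coverage >= 0,
            error_rate >= 0, error_rate < 1,
            gene_length %% 3 == 0)
  if (any(divergence >= 1))
    stop("divergence (Balding-Nichols F) must be < 1")
  if (is.null(n_sites)) {
    n_hap <- 2 * sum(pop_sizes)
    n_sites <- if (spectrum == "neutral") {
      round(theta * chrom_length * sum(1 / seq_len(n_hap - 1)))
    } else {
      # E[2p(1-p)] for p ~ U(0.05, 0.95) is 0.365
      round(theta * chrom_length / 0.365)
    }
  }
  if (!is.null(sweep_specs)) {
    sweep_specs <- tibble::as_tibble(sweep_specs)
    stopifnot(all(c("population", "chrom", "pos", "strength") %in%
                    names(sweep_specs)),
              all(sweep_specs$strength >= 0 & sweep_specs$strength <= 1),
              all(sweep_specs$population %in% pop_names),
              all(sweep_specs$pos >= 1 & sweep_specs$pos <= chrom_length))
  }
  if (!is.null(pav_specs)) pav_specs <- tibble::as_tibble(pav_specs)
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_populations = as.integer(n_populations),
    pop_names = pop_names, pop_sizes = as.integer(pop_sizes),
    divergence = divergence, theta = theta, n_sites = as.integer(n_sites),
    spectrum = spectrum, sweep_specs = sweep_specs,
    sweep_width = sweep_width, pav_specs = pav_specs,
    pav_buffer = as.integer(pav_buffer),
    n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
    read_length = as.integer(read_length), coverage = coverage,
    error_rate = error_rate
  ), class = "sim_config")
}

# least-squares per-population F from a pairwise Fst target matrix,
# under E[Fst_ij] ~ (F_i + F_j)/2
solve_divergence <- function(targets) {
  k <- nrow(targets)
  pairs <- utils::combn(k, 2)
  A <- matrix(0, ncol(pairs), k)
  y <- numeric(ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    A[m, pairs[1, m]] <- 0.5
    A[m, pairs[2, m]] <- 0.5
    y[m] <- targets[pairs[1, m], pairs[2, m]]
  }
  f <- stats::lm.fit(A, y)$coefficients
  pmin(pmax(f, 0), 0.95)
}

#' Simulate per-population allele frequencies (Balding-Nichols)
#'
#' For each site an ancestral frequency `p ~ Uniform(0.05, 0.95)` is drawn
#' and each population's frequency comes from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with F that population's
#' divergence parameter; `F = 0` copies `p` exactly (no drift). Site
#' positions are strictly increasing within each chromosome.
#'
#' @param config A [sim_config()].
#' @return Long tibble with `chrom`, `pos`, `anc_freq`, `population`,
#'   `freq`.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  purrr::map_dfr(seq_len(config$n_chromosomes), function(ci) {
    pos <- sort(sample.int(config$chrom_length, config$n_sites))
    p <- runif(config$n_sites, 0.05, 0.95)
    purrr::map_dfr(seq_len(config$n_populations), function(k) {
      f <- config$divergence[k]
      freq <- if (f == 0) p else {
        rbeta(config$n_sites, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      }
      tibble::tibble(chrom = paste0("chr", ci), pos = pos, anc_freq = p,
                     population = config$pop_names[k], freq = freq)
    })
  })
}

#' Simulate phased haplotypes (and a VCF) from allele frequencies
#'
#' Haplotypes are sampled binomially per site from each population's
#' frequency (or, under `spectrum = "neutral"`, by drawing each site's
#' derived-allele count proportional to 1/i and scattering the carriers
#' uniformly over all haplotypes). Hard sweeps are then imposed by forcing
#' a common core haplotype over `sweep_width` bp around each sweep
#' position in the target population: a `strength` fraction of that
#' population's haplotypes is overwritten with one template carrying the
#' derived allele at the focal site, producing locally elevated haplotype
#' homozygosity.
#'
#' @param freqs Output of [simulate_frequencies()].
#' @param config A [sim_config()].
#' @return List with `hap` (a `hap_set`), `vcf` (a `race_vcf`) and
#'   `sweep_truth` (tibble of forced windows: `chrom`, `start`, `end`,
#'   `pos`, `population`, `strength`; 0-based half-open).
#' @export
simulate_haplotypes <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"), all(freqs$freq >= 0 & freqs$freq <= 1))
  set.seed(config$seed + 102L)
  samples <- tibble::tibble(
    population = rep(config$pop_names, config$pop_sizes)
  )
  samples$sample <- paste0(samples$population, "_",
                           unlist(lapply(config$pop_sizes, seq_len)))
  n_hap <- 2L * nrow(samples)
  hap_sample <- rep(samples$sample, each = 2)
  hap_pop <- rep(samples$population, each = 2)

  site_tbl <- dplyr::distinct(freqs, .data$chrom, .data$pos, .data$anc_freq)
  S <- nrow(site_tbl)
  hap <- matrix(0L, n_hap, S)
  if (config$spectrum == "neutral") {
    w <- 1 / seq_len(n_hap - 1)
    counts <- sample.int(n_hap - 1, S, replace = TRUE, prob = w)
    for (j in seq_len(S)) hap[sample.int(n_hap, counts[j]), j] <- 1L
  } else {
    wide <- tidyr::pivot_wider(freqs, names_from = "population",
                               values_from = "freq")
    for (k in seq_len(config$n_populations)) {
      rows <- which(hap_pop == config$pop_names[k])
      fr <- wide[[config$pop_names[k]]]
      draws <- matrix(rbinom(length(rows) * S, 1L, rep(fr, each = length(rows))),
                      nrow = length(rows))
      hap[rows, ] <- draws
    }
  }

  # ref/alt alleles: deterministic draw, alt differs from ref
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, S, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  sites <- tibble::tibble(chrom = site_tbl$chrom, pos = site_tbl$pos,
                          id = paste0("s", seq_len(S)), ref = ref, alt = alt,
                          qual = round(runif(S, 30, 60), 1))

  sweep_truth <- tibble::tibble(chrom = character(), start = integer(),
                                end = integer(), pos = integer(),
                                population = character(), strength = double())
  if (!is.null(config$sweep_specs) && nrow(config$sweep_specs) > 0) {
    for (i in seq_len(nrow(config$sweep_specs))) {
      sw <- config$sweep_specs[i, ]
      lo <- max(0, sw$pos - config$sweep_width / 2)
      hi <- min(config$chrom_length, sw$pos + config$sweep_width / 2)
      idx <- which(sites$chrom == sw$chrom & sites$pos > lo & sites$pos <= hi)
      rows <- which(hap_pop == sw$population)
      n_car <- round(sw$strength * length(rows))
      if (length(idx) > 0 && n_car >= 1) {
        carriers <- sample(rows, n_car)
        template <- hap[carriers[1], idx]
        focal <- idx[which.min(abs(sites$pos[idx] - sw$pos))]
        template[idx == focal] <- 1L
        hap[carriers, idx] <- matrix(template, n_car, length(idx), byrow = TRUE)
      }
      sweep_truth <- dplyr::bind_rows(sweep_truth, tibble::tibble(
        chrom = sw$chrom, start = as.integer(lo), end = as.integer(hi),
        pos = as.integer(sw$pos), population = sw$population,
        strength = sw$strength))
    }
  }

  hs <- new_hap_set(hap, sites, samples[, c("sample", "population")], hap_sample)
  vcf <- hap_to_vcf(hs, config)
  list(hap = hs, vcf = vcf, sweep_truth = sweep_truth)
}

# phased VCF from a hap_set; DP drawn around the configured coverage
hap_to_vcf <- function(hs, config) {
  n <- nrow(hs$samples)
  S <- ncol(hs$haplotypes)
  a1 <- t(hs$haplotypes[seq(1, 2 * n, by = 2), , drop = FALSE])
  a2 <- t(hs$haplotypes[seq(2, 2 * n, by = 2), , drop = FALSE])
  gt <- matrix(paste0(a1, "|", a2), S, n)
  colnames(gt) <- hs$samples$sample
  lambda <- if (config$coverage > 0) config$coverage else 30
  dp <- matrix(rpois(S * n, lambda), S, n,
               dimnames = list(NULL, hs$samples$sample))
  new_vcf(hs$sites, gt, dp, hs$samples$sample)
}

#' Simulate per-accession genomes, gene annotation and truth tables
#'
#' An ancestral chromosome sequence is drawn, gene models are placed on it
#' without overlap, and each accession's genome is the ancestral sequence
#' with its first haplotype's alternate alleles substituted. Genes listed
#' in `pav_specs` are then deleted (whole-gene excision) from every
#' accession of the stated populations. Truth tables record every PAV and,
#' for genes retained by exactly one population, the realized private
#' gene sequences per retaining accession.
#'
#' @param config A [sim_config()] with `n_genes > 0` for gene-level truth.
#' @param haps Optional output of [simulate_haplotypes()]; simulated on
#'   the fly when NULL.
#' @return List with `reference` (named character, the ancestral genome),
#'   `genomes` (named character per accession), `genes` (gene-model
#'   tibble, 0-based half-open), `truth_pav` (tibble `gene_id`, `sample`,
#'   `population`, `present`), `truth_private` (tibble `population`,
#'   `gene_id`, `sample`, `seq`) and `haps`.
#' @export
simulate_genomes <- function(config, haps = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(haps)) {
    freqs <- simulate_frequencies(config)
    haps <- simulate_haplotypes(freqs, config)
  }
  set.seed(config$seed + 103L)
  bases <- c("A", "C", "G", "T")
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  reference <- vapply(chroms, function(ch) {
    paste(sample(bases, config$chrom_length, replace = TRUE), collapse = "")
  }, character(1))

  # place non-overlapping genes per chromosome
  genes <- purrr::map_dfr(chroms, function(ch) {
    if (config$n_genes == 0) return(tibble::tibble())
    gl <- config$gene_length
    slots <- floor(config$chrom_length / (2 * gl))
    stopifnot(config$n_genes <= slots)
    starts <- sort(sample.int(slots, config$n_genes)) * 2L * gl - 2L * gl
    tibble::tibble(
      gene_id = paste0(ch, "g", seq_len(config$n_genes)),
      chrom = ch, start = starts, end = starts + gl,
      strand = rep(c("+", "-"), length.out = config$n_genes),
      cds = purrr::map(starts, ~ tibble::tibble(start = .x, end = .x + gl,
                                                phase = 0L))
    )
  })
  if (nrow(genes) > 0 && any(duplicated_intervals(genes)))
    stop("overlapping gene placements")

  # make reference carry the REF allele at every variant site
  sites <- haps$hap$sites
  for (ch in chroms) {
    idx <- which(sites$chrom == ch)
    if (length(idx) == 0) next
    sq <- strsplit(reference[[ch]], "")[[1]]
    sq[sites$pos[idx]] <- sites$ref[idx]
    reference[[ch]] <- paste(sq, collapse = "")
  }

  samples <- haps$hap$samples
  hap1_rows <- seq(1, nrow(haps$hap$haplotypes), by = 2)
  absent_map <- pav_absence(config, genes, samples)

  genomes <- vapply(seq_len(nrow(samples)), function(i) {
    gseq <- reference
    hp <- haps$hap$haplotypes[hap1_rows[i], ]
    for (ch in chroms) {
      idx <- which(sites$chrom == ch & hp == 1L)
      sq <- strsplit(gseq[[ch]], "")[[1]]
      if (length(idx) > 0) sq[sites$pos[idx]] <- sites$alt[idx]
      # excise absent genes, highest coordinate first
      gone <- absent_map[absent_map$sample == samples$sample[i] &
                           !absent_map$present & absent_map$chrom == ch, ]
      if (nrow(gone) > 0) {
        buf <- config$pav_buffer
        for (j in order(gone$start, decreasing = TRUE)) {
          lo <- max(0L, gone$start[j] - buf)
          hi <- min(length(sq), gone$end[j] + buf)
          sq <- sq[-seq(lo + 1L, hi)]
        }
      }
      gseq[[ch]] <- paste(sq, collapse = "")
    }
    paste(gseq, collapse = "")
  }, character(1))
  names(genomes) <- samples$sample

  truth_pav <- absent_map[, c("gene_id", "sample", "population", "present")]

  # genes retained by exactly one population: private-segment truth with
  # realized (variant-substituted) sequences per retaining accession
  truth_private <- tibble::tibble(population = character(), gene_id = character(),
                                  sample = character(), seq = character())
  if (nrow(genes) > 0 && !is.null(config$pav_specs)) {
    by_gene <- dplyr::summarise(
      dplyr::group_by(truth_pav, .data$gene_id),
      pops = list(unique(.data$population[.data$present])), .groups = "drop")
    for (i in seq_len(nrow(by_gene))) {
      pops <- by_gene$pops[[i]]
      if (length(pops) != 1) next
      g <- genes[genes$gene_id == by_gene$gene_id[i], ]
      keep <- samples$sample[samples$population == pops]
      for (sm in keep) {
        si <- which(samples$sample == sm)
        hp <- haps$hap$haplotypes[hap1_rows[si], ]
        idx <- which(sites$chrom == g$chrom & hp == 1L)
        sq <- strsplit(reference[[g$chrom]], "")[[1]]
        if (length(idx) > 0) sq[sites$pos[idx]] <- sites$alt[idx]
        # coordinates are pre-deletion; the private gene itself is retained
        truth_private <- dplyr::bind_rows(truth_private, tibble::tibble(
          population = pops, gene_id = g$gene_id, sample = sm,
          seq = paste(sq[seq(g$start + 1L, g$end)], collapse = "")))
      }
    }
  }

  list(reference = reference, genomes = genomes, genes = genes,
       truth_pav = truth_pav, truth_private = truth_private, haps = haps)
}

# expand pav_specs into a gene x sample presence table
pav_absence <- function(config, genes, samples) {
  grid <- tidyr::expand_grid(gene_id = genes$gene_id, sample = samples$sample)
  grid <- dplyr::left_join(grid, samples, by = "sample")
  grid <- dplyr::left_join(grid, genes[, c("gene_id", "chrom", "start", "end")],
                           by = "gene_id")
  grid$present <- TRUE
  if (!is.null(config$pav_specs) && nrow(config$pav_specs) > 0) {
    for (i in seq_len(nrow(config$pav_specs))) {
      ps <- config$pav_specs[i, ]
      gone <- grid$gene_id == ps$gene_id &
        grid$population %in% unlist(ps$absent_in)
      grid$present[gone] <- FALSE
    }
  }
  grid
}

duplicated_intervals <- function(genes) {
  by_chr <- split(genes, genes$chrom)
  unlist(lapply(by_chr, function(g) {
    g <- g[order(g$start), ]
    c(FALSE, g$start[-1] < g$end[-nrow(g)])
  }))
}

#' Simulate sequencing reads from a genome
#'
#' Reads are placed uniformly, substitution errors are applied per base at
#' `error_rate`, and every base gets the Phred quality consistent with the
#' error rate (capped at Q40 when `error_rate = 0`).
#'
#' @param genome Single genome sequence (character scalar).
#' @param coverage Target fold coverage (> 0).
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution probability.
#' @param seed Seed for read placement and errors.
#' @param prefix Read-name prefix.
#' @return Tibble with `read_id`, `seq`, `qual`.
#' @export
simulate_reads <- function(genome, coverage, read_length = 100,
                           error_rate = 0, seed = 1, prefix = "read") {
  stopifnot(coverage > 0, length(genome) == 1)
  L <- nchar(genome)
  if (read_length > L) stop("read_length exceeds genome length")
  set.seed(seed)
  n_reads <- ceiling(coverage * L / read_length)
  starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
  seqs <- substring(genome, starts, starts + read_length - 1L)
  if (error_rate > 0) {
    n_err <- rbinom(n_reads, read_length, error_rate)
    hit <- which(n_err > 0)
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      sq <- strsplit(seqs[i], "")[[1]]
      at <- sample.int(read_length, n_err[i])
      sq[at] <- vapply(sq[at],
                       function(b) sample(setdiff(bases, b), 1), character(1))
      seqs[i] <- paste(sq, collapse = "")
    }
  }
  q <- if (error_rate <= 0) 40L else min(40L, round(-10 * log10(error_rate)))
  qual <- strrep(rawToChar(as.raw(q + 33L)), read_length)
  tibble::tibble(read_id = paste0(prefix, "_", seq_len(n_reads)),
                 seq = seqs, qual = qual)
}

#' Run the full simulator
#'
#' Convenience orchestrator: frequencies, haplotypes + VCF, genomes,
#' annotation and truth tables from one configuration.
#'
#' @param config A [sim_config()].
#' @return The [simulate_genomes()] result, with `freqs` and `sweep_truth`
#'   attached.
#' @export
simulate_panel <- function(config) {
  freqs <- simulate_frequencies(config)
  haps <- simulate_haplotypes(freqs, config)
  out <- simulate_genomes(config, haps)
  out$freqs <- freqs
  out$sweep_truth <- haps$sweep_truth
  out
}
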