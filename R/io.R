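#' Read and write FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that move between files and the named
#' character vectors used throughout the package.
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector of upper-case
#'   sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read and write FASTQ
#'
#' Reads are represented as a tibble with columns `read_id`, `seq`, `qual`
#' (Phred+33 encoded quality string).
#'
#' @param path File path.
#' @return A tibble of reads.
#' @export
read_fastq <- function(path) {
  # Biostrings notes the quality metadata column being detached when the
  # sequences are extracted; benign for a plain read tibble
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  suppressWarnings(tibble::tibble(
    read_id = names(x),
    seq = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  ))
}

#' @rdname read_fastq
#' @param reads Tibble with `read_id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual))
  names(x) <- reads$read_id
  # Biostrings warns that the quality metadata column is "dropped" even
  # though it is what gets written to the FASTQ; benign
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path))
  invisible(path)
}

#' Construct a multi-sample variant table
#'
#' The package's in-memory VCF: per-site records plus genotype and depth
#' matrices. Positions are 1-based (VCF convention); all interval types in
#' the package are 0-based half-open and converted at I/O boundaries.
#'
#' @param sites Tibble with `chrom`, `pos`, `id`, `ref`, `alt`, `qual`.
#' @param gt Character matrix (sites x samples) of GT strings
#'   (`"0|1"`, `"0/1"`, `"./."` ...).
#' @param dp Numeric matrix (sites x samples) of per-sample depths, or NULL.
#' @param samples Character vector of sample names (columns of `gt`).
#' @return An object of class `race_vcf`.
#' @export
new_vcf <- function(sites, gt, dp = NULL, samples = colnames(gt)) {
  stopifnot(nrow(sites) == nrow(gt), !is.null(samples))
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt))
  colnames(gt) <- samples
  structure(list(sites = tibble::as_tibble(sites), gt = gt, dp = dp,
                 samples = samples),
            class = "race_vcf")
}

#' @export
print.race_vcf <- function(x, ...) {
  cat("<race_vcf> ", nrow(x$sites), " sites x ", length(x$samples),
      " samples\n", sep = "")
  print(utils::head(x$sites, 5))
  invisible(x)
}

#' Read a VCF into a `race_vcf`
#'
#' Parsing is delegated to [vcfR::read.vcfR()]; multi-allelic records are
#' decomposed into one biallelic record per ALT allele (genotype indices
#' recoded to 0/1, other alleles set missing).
#'
#' @param path VCF file (plain text or bgzip).
#' @return A [new_vcf()] object.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_m <- vcfR::getFIX(v, getINFO = FALSE)
  if (is.null(dim(fix_m))) fix_m <- t(fix_m) # single-record files
  fix <- tibble::as_tibble(as.data.frame(fix_m, stringsAsFactors = FALSE))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_raw)))
    gt_raw <- matrix(gt_raw, nrow = 1, dimnames = list(NULL, names(gt_raw)))
  dp_raw <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                     error = function(e) NULL)
  samples <- colnames(gt_raw)
  sites <- tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID), ".", fix$ID),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )
  gt <- gt_raw
  dp <- if (is.null(dp_raw)) matrix(NA_real_, nrow(gt), ncol(gt)) else dp_raw
  # decompose multi-allelic records
  multi <- grepl(",", sites$alt)
  if (any(multi)) {
    pieces <- lapply(seq_len(nrow(sites)), function(i) {
      alts <- strsplit(sites$alt[i], ",", fixed = TRUE)[[1]]
      lapply(seq_along(alts), function(a) {
        g <- gt[i, ]
        g <- vapply(g, recode_allele, character(1), allele = a)
        list(site = dplyr::mutate(sites[i, ], alt = alts[a]),
             gt = g, dp = dp[i, ])
      })
    })
    pieces <- unlist(pieces, recursive = FALSE)
    sites <- dplyr::bind_rows(lapply(pieces, `[[`, "site"))
    gt <- do.call(rbind, lapply(pieces, `[[`, "gt"))
    dp <- do.call(rbind, lapply(pieces, `[[`, "dp"))
    colnames(gt) <- samples
  }
  new_vcf(sites, gt, dp, samples)
}

# recode a GT string so that allele index `allele` -> 1, 0 stays 0,
# any other alt allele -> missing
recode_allele <- function(g, allele) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return("./.")
  sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
  al <- strsplit(g, "[/|]")[[1]]
  al <- vapply(al, function(a) {
    if (a == ".") "."
    else if (a == "0") "0"
    else if (a == as.character(allele)) "1"
    else "."
  }, character(1))
  paste(al, collapse = sep)
}

#' Write a `race_vcf` to a VCF v4.2 text file
#'
#' Minimal writer emitting GT and DP per sample (plain text so outputs stay
#' diff- and pipeline-friendly).
#'
#' @param vcf A `race_vcf`.
#' @param path Output path.
#' @export
write_vcf <- function(vcf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=racesig",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vcf$samples), collapse = "\t")
  ), con)
  if (nrow(vcf$sites) == 0) return(invisible(path))
  dp_chr <- matrix(ifelse(is.na(vcf$dp), ".", as.character(vcf$dp)),
                   nrow = nrow(vcf$dp))
  body <- vapply(seq_len(nrow(vcf$sites)), function(i) {
    s <- vcf$sites[i, ]
    smp <- paste(vcf$gt[i, ], dp_chr[i, ], sep = ":")
    paste(c(s$chrom, s$pos, s$id, s$ref, s$alt,
            ifelse(is.na(s$qual), ".", format(s$qual, trim = TRUE)),
            "PASS", ".", "GT:DP", smp), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Genotype dosage matrix
#'
#' @param vcf A `race_vcf`.
#' @return Integer matrix (sites x samples) of alt-allele dosages 0/1/2,
#'   NA where any allele is missing.
#' @export
vcf_dosage <- function(vcf) {
  g <- vcf$gt
  d <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  d[g %in% c("0/0", "0|0")] <- 0L
  d[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[g %in% c("1/1", "1|1")] <- 2L
  d
}

#' Extract phased haplotypes from a `race_vcf`
#'
#' Requires fully phased, non-missing genotypes. The result is the
#' haplotype container used by the scan and window statistics: a 0/1
#' matrix with two rows per sample.
#'
#' @param vcf A `race_vcf`.
#' @param populations Optional tibble with `sample`, `population`.
#' @return A `hap_set`: list with `haplotypes` (2N x S integer matrix),
#'   `sites` tibble, `samples` tibble and `hap_sample` (row -> sample map).
#' @export
vcf_haplotypes <- function(vcf, populations = NULL) {
  g <- vcf$gt
  if (any(grepl("/", g, fixed = TRUE)))
    stop("vcf_haplotypes() requires phased genotypes (\"|\" separator)")
  if (any(grepl(".", g, fixed = TRUE)))
    stop("vcf_haplotypes() requires non-missing genotypes")
  a1 <- matrix(as.integer(substr(g, 1, 1)), nrow(g), ncol(g))
  a2 <- matrix(as.integer(substr(g, 3, 3)), nrow(g), ncol(g))
  n <- length(vcf$samples)
  hap <- matrix(0L, 2L * n, nrow(vcf$sites))
  hap[seq(1, 2 * n, by = 2), ] <- t(a1)
  hap[seq(2, 2 * n, by = 2), ] <- t(a2)
  hap_sample <- rep(vcf$samples, each = 2)
  rownames(hap) <- paste0(hap_sample, c("_1", "_2"))
  samples <- tibble::tibble(sample = vcf$samples)
  if (!is.null(populations))
    samples <- dplyr::left_join(samples, populations, by = "sample")
  new_hap_set(hap, vcf$sites, samples, hap_sample)
}

#' @rdname vcf_haplotypes
#' @param haplotypes 0/1 integer matrix, haplotypes x sites.
#' @param sites Site tibble (`chrom`, `pos`, ...), one row per column.
#' @param samples Tibble with `sample` (and usually `population`).
#' @param hap_sample Character vector mapping haplotype rows to samples.
#' @export
new_hap_set <- function(haplotypes, sites, samples, hap_sample) {
  stopifnot(nrow(sites) == ncol(haplotypes),
            length(hap_sample) == nrow(haplotypes))
  structure(list(haplotypes = haplotypes, sites = tibble::as_tibble(sites),
                 samples = tibble::as_tibble(samples),
                 hap_sample = hap_sample),
            class = "hap_set")
}

#' @export
print.hap_set <- function(x, ...) {
  cat("<hap_set> ", nrow(x$haplotypes), " haplotypes x ",
      ncol(x$haplotypes), " sites\n", sep = "")
  invisible(x)
}

# subset a hap_set to the haplotypes of the given samples
hap_subset <- function(hap, samples) {
  keep <- hap$hap_sample %in% samples
  new_hap_set(hap$haplotypes[keep, , drop = FALSE], hap$sites,
              dplyr::filter(hap$samples, .data$sample %in% samples),
              hap$hap_sample[keep])
}

#' Read gene models from GFF3
#'
#' GFF3 parsing is delegated to [rtracklayer::import()]; coordinates are
#' converted to the package-internal 0-based half-open convention. Gene
#' and CDS features are linked through the CDS `Parent` (or shared `ID`
#' prefix) attribute.
#'
#' @param path GFF3 file.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand` and a
#'   `cds` list-column of tibbles (`start`, `end`, `phase`), all 0-based
#'   half-open.
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_models() needs the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::as_tibble(as.data.frame(gr))
  genes <- dplyr::filter(df, .data$type == "gene")
  cds <- dplyr::filter(df, .data$type == "CDS")
  parent_of <- function(p) if (length(p)) sub("^gene:", "", p[[1]]) else NA_character_
  cds$gene_id <- vapply(cds$Parent, parent_of, character(1))
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gid <- g$ID
    cd <- dplyr::filter(cds, .data$gene_id == gid)
    tibble::tibble(
      gene_id = gid, chrom = as.character(g$seqnames),
      start = g$start - 1L, end = g$end,
      strand = as.character(g$strand),
      cds = list(tibble::tibble(start = cd$start - 1L, end = cd$end,
                                phase = as.integer(cd$phase)))
    )
  })
}

#' Write gene models to GFF3
#'
#' @param genes Gene-model tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(paste(g$chrom, "racesig", "gene", g$start + 1L, g$end, ".",
                     g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"), con)
    cd <- g$cds[[1]]
    for (j in seq_len(nrow(cd))) {
      writeLines(paste(g$chrom, "racesig", "CDS", cd$start[j] + 1L, cd$end[j],
                       ".", g$strand, cd$phase[j],
                       paste0("ID=", g$gene_id, ".cds", j, ";Parent=", g$gene_id),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED is 0-based half-open, matching the package-internal convention, so
#' coordinates pass through unchanged.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                  col_types = "ciic", progress = FALSE)
}

#' @rdname read_bed
#' @param x Interval tibble (`chrom`, `start`, `end`, `name`).
#' @export
write_bed <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end", "name")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a sample-to-population assignment table
#'
#' @param path Two-column TSV (`sample`, `population`), no header required.
#' @return Tibble with `sample`, `population`.
#' @export
read_populations <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("^sample\t", first)
  readr::read_tsv(path,
                  col_names = if (has_header) TRUE else c("sample", "population"),
                  col_types = "cc", progress = FALSE, skip = 0)
}
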