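---
title: "Methods: models, parameters and design choices in racesig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in racesig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racesig)
```

racesig compares crop subpopulations ("races") from whole-genome
sequence along two complementary routes: a reference-free k-mer route
(distances, sharing, race-specific sequence, gene presence–absence) and
a variant-based route (diversity, differentiation and haplotype-based
selection scans). This vignette explains the models behind each piece,
the parameters that matter, the synthetic-data generator the pipeline is
calibrated against, and the design decisions taken where the design was
genuinely open.

## 1. The k-mer route

### Canonical counting

Every window of length *k* over `{A,C,G,T}` contributes the
lexicographic minimum of itself and its reverse complement; windows
containing any other character (N and IUPAC ambiguity codes) contribute
nothing. *k* must be odd, which excludes palindromic k-mers that equal
their own reverse complement and would otherwise make canonicalization
ambiguous. Counting runs in compiled code; correctness is defined purely
set-theoretically and is checked against a plain substring-enumeration
oracle in the tests.

Two k presets circulate in this kind of study — 31 for hash-based read
counting and 47 for race-comparison work — and the two are genuinely in
tension in the literature this package follows. Neither is hard-coded:
every function takes `k` as an argument; 31 is the package default for
read-derived counting.

`min_count` implements the standard error guard: k-mers seen only once
in reads are overwhelmingly sequencing errors (a fresh error creates up
to *k* novel k-mers), so `min_count = 2` is the recommended setting on
reads and the default on assembled sequence is 1.

`choose_k()` scores each candidate k by the number of distinct k-mers
with abundance at least `min_count` — a proxy for the "genomic k-mer"
count that a full histogram-model fit estimates. On clean data both
scores share their argmax: the distinct count rises while `4^k/2` is the
binding constraint, then declines through repeat collapse and window
loss. Ties go to the smaller k (cheaper downstream).

### MinHash sketches and Mash distance

Sketches keep the *s* smallest 64-bit hashes of the distinct canonical
k-mer set. The hash is FNV-1a with a splitmix64 finalizer and a fixed
seed constant (42), so sketches are reproducible across runs and
platforms; hashes are stored as fixed-width hex strings because R has no
native unsigned 64-bit integer, and lexicographic order on those strings
equals numeric order. The Jaccard index is estimated on the merged
bottom-*s* sketch and converted to the Mash distance
`D = -(1/k) ln(2j/(1+j))`, with `j = 0` mapped to `D = 1` by convention.
With `s = 1000` the binomial sketch error keeps `|j_hat - j|` under
about 0.02, which the acceptance checks measure against exact Jaccard on
constructed sequence pairs.

### Sharing and group-specific k-mers

`sharing_decomposition()` assigns every distinct k-mer its exact
membership subset over the input samples; the per-cardinality tallies
partition the union by construction, and that partition is asserted, not
assumed. A k-mer is *group-specific* iff every sample containing it
belongs to one group — k-mers spanning two groups belong to nobody.

### Gene presence–absence

Read mapping is replaced by exact canonical k-mer lookup against the
reference: a k-mer hits every position whose canonical k-mer equals it,
multi-mapping k-mers hit all their loci, and per-base depth is the count
of overlapping hits. At k = 31 the chance of a spurious 31-mer match is
negligible, and the procedure is deterministic and dependency-free;
mismatch-tolerant mapping is deliberately out of scope. A gene is called
present when at least `min_support = 3` distinct k-mers intersect it —
support counts distinct k-mers, not occurrences, so depth cannot
substitute for breadth. Horizontal (covered-base fraction) and vertical
(mean depth) coverage are reported alongside; an optional horizontal
floor can be enabled as a secondary filter but is off by default, since
the 3-k-mer rule is the primary published criterion and the horizontal
range observed in real panels (0.4–1) suggests it was descriptive, not a
gate.

## 2. The variant route

### Filtering and descriptive statistics

`filter_sites()` applies the standard hard-filter triple — minor allele
frequency, mean depth over non-missing samples, site quality — with
inclusive (`>=`) boundaries, vcftools-style, since published pipelines
list flag values without stating boundary semantics. The first failing
criterion per dropped site is logged in the order maf, depth, quality,
and the operation is idempotent. Multi-allelic records are decomposed
into biallelic records at parse time (other alt alleles become missing);
missing genotypes never enter MAF or depth denominators.

### Effect annotation

The annotator is a minimal codon rewriter, not a full effect-ontology
engine: for a SNP inside a CDS the affected codon is rebuilt with the
alternate allele, respecting strand and phase, and classified as
synonymous, non-synonymous, stop gained/lost or start lost; gene-body
SNPs outside CDS are intronic, the rest intergenic. Impact follows the
conventional mapping (high for start/stop changes, moderate for
non-synonymous, low for synonymous, modifier for non-coding). Reference
CDSs with internal stops, or sites whose stated reference allele
disagrees with the reference sequence, are flagged and skipped rather
than guessed at. "Start gained" annotation would require UTR models,
which the gene representation does not carry, so it is not emitted.

## 3. Diversity, differentiation, LD

Per-site π uses the unbiased pairwise form `2·c_ref·c_alt/(n(n−1))`;
windowed values are sums of per-site values divided by window length, so
no re-normalization drift can arise. Tajima's D is implemented with the
full 1989 constant set and verified against an independent long-hand
transcription to 1e−10; windows with no segregating sites are flagged
NA and excluded from scans. At n = 2 the variance constants vanish
identically along with the numerator, and D is defined as 0 there.

Weir–Cockerham F<sub>ST</sub> uses the 1984 two-level variance
components computed from per-population sample sizes, allele frequencies
and *observed* heterozygosities; negative estimates are reported as-is,
and multi-site summaries are ratios of sums (Σa/Σ(a+b+c)), the
recommended combination rule.

LD decay computes r² on haplotypes when input is phased and on genotype
dosages (Rogers–Huff style) otherwise, recording the basis; pairs are
binned by distance with no monotone smoothing. Under linkage
equilibrium the expected r² is the 1/n sampling floor, which the tests
assert.

Windows default to fixed-width, non-overlapping 100 kb — the bin width
is a free parameter in the source analyses and is exposed as an argument
everywhere. The composite classifier marks windows in the chosen
Tajima's-D tails (default 5% each) and the bottom tail of windowed
F<sub>ST</sub> (default 5%, empirical quantiles — no distributional test
is available for "significantly low"); extreme-D windows that also sit
in the low-F<sub>ST</sub> tail are labelled `purifying_expansion`, the
recent-population-expansion signature. The raw D sign and both class
columns are kept so users can re-alias labels; the literature is not
internally consistent about which D sign maps to which selection story,
and the package does not adjudicate.

## 4. Haplotype scans

EHH among the carriers of an allele is the probability that two randomly
chosen carriers are identical over the whole stretch from the focal site
outward; it is computed by incremental haplotype-group refinement in
compiled code and checked exactly against exhaustive enumeration. iHH
integrates the EHH curve by trapezoid over physical distance, truncating
a side after the first site whose EHH falls below the cutoff (default
0.05, the rehh convention; the segment reaching that site is included).
No gap-scaling penalty is applied between distant markers — distances
enter only through trapezoid widths — a documented deviation from some
implementations. EHH never extends across a chromosome boundary.

iHS is `ln(iHH_A/iHH_D)` standardized within derived-allele-frequency
bins (50 equal-width bins, bins with fewer than 10 sites merged into
their nearest neighbor); sites with minor allele frequency below 0.05 or
zero/undefined iHH on either allele are excluded and flagged. Ancestral
polarity comes from the simulator's truth channel; for external data the
reference allele is taken as ancestral, which callers should treat as an
assumption, not a fact. XP-EHH uses all-haplotype EHH per population and
standardizes genome-wide (the standard choice for a two-population
statistic; per-bin standardization would reabsorb exactly the frequency
differentiation the statistic is meant to see). Positive scores mean
longer haplotypes in the first population, and swapping populations
negates scores exactly.

p-values are two-sided normal tails of the standardized scores;
correction is BH by default with Bonferroni available (the two are kept
distinct because "Bonferroni FDR" in the source literature conflates
them), and the procedure used is recorded on the result. Significant
sites within `merge_gap = 10` kb on one chromosome merge into a sweep
region — region construction from significant sites is not defined in
the source analyses, so the gap is an explicit free parameter — and
genes are partitioned into those overlapping the region and those within
5 kb of a flank.

## 5. Interval algebra and relatedness

Intervals are 0-based half-open everywhere inside the package; VCF
(1-based) and GFF3 (1-based inclusive) are converted at the I/O
boundary, BED passes through. Overlap queries match the all-pairs
definition exactly. Cross-set region identity for Venn-style tallies is
reciprocal overlap at 50% of both lengths, transitively closed —
"the same region seen in several races" has no published definition, so
the threshold is a parameter.

The SNP distance is allele sharing (1 − IBS over co-non-missing sites);
the distance behind published NJ trees is rarely stated, and allele
sharing is the conventional neutral choice. NJ agglomeration itself is
standard and delegated to `ape::nj()`; negative branch lengths are then
clamped to zero with the deficit transferred to the sibling branch,
preserving path lengths through the parent. Bootstrap support resamples
sites (columns), not samples, and counts bipartition recovery. PCoA is
classical Gower double-centering via eigendecomposition; negative
eigenvalues are reported, never silently dropped, and requested axes
beyond the positive spectrum are zero-padded.

## 6. The synthetic-data generator

The generator defines the study conditions the pipeline is validated
under; it is first-class, tested code.

* **Structure.** The Balding–Nichols island model: each site draws an
  ancestral frequency p ~ U(0.05, 0.95) and each population draws its
  frequency from Beta(p(1−F)/F, (1−p)(1−F)/F), where F is that
  population's divergence parameter. F = 0 copies p exactly. The
  expected pairwise Weir–Cockerham F<sub>ST</sub> between populations i
  and j is ≈ (F_i+F_j)/2; a full target matrix is converted to
  per-population F by least squares. Defaults put F in the 0.04–0.18
  range typical of crop race panels. Coalescent simulation was
  considered and set aside: the single-parameter mapping from F to
  F<sub>ST</sub> is direct, and sweeps need deterministic strength
  control (below).
* **Neutral spectrum.** The uniform ancestral-frequency spectrum is
  right for differentiation studies but far from the neutral site
  frequency spectrum, so Tajima's D cannot be calibrated on it. The
  `spectrum = "neutral"` mode instead draws each site's derived-allele
  count i ∈ {1, …, 2N−1} with probability ∝ 1/i (the fixed-S neutral
  SFS) and scatters carriers uniformly; under it E[θπ] = E[θW] exactly,
  so D is centred at 0 by construction and the calibration checks test
  the implementation, not the generator.
* **Sweeps.** Hard sweeps are imposed, not forward-simulated: a fraction
  (the strength proxy) of the target population's haplotypes is
  overwritten with one template haplotype over a window (default 100 kb,
  50 kb in the calibration runs) centred on the sweep position, with the
  focal site forced derived. Strength 1 means local fixation; strength 0
  is a no-op. This gives exact, deterministic control of the quantity
  the scans respond to — locally elevated haplotype homozygosity — at
  the cost of realism in the sweep's flanking decay pattern.
* **Genomes, PAVs and reads.** Each accession's genome is the ancestral
  sequence with its first haplotype's alternate alleles substituted.
  Deleted genes are excised together with a 50 bp flanking buffer: real
  deletions do not respect gene boundaries, and the buffer prevents the
  deletion junction from coincidentally reproducing the gene's first
  bases (a ~4^−n event per junction that would otherwise contaminate
  the PAV truth tables). Truth tables record every PAV and, for genes
  retained by exactly one population, the realized private gene
  sequences per retaining accession. Reads are placed uniformly with
  per-base substitution errors at the configured rate and the matching
  Phred quality (capped at Q40).
* **Determinism.** Every stage seeds the RNG at the master seed plus a
  fixed offset (frequencies +101, haplotypes +102, genomes +103, reads
  +104), so a configuration reproduces byte-identical output.

What the generator does *not* emulate: recombination maps and realistic
LD decay profiles, indels other than whole-gene deletion, demography
beyond the island model, coverage biases, mapping artifacts, and real
ancestral-state uncertainty. Passing the calibration suite therefore
demonstrates that the statistics are computed correctly and respond to
the signals they target at realistic effect sizes — not that the
pipeline's power estimates transfer quantitatively to any particular
real panel.

## 7. Problem sizes and numerical choices

The calibration experiments run at: F<sub>ST</sub> recovery with 2
populations × 50 diploids at 10,000 sites over 5 replicates; neutrality
calibration on 2 × 1 Mb chromosomes with 2,000 sites each (~200 windows
of 10 kb); sweep power at strength 0.9 with 100 haplotypes over 20
replicates; FDR behaviour on 20 × 10,000 uniform p-values; PAV recovery
on a 5-race, 60-gene, 50-deletion panel at 10× coverage and 1% read
error. These sizes were chosen once as the smallest panels at which the
expected effects are comfortably resolvable (e.g., the ±0.02
F<sub>ST</sub> tolerance is several Monte-Carlo standard errors at
10,000 sites).

Two statistical subtleties deserve note. Locus-level sweep power is
scored as the maximum |iHS z-score| inside the truth window reaching the
genome-wide top percentile: a swept window's own sites legitimately fill
the extreme tail, so a single-site rank check would measure tie-breaking
among the sweep's sites rather than detection. And under a complete
uniform null the per-replicate false-discovery proportion of BH is 0 or
1 with E[FDP] = α exactly, so a 20-replicate sample mean sits at or
above α about a quarter of the time no matter how correct the
implementation; the test suite therefore uses the exact one-sided
binomial acceptance region (at most 3 of 20 replicates with any
rejection) as the control check, and the acceptance script reports the
raw mean FDP.

## 8. Known limitations

* Exact-lookup PAV calling cannot see genes that diverged by more than
  scattered SNPs; it measures presence of near-identical sequence.
* iHS/XP-EHH power depends on marker density around the sweep; the
  simulator's independent-site background understates the long-range LD
  of real genomes, which mainly affects the null EHH decay rate (and is
  why the EHH cutoff matters little here).
* The codon annotator handles SNPs only; indel effects and full
  effect-ontology grammars are out of scope.
* Bootstrap support and NJ assume the distance matrix is meaningful at
  the site counts provided; no LD pruning is applied before PCoA.
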