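---
title: "Promoter SNP variability: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter SNP variability: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promvar)
```

# The question and the statistic

Promoters — the few hundred bases upstream of a transcription start site
(TSS) — harbour the binding sites through which transcription factors set
a gene's expression level. A single-nucleotide polymorphism (SNP) in this
region can change binding affinity and hence expression, so a gene family
whose promoters are systematically more polymorphic than the genome-wide
background is a candidate for regulatory diversity at the population
level. Olfactory receptor and HLA gene families are the canonical
examples.

The core per-transcript statistic is deliberately simple: the **SNP
content**, i.e. the number of qualifying SNP records falling in a fixed
window upstream of the transcript's anchor. Everything downstream —
SNP-rich subsets, group tests, gene-set enrichment — is a function of
this count.

# Coordinate and window conventions

All coordinates are 0-based half-open, the convention in which UCSC
stores genePred and SNP tracks; this removes every ±1 ambiguity from the
window arithmetic:

* the TSS boundary is `tx_start` (`+` strand) or `tx_end` (`−` strand);
  the CRS (coding region start) boundary is `cds_start` / `cds_end`;
* the upstream window of length L at boundary b is `[b − L, b)` on `+`
  and `[b, b + L)` on `−`. The window is *strictly* upstream: a SNP at
  position b lies in the transcript body on the `+` strand and is not
  counted. The mirror-symmetry test (flip every coordinate and strand)
  guarantees the two strands are treated identically;
* windows running past position 0 are clipped, not discarded — dropping
  telomere-proximal genes would silently bias gene-family comparisons —
  and the `effective_length` column records the bases actually covered so
  users can exclude short windows if they prefer;
* the 5′UTR length is the TSS→CRS distance; zero encodes a transcript
  with no annotated 5′UTR. Analysis cases either admit these
  (`5'UTR ≥ 0`) or exclude them (`5'UTR > 0`), because a missing 5′UTR
  annotation makes "upstream of the TSS" partly mean "upstream of the
  CRS".

The six default cases — (≥0, TSS, 500), (≥0, TSS, 1000), (≥0, CRS, 500),
(>0, TSS, 500), (>0, CRS, 500), (>0, CRS, 1000) — triangulate whether an
enrichment is attributable to the promoter proper, the 5′UTR, or both;
the full 2×2×2 matrix is available via `default_cases(full = TRUE)`.

# Transcript selection

`filter_transcripts()` applies, in order: curated accessions only
(`NM_`), canonical chromosomes (1–22, X, Y), protein-coding only
(`cds_start < cds_end`; the CRS anchor is undefined otherwise), then one
transcript per distinct (chrom, strand, TSS) key. Two choices here were
genuinely open and are worth recording:

* **Duplicate-TSS survivor.** When several transcripts share a TSS the
  analysis keeps exactly one; which one is statistically irrelevant
  (identical windows give identical contents) but affects reported
  accessions, so the lexicographically smallest accession is kept — a
  deterministic, reproducible tie-break. The dedup key includes strand by
  default (`dedup_strand = FALSE` collapses opposite-strand collisions
  too, for sensitivity analysis).
* **Order of operations.** Non-coding records are removed *before* TSS
  dedup, so a non-coding transcript can never displace a coding one at a
  shared TSS. The filter is idempotent.

Accessions mapping to multiple loci (common for olfactory-receptor genes)
are kept as separate records; dropping them would bias exactly the family
this kind of analysis usually targets.

# SNP qualification and counting

Qualifying SNPs have class `single` and carry the `by-1000genomes`
validation token (matched case-insensitively with hyphen/underscore
equated, because UCSC releases are inconsistent). Records are counted as
point positions; two distinct rsIDs at one position count twice (only
exact (chrom, pos, rsid) duplicates are collapsed at parse time, with a
count in the reader's report), since density estimates are per track
record. Windows of different transcripts may overlap and are counted
independently.

Counting is two binary searches per window over the per-chromosome sorted
position vector. The test suite holds this against a naive per-record
scan on hundreds of random instances — an intentionally dumb oracle that
cannot share a bug with the fast path.

# The group-vs-background test

For threshold N, p₁ and p₂ are the fractions of group and background
transcripts with content ≥ N. On the angular scale y = 2·arcsin(√p) the
sampling variance of y is approximately 1/n independent of p, so

$$z = \frac{y_1 - y_2}{\sqrt{1/n_1 + 1/n_2}}$$

needs no estimated variance. Three decisions were open:

* **Reference distribution.** Because no variance is estimated, there is
  no natural Welch–Satterthwaite df; the statistic is referred to the
  standard normal. Output keeps the field's customary "t-test for arcsine
  transformed proportions" labelling, and `df = NULL` (n₁ + n₂ − 2) is
  available for sensitivity analysis — at the sample sizes involved the
  two are numerically indistinguishable.
* **Sidedness.** One-sided (group > background) by default, since the
  scientific hypothesis is enrichment; two-sided is a flag.
* **Background composition.** The background is the whole-genome table
  *including* the group, which mirrors how such comparisons are usually
  reported; it makes the test slightly conservative because the two
  proportions are positively correlated. A disjoint-background mode
  (`background = "disjoint"` in the pipeline config) subtracts the group.
  The end-to-end null-calibration band in the acceptance tests
  ([0.02, 0.08] rather than a tight nominal band) accounts for this
  overlap.

No multiple-testing correction is applied across the N-sweep by default —
the thresholds are nested and highly dependent, and the sweep is a
robustness display, not twenty independent hypotheses. P-values are
stored at full precision; significance flags are derived columns.

# Gene-set enrichment

Fold enrichment is (k/n)/(K/N_bg) and the EASE score is the one-sided
Fisher exact (hypergeometric upper-tail) p-value with the overlap
decremented by one — a conservative variant that penalizes sets supported
by a single gene (so EASE ≥ Fisher always, and k = 1 can never look
significant). The effective universe counts only genes annotated by at
least one supplied set, the usual annotation-tool behaviour; the
background is user-supplied (typically all genes in the filtered catalog)
rather than a frozen annotation snapshot, so published values from tools
with internal backgrounds are reproducible only up to that choice.
Transcripts are collapsed to gene symbols before counting. The reporting
screen keeps sets with k ≥ 2 and EASE ≤ 0.1, with p < 0.05 as a separate
flag, and Benjamini–Hochberg adjustment is available as an opt-in column.
No GO-graph propagation is performed: a gene belongs to exactly the sets
that list it (sets arrive as flat GMT).

# The synthetic world

`simulation_spec()` fixes the generator's stated world. Values that the
analysis context dictates are: 20 000 transcripts, one designated group
of 400, baseline density λ₀ = 0.0037 SNPs/bp (3.7 per kb, the genome-wide
upstream-region density from the 1000 Genomes-era dbSNP), elevation
multiplier ρ = 1.5 over the 1000 bp upstream of group TSSs, and a
zero-length-5′UTR weight of 0.05 (matching the ≈4.6% of curated human
transcripts without an annotated 5′UTR). Values neither source fixes were
chosen once, for realism at desk scale, and are not tuned: 4 chromosomes
of 30 Mb (keeps the genome ~120 Mb so a 500-replicate study fits a
minute-scale budget while per-window statistics are unchanged by total
genome size), transcript lengths uniform on 1–100 kb (overlap permitted —
transcript bodies never enter the statistic), strand probability 0.5, and
a geometric positive 5′UTR part with mean 170 bp (the order of real
median 5′UTR lengths).

Design choices:

* **Per-base Bernoulli, not Poisson**, so `snp_content ≤
  effective_length` holds structurally. It is implemented as a binomial
  count plus uniform sampling of distinct positions, which is the same
  process, vectorized.
* **Elevation applies to the union of group members' 1000-bp TSS
  windows**, so every default analysis case (500/1000 × TSS/CRS) sees the
  planted signal; baseline SNPs inside the union are removed before
  redrawing at λ₀ρ, keeping the realized rate exactly λ₀ρ rather than
  λ₀ + λ₀ρ.
* **Substream seeding.** One master seed expands into independent
  per-stage seeds (annotation, SNPs), so adding a stage never perturbs
  earlier draws and `simulate_snps()` is reproducible independently of
  when the annotation was drawn.

What the generator does *not* emulate: linkage disequilibrium, allele
frequencies, mutation-rate heterogeneity (CpG islands, recombination
hotspots), chromosome-length variation, shared promoters of divergent
gene pairs, and annotation error. A green simulation test therefore
establishes that the pipeline recovers a planted uniform-density signal
at the stated effect size and is calibrated under a uniform null — not
that real promoter SNP counts are binomial, nor anything about any
particular genome snapshot.

# Numerical and degenerate-input notes

* `angular_transform` rejects inputs outside [0, 1]; p = 0 and p = 1 map
  exactly to 0 and π, so all-zero and all-hit groups are well defined
  (the boundary z = π/√(1/n₁ + 1/n₂) case is tested in closed form).
* Equal proportions give z = 0 and one-sided p = 0.5 exactly — including
  the 0/n vs 0/m case.
* The EASE tail is computed via the hypergeometric distribution function;
  tests hold it to 1e−10 against direct `choose()` enumeration over all
  small tables, and `ease_p ≥ fisher_p` is asserted everywhere.
* Empty inputs (no SNPs, no transcripts satisfying a 5′UTR requirement,
  empty gene sets) produce empty, well-typed results rather than errors;
  the only fatal degeneracies are empty content tables handed to the
  sweep and an empty enrichment background.
* TSV outputs are written with C-locale numerics; re-reading a written
  content table restores counts and the analysis-case attribute exactly.

# Known limitations

* Genome-scale published counts (total curated transcripts, percent of
  promoters with ≥1 SNP, specific SNP-rich gene lists) are functions of
  versioned external snapshots and are out of scope; the package
  reproduces the *method*, with correctness anchored in oracles and a
  hand-audited fixture instead.
* The angular-transform test treats transcripts as independent; tandem
  gene clusters with overlapping windows (olfactory-receptor loci!)
  violate this mildly. The one-sided normal test is anti-conservative
  under strong local dependence — a permutation null would be the
  extension of choice.
* VCF ingestion is minimal (single-base REF/ALT records only, no INFO
  parsing) and exists to let users bypass the UCSC dialect, not to
  replace a variant toolkit.
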