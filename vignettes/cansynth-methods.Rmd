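---
title: "Methods: paralog typing and transcript quantification for cannabinoid synthase gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paralog typing and transcript quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The *Cannabis sativa* cannabinoid synthases — THCAS, CBDAS and CBCAS — are
single-exon paralogs of 1635–1638 nt sharing roughly 84–96% nucleotide
identity between gene classes and more than 99% within a class. Three things
make them analytically awkward: (i) clones of one class differ from their
reference by only a handful of private SNPs, so class membership cannot be
read off overall identity alone near the class boundary; (ii) PCR assays
cross-amplify unless primers are anchored on class-diagnostic positions;
(iii) transcript quantification requires class-specific RT-qPCR with careful
reference-gene normalization because the targets span two orders of
magnitude of expression.

`cansynth` implements the complete desk-side toolchain for this situation:
cds completeness classification, SNP and substitution-effect annotation,
diagnostic-position discovery and clade classification, in-silico PCR with a
primer-specificity screen, B-locus chemotype marker interpretation,
distance-based phylogenetics, and standard-curve RT-qPCR quantification —
plus a synthetic-data generator that reproduces the statistical structure of
such a gene family so every stage can be validated against known truth.

# Sequence model and coordinate conventions

All cds positions are 1-based from the A of ATG; codon (residue) index is
`floor((pos - 1)/3) + 1` with Met = residue 1. A *complete* cds starts with
ATG, ends with an in-frame TAA/TAG/TGA, has length divisible by 3 and no
internal stop. An internal stop or a frameshift length makes a *pseudogene*;
a missing start or terminal stop makes a *fragment*. Ambiguity codes are
tolerated in the cds body (they translate to `X` with a warning) but not in
the first or last codon, where completeness must be decidable.

One known numbering subtlety: a substitution at nt 986 lies in codon 329 by
the standard formula, although residue numbers one lower are sometimes seen
in the literature for this position (off-by-one conventions around the
initiator Met). The package applies the standard formula everywhere and does
not special-case any position.

Percent identity between equal-length sequences is positional — the family's
cds are co-linear, so no alignment step is interposed — and is rounded
half-up to two decimals, the precision at which such identities are
conventionally reported (one mismatch over 1635 nt = 99.94). Unequal lengths
fall back to a global alignment (match +1, mismatch −1, gap −2, end gaps
penalized) with identity = matches / alignment columns. Indels are excluded
from SNP tables and reported separately, keeping SNP counts
substitution-only.

# Clade typing

`discover_diagnostic_positions()` requires *strict fixation*: a position
qualifies only when every member of one set carries one unambiguous base and
every member of the other set a different one. A minor-allele tolerance knob
exists (`max_minor_freq`) but defaults to 0; relaxing it trades specificity
for robustness to sequencing errors and should be done deliberately.

`classify_sequence()` assigns a class iff **all** diagnostic alleles match
and identity to the class reference is at least `identity_threshold`
(default 97%). The default separates the observed within-class identities
(>99%) from between-class identities (95.7–96.0% for CBCAS vs THCAS) with
margin on both sides; it is configurable because other gene families will
sit elsewhere. Ambiguity codes at a diagnostic position count as
non-matching: a position that cannot be read cannot support a call. Ties are
broken by highest identity, then by profile registration order, and the
rationale string records the decision.

# In-silico PCR

Primer binding uses the standard in-silico proxy for extension competence: a
site qualifies with at most `max_mismatch` (default 2) mismatches overall
and zero mismatches in the `clamp_3prime` (default 3) bases at the 3' end.
IUPAC codes in the template match any compatible base. These two knobs are
deliberately exposed: the true wet-lab tolerance depends on polymerase and
conditions and cannot be derived from sequence alone. Product lengths are
measured 5' end of one primer footprint to 5' end of the other, inclusive,
so a pair sitting exactly on start and stop codons returns the cds length
(1635 bp for the CBDAS pair shipped in the fixture).

The specificity screen mirrors the three-step wet-lab validation as far as
it is computable: PASS requires at least one predicted product on every
positive template and none on any negative. The melting-curve step is not
physically modelled; a rough Tm (Wallace rule below 14 nt, otherwise
`64.9 + 41(GC − 16.4)/N`) is attached to the report for orientation only and
never filters anything.

B-locus marker bands are matched to the 1080/1081-bp (functional CBDAS) and
1192-bp (functional THCAS) classes with a ±5 bp tolerance — the CBDAS band
is reported at both 1080 and 1081 bp in practice, so the two are one class.
THCAS-only patterns are called chemotype I, two-band patterns chemotype II,
CBDAS-only patterns the CBDA-dominant classes III–V, which this marker
cannot distinguish. The packaged three-primer panel is synthetic
(`synthetic_b_marker_panel()`): it reproduces the band logic on constructed
haplotype templates, not the proprietary primer sequences.

# Phylogenetics

Pairwise distances support p-distance, JC69 and TN93, computed pair by pair
with pairwise deletion (columns with a gap or ambiguity in either member are
excluded for that pair), so the TN93 base frequencies are empirical
frequencies of each pair's retained sites. TN93 is the default model: the
maximum-composite-likelihood distances of common GUI phylogenetics software
are not reproducible outside it, and TN93 is the closest widely specified
model (unequal base frequencies, separate purine/pyrimidine transition
rates). Under balanced composition and a uniform substitution pattern TN93
reduces to the JC69 closed form, which the test suite verifies to 1e−9.

Tree construction is Saitou–Nei neighbor joining (via ape), exact on
additive matrices; negative branch estimates, which NJ produces on noisy
input, are clamped to zero with a warning. Bootstrap support resamples
alignment columns, rebuilds the tree per replicate and scores the original
tree's bipartitions. Two numerical choices matter here: zero-length internal
edges of the point-estimate tree are treated as unresolved *before* scoring
(an alignment of identical sequences therefore collapses to a star rather
than inheriting an arbitrary resolution with spurious 100% support), and
edges below the `collapse_below` threshold (default 50%) are contracted into
polytomies. Codon-position filtering is not implemented; all positions are
used, subject to pairwise deletion. The package does not build multiple
alignments — synthase cds are co-linear, and `check_colinear()` verifies the
assumption instead.

# RT-qPCR quantification

The standard-curve method is used throughout. A curve is an OLS fit of Cq on
log10 input over a dilution series (the emulated design: 5 points of 1:4
serial dilutions); amplification efficiency is `E = 10^(−1/slope) − 1`, so a
perfectly doubling assay has slope ≈ −3.3219 and E = 1. Technical replicates
are averaged on the Cq scale before interpolation — averaging before the
exponential transform is the lower-variance choice when the noise is
additive in Cq, which is how qPCR instruments behave.

Relative quantity per biological replicate is the target quantity divided by
the geometric mean of the reference-gene quantities; per genotype, RQ is the
mean over biological replicates with SEM = SD/√n (n = biological replicates
only). A target undetermined in every replicate is reported `n.d.` and
excluded from testing; a replicate with an undetermined reference gene is
dropped with a warning, since its normalizer is undefined.

Reference-gene stability is ranked by a fully specified stand-in for
multi-tool web consensus rankers: (a) a geNorm-style M value — the mean SD,
across samples, of pairwise log2 expression ratios against each other
candidate (computed on Cq differences, i.e. assuming ideal doubling for the
ratio scale) — and (b) a comparative ΔCt SD — the SD of the gene's Cq minus
the mean Cq of the other candidates; the final rank is the geometric mean of
the two ranks, with ties broken by ΔCt SD then name. With only three
candidates both scores are dominated by the noisiest partner gene, which
limits how finely two quiet genes can be separated: in simulations with
per-gene noise SDs 0.05/0.2/0.8, full-order recovery is about 78% at the
study-like panel size of 39 samples and exceeds 95% from roughly 250
samples. The consistency property in the test suite is therefore exercised
at 250 samples; the estimator itself is identical at any panel size.

Genotype-vs-baseline comparison is a two-sided Student's t-test with pooled
variance on natural-log-transformed per-replicate RQs — the log transform
makes fold-changes symmetric and stabilizes the variance — with the
conventional star thresholds (* p < 0.05, ** p < 0.01, *** p < 0.001).
Replicates with non-positive RQ are dropped from the log transform with a
warning.

# The synthetic-data generator

`simulate_gene_family()` emulates the structure observed in resequenced
synthase families: a random ancestor cds of 1638 nt (545 codons + stop, the
THCAS/CBCAS length), two clades fixed apart at positions 13, 18 and 1628
from the starting codon, and 3–8 private substitutions per clone — the
per-clone SNP range observed in such surveys. Private SNPs avoid the
diagnostic positions, the start and stop codons, and a protected window
covering the catalytic residues (Arg110–His114, Cys176, which the generator
sets to their canonical identities), and never create an in-frame stop.
A configurable fraction of clones is designated pseudogene and receives one
internal stop. Every run returns a truth table sufficient to score each
downstream call, and identical seeds give byte-identical FASTA.

What the generator does *not* emulate: indels, recombination, copy-number
variation, transition/transversion bias, and sequencing error. Tests passing
on this generator therefore demonstrate algorithmic correctness on clean
co-linear families, not robustness to alignment artefacts or base-calling
noise.

`simulate_qpcr_plate()` draws every well as
`Cq = intercept − log10(q)/log10(1 + E) + Normal(0, noise_sd)` — the
exponential-phase idealization of amplification — with a default Cq noise SD
of 0.15, a typical technical scatter. The default design mirrors the study
panel: 13 genotypes × 3 targets + 3 candidate references, 3 biological × 3
technical replicates, with true absences (THCAS in hemp, CBDAS in the
THCA-predominant genotype) producing undetermined Cq. Where the study prints
an RQ the printed value is used as the true expression input; unprinted hemp
levels are fixed plausible values inside the printed ranges. These are
simulation inputs, not expected outputs.

# Problem sizes used by the checks

The bundled verification runs at desk scale, chosen to finish in minutes on
one core while leaving no property under-powered: NJ exactness over 100
random additive 6-taxon matrices (tolerance 1e−9), an exhaustive 15-topology
least-squares oracle at 5 taxa, bootstrap properties at 20–200 replicates on
6–8 taxa, qPCR ratio recovery (true ratios 2/15/300) over 100 seeded plates
per ratio at 3×3 replicates, and stability ranking over 200 runs of a
250-sample panel. The 202-taxon tree and absolute RQ magnitudes of the
original study depend on external sequence archives and wet-lab material and
are deliberately out of scope.

# Worked example

```{r example}
library(cansynth)

sim <- simulate_gene_family(family_config(seed = 42))
profiles <- profiles_from_simulation(sim)
typing <- run_type_seqs(sim$records, profiles)
typing$summary

plate <- simulate_qpcr_plate(seed = 42)$plate
quant <- run_qpcr(plate, c("THCAS", "CBDAS", "CBCAS"),
                  c("CsClathrin", "CsRAN", "CsActin"),
                  baseline_genotype = "CINRO")
head(quant$summary)
```

# Known limitations

* Classification assumes co-linear cds; families with indel variation need
  external alignment first, after which positional coordinates refer to the
  alignment.
* The in-silico specificity screen is a sequence-level proxy; it cannot see
  concentration- or temperature-dependent effects, which in the wet lab can
  rescue (or doom) a borderline pair.
* The Tm estimate is deliberately crude and is never used as a filter.
* TN93 distances are not numerically identical to maximum-composite-
  likelihood distances; trees on real family data will differ slightly in
  branch lengths from GUI-software output, though not in well-supported
  topology.
* The stability ranking is a two-score consensus, not a reimplementation of
  any specific web tool; rankings can differ from such tools in close calls.
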