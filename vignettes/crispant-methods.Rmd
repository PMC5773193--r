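---
title: "Quantifying mosaic CRISPR-Cas9 mutagenesis in F0 animals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mosaic CRISPR-Cas9 mutagenesis in F0 animals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispant)
library(dplyr)
```

## The problem

Injecting Cas9 with one or several single guide RNAs (sgRNAs) into a
one-cell embryo produces a mosaic F0 animal: editing happens over the first
cleavage divisions, so different cells carry different alleles — wildtype,
frameshift indels, in-frame indels, and indels outside coding sequence.
Screening phenotypes directly in F0 ("crispant") animals is attractive
because it avoids two generations of breeding, but it is only interpretable
if one can quantify, per animal, how likely it is that *both* alleles of
the target gene are disrupted. `crispant` implements that quantification
from amplicon deep sequencing:

1. align each animal's amplicon reads to the reference and call
   insertion/deletion/substitution events;
2. attribute indels near each sgRNA's predicted cut site to CRISPR
   activity and classify every read per target as unmodified, frameshift,
   in-frame or non-coding;
3. convert the per-target allele fractions into the probability that each
   of the two alleles carries at least one (frameshift) mutation, for
   single sgRNAs and for a pooled panel;
4. profile the sgRNA-specific indel spectrum across a cohort;
5. optionally relate genotype to a morphometric phenotype through a
   normalized head-size ("microcephaly") index.

A synthetic-cohort generator with exact ground truth makes the entire
pipeline testable without sequencing data.

## Reference geometry

Coordinates are 0-based and half-open throughout; cut sites are
between-base integers. This is stated once and holds in every module: it
makes interval arithmetic (window overlap, coding overlap) unambiguous.

SpCas9 cuts between the third and fourth nucleotide upstream of its NGG
PAM. For a `+`-strand protospacer occupying `[s, s+20)` with PAM at
`[s+20, s+23)`, the cut coordinate is `c = s + 17`; the `-` strand is the
mirror image (`c = s + 3` with the PAM immediately 5' of the protospacer on
the reference). Targets are validated against the amplicon before any read
is processed: the protospacer must match the reference at the implied
location (reverse complement for `-`) and the PAM must read NGG on the
target strand; mismatches abort with the offending coordinates.

Indels are attributed to CRISPR activity only within a **quantification
window** of `w` reference bases on each side of the cut, `[c-w, c+w)`,
with insertion anchors accepted on the closed range `[c-w, c+w]`. The
default half-width is `w = 5`. The phrase "a window of five nucleotides
around the cleavage site", common in amplicon-sequencing methods, is
ambiguous between 5 bases total and 5 per side; we adopt the ±5 convention
used by the standard amplicon quantification tools (CRISPResso's window
parameter has the same meaning) and expose `window_halfwidth` so either
reading can be enforced.

## Alignment and event calling

Amplicon reads are designed to span the whole amplicon, so reads are
aligned end-to-end (Needleman–Wunsch) with affine gap penalties rather than
locally: this avoids soft-clip ambiguity at read ends. Defaults are match
+2, mismatch −4, gap open −10, gap extend −1 — ordinary values for short
high-identity reads; they are configurable and carry no special
justification beyond favouring a single contiguous gap over scattered
mismatches at plausible error rates. Alignment itself is delegated to
`Biostrings::pairwiseAlignment()`; identical reads are dereplicated first
and carried with counts, which makes deep samples with few distinct alleles
(the typical mosaic amplicon) cheap to process.

From each alignment, maximal gap runs become single insertion/deletion
events and each mismatch column a length-1 substitution. Two
normalizations matter for reproducibility:

* **Left alignment.** Equal-scoring indel placements (homopolymers,
  repeats) are shifted to the leftmost equivalent reference coordinate,
  VCF-style, so event coordinates are deterministic across
  implementations. Normalization provably preserves the edited sequence.
* **Terminal gaps are coverage, not deletions.** A read that does not
  reach an amplicon end yields leading/trailing reference-gap runs; these
  define the covered interval instead of deletion events, and a read only
  enters a target's denominator if its covered interval contains the whole
  window. Alignment identity is likewise computed over the covered region,
  and reads below `min_identity` (default 0.60) are excluded from every
  denominator.

## Read classification

A read is **mutated** for a target iff at least one indel event intersects
the target's window. Substitutions never change status: single-nucleotide
substitutions are the dominant error mode of bridge-amplification
sequencers and of PCR, so they are treated as non-CRISPR throughout — an
assumption, not an inference, and it means true Cas9-induced point edits
(rare without a repair template) are invisible to this pipeline.

For mutated reads the **net coding shift** sums, over in-window indels,
the inserted length for insertions anchored strictly inside a coding
interval and minus the deleted overlap with coding intervals for
deletions. The category is

* `frameshift` if the net shift is not a multiple of 3,
* `inframe` if it is a multiple of 3 and some in-window indel touches
  coding sequence,
* `noncoding` if no in-window indel touches coding sequence.

Per animal and target, `q`, `fs`, `im`, `nm` are the unmodified,
frameshift, in-frame and non-coding fractions **of all covering reads**,
so they conserve: `q + fs + im + nm = 1`. (An alternative reading would
express `im`/`nm` as fractions of mutated reads; the loss-of-function
formula below requires fractions of all alleles, so the conserving
definition is the computable one, and `frameshift_of_mutated = fs/(1-q)`
is reported separately.) Targets with fewer than `min_reads` (default 100)
covering reads are marked insufficient rather than estimated.

A deletion spanning two targets' windows on one amplicon counts as mutated
for both targets — proximal sgRNA pairs really do excise the intervening
segment, and each target's fraction table must reflect its own locus.

## The biallelic loss-of-function model

Read fractions are taken as allele fractions in the animal (the embryo's
allele pool is treated as well mixed and PCR as unbiased). For sgRNA `r`,
`q_r` is then the probability that one allele is wildtype at that locus;
for a pool of `R` sgRNAs on the same gene, independence across loci on an
allele gives

$$P(M) = \Bigl(1 - \prod_{r=1}^{R} q_r\Bigr)^{\!2},\qquad
  P(F) = \Bigl(1 - \prod_{r=1}^{R} (q_r + im_r + nm_r)\Bigr)^{\!2},$$

the squares accounting for the two alleles of a diploid cell. With `R = 1`
these reduce to `(1-q)^2` and `(1-(q+im+nm))^2`. `P(F)` treats only
frameshifts as loss-of-function; it is conservative in that a large
in-frame deletion removing a functional domain still counts as
non-disrupting.

Cohort summaries are **per-animal-then-median**: the model is evaluated on
each animal's fractions and the median taken across animals (midpoint
convention for even cohorts). The order matters — the median of
`(1-q)^2` over animals is not `(1-median q)^2` — and published per-sgRNA
median pairs are only mutually consistent under the per-animal-first
order, which is why the package fixes it. Percentages are reported at one
decimal; full precision is kept internally.

## Indel spectra

For each target, the per-animal spectrum maps each signed indel size
(negative deletions, positive insertions) to the fraction of that animal's
mutated reads carrying at least one in-window event of that size; a read
with several distinct indels contributes to each size, so fractions can
sum above 1. The cohort profile averages these fractions over animals that
have at least one mutated read for the target (a fraction of zero reads is
undefined, so such animals are excluded from that target's mean). The
deletion/insertion split is event-level over all in-window events. Top
indels break frequency ties toward smaller absolute size, deletions before
insertions — a deterministic, biologically neutral rule.

## The synthetic cohort generator

The generator emulates the features of real mosaic cohorts that the
pipeline must survive, with exact ground truth:

* **Mosaicism** as a small founder-allele pool (default `K = 4` alleles
  per animal, `Dirichlet(1,...,1)` frequencies): editing during the first
  cleavages creates few distinct alleles but at very uneven frequencies,
  which reproduces the broad 0–100% per-animal spread of mutagenesis
  rates.
* **Editing rates** per animal and target drawn from `Beta(5, 2)` by
  default (mean 0.71, wide spread) or fixed.
* **Deletion bias**: an edit is a deletion with probability 0.8 (~4:1
  deletion:insertion, as observed in Cas9 repair outcomes), with truncated
  geometric sizes on 1–30 bp; insertions are geometric with mode 1 bp and
  uniform random bases.
* **A recurrent MMEJ-like deletion** per target: one privileged deletion
  size (default 3 bp) whose per-animal weight among deletions is
  `0.8 × Beta(1, 2)` — highly variable across animals (spanning ~0–0.8),
  mimicking microhomology-driven locus-specific outcomes.
* **Sequencing errors** as i.i.d. per-base substitutions (default 0.002),
  never indels, matching the dominant Illumina/PCR error mode.

Exact truth fractions are computed by classifying each founder allele's
events with the same window/coding rules applied to reads, and exact
`P(M)`/`P(F)` by the closed form on those fractions. What the generator
does **not** emulate: PCR duplicates and chimeras, quality-score
structure, indel sequencing errors, alignment-confounding repeats, and
joint large deletions between proximal sgRNA pairs (events are kept
disjoint). Passing recovery tests therefore demonstrates correctness of
the analysis under the stated generative model, not robustness to every
artefact of real libraries.

## Numerical and degenerate-input choices

* Fractions are validated into `[0, 1]` with tolerance 1e-9; `q+im+nm`
  above `1 + 1e-9` is a domain error.
* Zero covering reads yield an insufficient-coverage marker, never a
  division by zero; a pooled estimate is unavailable for an animal if any
  panel target is insufficient.
* `frameshift_of_mutated` is `NA` when the mutation rate is 0.
* Deterministic tie-breaks everywhere (left-aligned indels, top-indel
  rule, stable ordering), so identical inputs give byte-identical outputs;
  the simulator is fully determined by `(config, seed)`.
* Simulated edits that would overlap an existing event on the same allele
  are skipped (kept disjoint); with targets placed tens of bases apart
  this is rare and keeps allele reconstruction exact.

## Problem sizes used in the test-suite

The package's statistical tests run at sizes chosen to make the sampling
bounds they assert comfortably valid: single-animal recovery at 10,000
reads (±0.02 on `q` is ≈4 binomial standard errors), a 96-animal cohort at
10,000 reads per animal for cohort-median recovery within ±0.05, and a
220-animal, 16-founder cohort for the deletion/insertion split, which
yields over 5,000 distinct founder events so the ±0.02 binomial bound on
the 0.8 deletion probability applies to genuinely independent draws
(reads sharing a founder allele share its event and are not independent
evidence about the generator's deletion probability).

## Worked example

```{r example}
# three sgRNAs with mutagenesis rates 50%, 60%, 80%
p_mut(c(0.5, 0.4, 0.2))

# a single sgRNA with median mutagenesis 79.6%
round(100 * p_mut(1 - 0.796), 1)

quant <- tibble::tibble(
  animal_id = "larva_01",
  target_id = c("sg1", "sg2", "sg3"),
  q  = c(0.31, 0.07, 0.20),
  fs = c(0.40, 0.50, 0.55),
  im = c(0.25, 0.38, 0.20),
  nm = c(0.04, 0.05, 0.05)
)
est <- estimate_lof(quant)
tidy(est)
glance(est)
```

## Known limitations

* Read fractions equal allele fractions only under unbiased PCR and
  uniform tissue sampling; no duplicate correction is attempted.
* Pooled `P(M)`/`P(F)` assume independence of editing across loci on the
  same allele; physically linked outcomes (one deletion spanning two
  target sites) violate this mildly in the pooled direction.
* Paired-end merging is out of scope; inputs are amplicon-spanning single
  (or pre-merged) reads.
* Non-NGG nucleases and HDR/base-editing outcomes are out of scope.
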