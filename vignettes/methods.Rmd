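---
title: "Methods: mapping a recessive embryonic-lethal deletion and estimating its fertility cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a recessive embryonic-lethal deletion and estimating its fertility cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethalscan)
```

# The problem

A fully recessive lethal allele at carrier frequency $c$ produces homozygous
conceptuses in a fraction $c^2/4$ of random matings (both parents carriers,
both transmit), yet if those conceptuses die before term the defect
manifests only as a depressed non-return rate in carrier × carrier
inseminations, not as affected births. Three signals identify such an
allele: affected survivors share one autozygous haplotype; the causal lesion
(here, a multi-kb deletion) is visible in sequencing data; and insemination
records show a mating-class-specific excess of pregnancy failure. This
package implements each link of that chain, plus seeded simulators for every
input, so the full inference is testable without any proprietary data.

# Autozygosity mapping

## Model and statistic

All affected individuals are assumed homozygous for a single ancestral
haplotype across the causal locus (genetic homogeneity, full penetrance).
`shared_segment_at()` finds the maximal marker interval on which every case
is homozygous, non-missing, and identical — for biallelic dosages that is
simply "all 0 or all 2" per marker — and `genomewide_scan()` evaluates each
such segment with the point statistic

$$p(s) = f^{2n}, \qquad
  f = \frac{\mathrm{matches} + 1}{2N_{\mathrm{controls}} + 2},$$

the probability that $2n$ random chromosomes all carry the segment's
haplotype, with $f$ estimated from a *phased* control pool under an add-one
pseudocount. Controls must be supplied phased (the simulator emits truth
phase); embedding a phasing algorithm is out of scope, and unphased controls
are rejected rather than guessed at.

Genome-wide calibration is Monte-Carlo: each null replicate draws $2n$
chromosomes with replacement from the control pool, assembles $n$
pseudo-cases, reruns the identical scan, and records the genome-wide minimum
$p(s)$. The reported probability is the add-one estimator
$P_{gw} = (1 + \#\{\min_{\mathrm{null}} \le p_{\mathrm{obs}}\})/(R + 1)$,
which is bounded below by $1/(R+1)$ — with the default $R = 1000$ the
smallest reportable value is $\approx 0.001$. We report this Monte-Carlo
estimate only; no parametric bound is attempted.

Two properties of this design are worth stating plainly. First, because
null chromosomes are drawn *from* the pool, every null segment matches at
least its own source haplotype, so a case haplotype absent from the pool
always beats the null and attains the floor — that is the intended behaviour
for a rare defect-carrying haplotype. Second, the null ignores relatedness
among the real cases; with closely related cases the scan is
anti-conservative. We document this rather than correct it, since the
statistic is used to localise, not to publish a calibrated p-value.

## Parameters

* `min_markers = 20`, `max_het = 0` (`detect_roh()`): a 50K-style array
  places ~1 marker per 50 kb, so 20 markers ≈ 1 Mb, well above typical
  background homozygosity runs; heterozygous calls break case runs because
  autozygosity at the causal locus admits none. Missing genotypes also break
  runs (conservative: autozygosity is only declared where observed).
* `pseudocount = 1`: keeps $f > 0$ when the case haplotype is absent from
  the pool and makes $p(s)$ monotone in the match count.
* `n_reps = 1000`: resolves $P_{gw}$ to $10^{-3}$ in a few seconds at the
  default problem size.

# Deletion calling

`fit_insert_model()` estimates the concordant mapped-distance distribution
from the central quantiles (default: trim 5% per tail), so a minority of
deletion-spanning pairs does not inflate the model, and sets the discordance
threshold at mean + 4 sd. No threshold is stated by eye-on-IGV practice;
4 sd keeps the per-pair false-discordance rate negligible at any realistic
library size while sitting far below the distance shift caused by a multi-kb
deletion. Only forward–reverse pairs enter clustering; inversions and
translocations are out of scope.

Each discordant pair brackets the deleted segment between its left read's
end and its right read's start; single-linkage clustering (slack
`max_gap = 1000` bp) groups compatible pairs, and the cluster's size
estimate is mean(distance) − insert mean. The bracket is accurate to within
one read length: a read that itself crosses the junction is left-anchored by
the simulator (as an aligner would soft-clip it), so its end can overshoot
the breakpoint by up to `read_length`.

`detect_dropout()` finds maximal zero-depth runs of at least `window` bp
flanked by `window` bp of depth ≥ `min_flank_depth` on both sides. The
`window` floor separates genuine dropouts from the Poisson gaps of sparse
libraries: at 1.7× coverage, read starts arrive at ~0.022/bp, so a ≥ 500 bp
spontaneous gap has probability $e^{-11}$ per position and a 3.3 kb deletion
is still unambiguous. The heterozygous mode bands the *smoothed* depth
(running mean, width ≥ 51 bp) at 0.5 ± 0.2 of the flanking level —
deliberately simple, since the primary use case is homozygous dropouts.

`merge_evidence()` promotes a call to tier 1 when a cluster and a dropout
overlap reciprocally by ≥ 0.5, taking boundaries from the dropout (per-base
evidence). `refine_breakpoints()` then split-aligns junction reads by
exact-match seed-and-extend (seed 20 bp): the longest reference-matching
prefix anchors the left breakpoint, the longest matching suffix the right;
when the two alignments overlap inside the read, that overlap is the
breakpoint microhomology, the junction placement is ambiguous by exactly
that many bases (we left-align), and the deletion *size* is invariant. A
gapped aligner is unnecessary because junction reads are simulator-clean;
that is also the stated limitation — no sequencing-error model exists, so
refinement exactness on real data would degrade with error rate.

# Consequence prediction

`apply_deletion()` removes exons fully inside the deletion and rejects
partial-exon overlaps ("unsupported case") rather than guessing truncated
splice behaviour; the motivating event deletes whole exons. Strand is
handled by projecting to transcript coordinates before any arithmetic.
`protein_effect()` translates wild-type and mutant CDS (via
`Biostrings::translate`) and reports: frameshift iff the deleted coding
length is not a multiple of 3 (asserted in tests against an independent
hand-rolled codon-table oracle), the first divergent codon, the novel
peptide up to the first shifted-frame stop, and the count of lost wild-type
residues. `predict_nmd()` applies the 50-nt rule — decay is predicted when
the termination codon lies at least 50 nt upstream of the final exon–exon
junction — with an *inclusive* boundary (a PTC exactly 50 nt upstream
triggers decay; 55 nt is available via `boundary_nt`). `predict_amplicons()`
is exact-match PCR: one occurrence per primer per strand (multiple matches
are an ambiguity error), product size measured 5′-end to 5′-end inclusive,
and a `max_amplicon = 5000` bp reach on genomic DNA. These rules make the
diagnostic identities testable: a junction-spanning product appears only on
the deleted allele with size reference-span − deletion-size, internal
primers amplify only the intact allele, and the cDNA product shrinks by
exactly the summed deleted exon lengths.

# Population genetics

`carrier_frequency()` is $\hat c = n_{D/+}/N$ with a Wilson score interval
(via `prop.test`; Wilson is accurate for small proportions where Wald is
not). `allele_freq_from_carrier()` solves $2q(1-q) = c$ for the smaller
root. `expected_incidence()` deliberately uses the carrier-pairing
approximation $c^2/4$ rather than $q^2$, because that is the form in which
the field quotes "1 affected per N births"; the exact $q^2$ (≈ 8% larger at
$c = 0.074$) is returned alongside. `prob_zero_homozygotes()` is the exact
binomial zero-class probability $(1-q^2)^N$. `survival_adjusted_incidence()`
scales $c^2/4$ by the surviving fraction and rounds the headline reciprocal
to the nearest 100 above 1,000 (the raw reciprocal is also returned).

# Fertility contrast and lethality estimation

Dams are classified by their own sire's genotype, so dam carrier status is
probabilistic: $0.5 + c/2$ for carrier-sired dams (one half from the
grand-sire plus $c/2$ from the ungenotyped grand-dam, ignoring the
negligible double-inheritance overlap), $c/2$ otherwise. With a genotyped
carrier sire, $P_{hom} = P(\text{dam carrier})/4$.

The contrast is **additive** — a difference of failure probabilities, not an
odds ratio — because the identity that makes the estimator a one-liner,
$\text{excess}(t) = P_{hom}\, m(t)$, is additive. The mating simulator
enforces the same arithmetic exactly: failure by day $t$ is generated from a
single uniform $u$ as $u < b(t) + \mathbf{1}[D/D]\, m(t)$, i.e. the baseline
and lethality events are *disjoint* slices of $[0,1]$ (validated
$b + m \le 1$), so risks add exactly, baseline cancels in every contrast,
and each record's failure indicators are monotone over the 56/90/270-day
grid. Had the two causes been drawn independently, the excess would shrink
to $(1-b)P_{hom}m$ and the moment estimator would be biased downward by the
baseline level — incompatible with the additive bookkeeping the analysis
rests on.

`estimate_mortality()` inverts the identity, clips to $[0,1]$, and attaches
two 95% intervals: delta-method (binomial variance of the risk difference
scaled by $1/P_{hom}$) and a nonparametric bootstrap over matings (default
200 resamples). Per-class/stage 2×2 tests use `chisq.test` without
continuity correction, switching to Fisher's exact test when any expected
cell is below 5; raw p-values are reported with no multiplicity correction
across the 3 stages × 3 classes. `recover_parameters()` closes the loop:
simulate → estimate over seeded replicates, reporting bias, RMSE and
delta-interval coverage.

Two effects observed in real insemination data are deliberately **not**
modeled: excess failure in carrier-dam × non-carrier-sire matings (the
recessive-lethal model cannot produce it; under the model that class's
excess converges to 0, so a non-zero value is a model-misfit diagnostic,
never a fitted effect) and cows culled without reported calving
("removers"), an unquantified ascertainment bias we document rather than
invent a correction for.

# The synthetic-data generators

What they emulate — and the defaults that define the study conditions:

* **Genotypes**: a 50K-style map (default 1,200 markers on a 60 Mb
  chromosome), 6 cases homozygous for one planted haplotype across a
  2.46 Mb interval, controls as two independent phased haplotypes. A control
  haplotype is the carrier haplotype with probability $q$, the smaller root
  of $2q(1-q) = c$, so the expected heterozygous-carrier fraction is exactly
  $c$ and carriers of ≥ 1 copy occur at $c + q^2$; homozygous-carrier
  controls are *not* suppressed (homozygote-deficit tests need the
  unconstrained model). Other allele frequencies are Uniform(0.05, 0.95) —
  a flat stand-in for an ascertained SNP-array spectrum.
* **Mate pairs**: inserts Uniform(4000, 4500) bp (a normal option exists for
  sensitivity tests), 2×76 bp reads, pair count exactly
  `round(coverage · L / (2 · read_length))`, fragments uniform on the allele
  sequence, D/+ mixing haplotypes 1:1. The reference is a seeded random
  nucleotide string: no repeats, no base-quality or error model, no FASTQ.
  Consequently split-read refinement sees clean reads, and repeat-driven
  false discordance does not occur — passing tests bound the method's
  correctness, not its robustness to real-library artefacts.
* **Matings**: four classes of equal size (default $10^5$ per class in the
  pipeline, $10^6$ in the acceptance reproduction), baseline cumulative
  failure 0.35/0.40/0.45 at 56/90/270 d — plausible dairy non-return
  complements, configurable, and cancelling in every contrast — and
  homozygote cumulative mortality 0.30/0.40/0.52, chosen so that more than
  half of the 270-day mortality has occurred by day 56 and the terminal
  value matches the ~52% the fertility contrast is expected to recover.

Every generator takes one integer seed; identical config + seed gives
byte-identical output (the pipeline derives per-stage child seeds from one
root seed so stages are independently rerunnable).

# Numerical choices and degenerate inputs

* Coordinates: 0-based half-open internally (exons, deletions, BED, depth);
  1-based on VCF output and marker maps. The planted genotype interval is
  1-based inclusive, so its BED width is `end − start + 1`.
* Ties and floors: $P_{gw}$ uses add-one counting on both sides (never 0);
  breakpoint refinement takes the majority vote across junction reads and
  left-aligns within microhomology.
* Degenerate inputs are errors, not guesses: all-zero depth tracks ("no
  flanking coverage"), unphased controls, deletions splitting exons,
  carrier frequency > 0.5 in the Hardy-Weinberg back-calculation, an empty
  reference mating class, $P_{hom} = 0$ (uninformative class).
* Estimator clipping: $\hat m(t)$ and its interval ends are clipped to
  $[0,1]$; an isotonic (cumulative-maximum) option exists but is off by
  default so the raw moment estimates remain visibly noisy when they are.

# Problem sizes

The shipped test suite and acceptance reproduction use: 1,200-marker scans
with 100 controls and 1,000 Monte-Carlo replicates; 150 kb mate-pair windows
at 15–30× (plus one 1.7× sparse-coverage case); $10^6$ matings per class for
the headline excess and 200 × $10^5$-per-class replicates for estimator
calibration. These sizes keep every statistic's Monte-Carlo error an order
of magnitude below the tolerances being asserted while the whole suite runs
in minutes on one core.

# Known limitations

Relatedness among cases (anti-conservative scan), no phasing/imputation, no
read-error or repeat model (refinement exactness is an upper bound on real
performance), heterozygous dropout detection is band-based and simple,
"removers" and the carrier-dam excess are surfaced but unmodeled, and the
dataset-specific discordant-pair support count of a real 1.7× library is
checked only as an order-of-magnitude property of physical coverage.
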