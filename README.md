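# lethalscan

Recessive embryonic-lethal mutations hide in plain sight in livestock
populations: the causal allele can reach a carrier frequency of several
percent while almost no affected animals are ever born, because homozygous
conceptuses die in utero and the loss is booked as "infertility" rather than
as a genetic defect. `lethalscan` implements, as a tested and reusable R
pipeline, the complete inference chain by which such a defect — a multi-kb
deletion causing fetal death and a congenital syndrome in Holstein dairy
cattle — can be mapped and its fertility cost quantified:

1. **Autozygosity mapping.** Affected animals from a recessive defect share
   one ancestral haplotype homozygous across the causal locus. For `n` cases
   sharing a segment whose haplotype has population frequency `f` (estimated
   from a phased control pool with an add-one pseudocount), the chance-sharing
   point probability is `p(s) = f^(2n)`; genome-wide significance is
   calibrated by a Monte-Carlo null that redraws `2n` chromosomes from the
   control pool and records each replicate's minimum `p(s)`, giving
   `P_gw = (1 + #{null min <= observed}) / (n_reps + 1)`.
2. **Deletion calling.** In a long-insert mate-pair library (4–4.5 kb
   fragments, 2×76 bp reads), a deletion inflates the reference-mapped
   distance of spanning pairs by its own length and abolishes coverage inside
   the lost segment. Discordant pairs (distance > trimmed mean + 4 sd) are
   clustered, coverage dropouts detected, the two evidence types merged at
   reciprocal overlap ≥ 0.5, and exact breakpoints recovered by split-aligning
   junction-bridging reads (with breakpoint microhomology reported).
3. **Consequence prediction.** Deleting whole exons juxtaposes their
   neighbours in the mRNA; if the lost coding length is not a multiple of 3
   the downstream frame shifts, creating a short illegitimate peptide and a
   premature termination codon that triggers nonsense-mediated decay when it
   lies ≥ 50 nt upstream of the final exon–exon junction. Validation PCR
   amplicons (junction-spanning, internal, and cDNA) are predicted per allele.
4. **Population genetics.** Carrier frequency `c` with a Wilson interval;
   Hardy-Weinberg back-calculation `2q(1−q) = c`; expected incidence
   `c²/4` ("1 in N births"); the homozygote-deficit probability
   `(1 − q²)^N` of seeing no homozygotes among `N` genotyped animals.
5. **Fertility contrast and lethality.** Inseminations are classed by sire
   genotype and the dam's sire's genotype. A carrier-sired dam carries the
   allele with probability `0.5 + c/2`, a non-carrier-sired dam with `c/2`;
   with a carrier sire the conceptus is homozygous with probability
   `P_hom = P(dam carrier)/4`. Under the additive risk model the excess
   pregnancy-failure rate of carrier×carrier matings over the non-carrier
   reference at gestation day `t` equals `P_hom · m(t)`, so the cumulative
   in-utero mortality of homozygotes is estimated as
   `m̂(t) = excess(t) / P_hom`, with delta-method and bootstrap intervals.

No real genotype, sequence or insemination data ship with the package;
a first-class synthetic-data module generates every input with the
statistical structure the analysis assumes, and the whole pipeline runs end
to end from a single seed.

## Worked example

```r
library(lethalscan)

## map a planted 2.46 Mb autozygous haplotype in 6 cases vs 100 controls
map  <- marker_map("21", 1200, 6e7, seed = 2)
sim  <- simulate_genotypes(map, 6, 100, carrier_freq = 0,
          interval = list(chrom = "21", start = 20132767, end = 22592766),
          seed = 7)
genomewide_scan(sim, sim$case_ids, n_reps = 1000, seed = 9)
#> Autozygosity scan over 1200 markers; 1000 null replicates
#> Best segment: 21:20,202,342-22,539,039 (48 markers), p = 2.17e-28, P_gw = 0.000999

## call a 3,329 bp deletion from a 30x mate-pair library and refine it
mp    <- simulate_matepairs(150000, deletion = c(80000, 83329),
                            genotype = "D/D", coverage = 30, seed = 3)
calls <- merge_evidence(cluster_discordant(mp$pairs, fit_insert_model(mp$pairs)),
                        detect_dropout(mp$depth, 500, 1))
refine_breakpoints(calls[1, ], mp$junction_reads, mp$reference)
#>   start   end size n_discordant_pairs     evidence microhomology
#> 1 79999 83328 3329                841 pair+dropout             3

## estimate homozygote in-utero mortality from 4 x 1e6 simulated matings
recs <- simulate_matings(1e6, carrier_freq = 0.074, seed = 11)
estimate_mortality(recs, 0.074, n_boot = 0)
#> Cumulative homozygote in-utero mortality (class CdamxCsire, P_hom = 0.1342)
#>   day  56: m_hat = 0.310 (excess 0.0416; 95% delta CI 0.300-0.320)
#>   day  90: m_hat = 0.412 (excess 0.0553; 95% delta CI 0.402-0.422)
#>   day 270: m_hat = 0.530 (excess 0.0712; 95% delta CI 0.520-0.541)

expected_incidence(0.074)$reciprocal   # expected 1 affected birth per 730
#> [1] 730
```

The scan pins the shared segment onto the planted interval with the smallest
genome-wide probability the 1,000-replicate null can resolve; the deletion
call recovers the planted size exactly (breakpoint placement is ambiguous by
the 3 bp of junction microhomology, left-aligned); and the mating contrast
recovers the ~52% cumulative mortality (m̂(270) = 0.53) that reconciles a
7.4% carrier frequency with a near-absence of affected births.

A one-command version of the whole chain, with a JSON run manifest and a
plain-text report:

```r
run_pipeline(list(seed = 42, out_dir = "run1"))
writeLines(make_report("run1"))
```

or from a shell via the thin wrapper `inst/exec/lethalscan`
(`lethalscan run --config cfg.yaml`, `lethalscan report --dir run1`,
`lethalscan popgen --counts 2813,225,0`).

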