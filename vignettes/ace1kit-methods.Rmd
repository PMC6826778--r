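---
title: "Methods and design notes for ace1kit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for ace1kit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ace1kit)
```

`ace1kit` packages the desk analyses of a target-site insecticide
resistance study at the mosquito *Ace-1* locus: bioassay and association
statistics, sequence polymorphism and neutrality tests, haplotype networks
and distance trees, and duplication calling from cloned haplotypes. This
vignette records the models behind each stage, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Coordinates and the diagnostic site

All coordinates are **1-based and inclusive**. The resistance-diagnostic
site is the G→A substitution at the first position of codon 119
(glycine→serine). Published coordinates for such sites may index either
the raw amplicon or a trimmed alignment, so the diagnostic column is a
required configuration value (`codon_column`) and is never hard-coded.
Classification reads the single diagnostic column — `G` susceptible, `A`
resistant, `R` heterozygous, anything else undetermined — matching how
direct Sanger traces are scored; full codon translation
(`translate_frame()`) is provided only as a coordinate cross-check.

## Association statistics

Tables are oriented so that OR > 1 means the resistance category is
enriched among survivors. The allelic comparison counts two alleles per
individual (`2·SS + GS` resistant vs `2·GG + GS` susceptible); the
genotypic comparison contrasts homozygotes only.

* **Zero cells.** The default policy adds 0.5 to every cell (Haldane)
  before the OR and the Woolf logit CI; `haldane_if_zero` and `none` are
  available. Applying the correction to *all* cells, not just zero ones,
  is the convention that reproduces the worked values in the README.
* **Fisher exact test** is two-tailed by the standard "sum of all tables
  no more probable than the observed" rule (delegated to
  `stats::fisher.test`; the test suite checks it against a direct
  hypergeometric enumeration).
* **Hardy–Weinberg** uses the exact conditional test (enumeration of
  heterozygote counts given allele counts, two-sided by the same
  probability rule), computed with log-factorials; a chi-square variant is
  optional. At a duplicated, dosage-genotyped locus a strong heterozygote
  deficit is expected and this test is the instrument that shows it.
* **WHO bioassay thresholds** are encoded as mortality ≥ 98% susceptible,
  90–<98% suspected resistance, < 90% resistant (the WHO 2016 test
  procedures), with SEM taken across replicate tubes.
* **Percentages to counts.** Published tables often give only percentages
  of a known group size. `counts_from_percentages()` rounds each class to
  the nearest integer and reconciles any off-by-one on the largest class,
  which recovers the intended integer counts whenever the source rounded
  to ≤ 1 decimal.

## Polymorphism and neutrality statistics

Site policy follows the common polymorphism-software default: columns
containing gaps or ambiguity codes are excluded globally for *S*, η,
Tajima's *D*, Fu & Li's *D\** and Fu's *Fs* (complete deletion), and
pairwise for π. Statistics on monomorphic data return a typed `NA` with a
message, never a silent zero.

* **Tajima's D** uses the 1989 constants
  (`a1, a2, b1, b2, c1, c2, e1, e2`) with *S* segregating sites and the
  mean pairwise difference k̄.
* **Fu & Li's D\*** (no outgroup) contrasts total mutations η with
  singletons η_s (minor allele in exactly one sequence; per column at most
  alleles−1 singletons), using the corrected variance constants adopted by
  standard polymorphism software.
* **Fu's Fs** computes `S′ = P(K ≥ k_obs | θ̂_π)` under the Ewens sampling
  formula with unsigned Stirling numbers of the first kind, evaluated in
  log space (stable to n ≈ 60 and beyond), and `Fs = ln(S′/(1−S′))`.
  Boundary cases (single haplotype, S′ hitting 0/1) are `NA`.
* **Significance** comes from a neutral coalescent null conditioned on the
  observed number of segregating sites (`fixed_S`): genealogies are drawn,
  exactly *S* mutations placed multinomially by branch length, and the
  statistic's empirical distribution built. *D* and *D\** get two-sided
  empirical p-values, *Fs* a lower-tail one. One caveat worth knowing:
  conditioning on *S* shifts the mean of *D* slightly negative (about
  −0.1 at n = 24, S = 29, against a null SD near 0.9); the test suite
  allows for this offset when checking that the null is centred.

### Heterozygous direct sequences

A diploid amplicon sequenced directly yields one consensus with IUPAC
codes at heterozygous sites — not a haplotype. Two policies are offered:
`exclude` (drop such sequences from haplotype-based statistics; the
package-level default) and `expand` (replace each with two naive
pseudo-phases, first/second base of every code, labelled `.a`/`.b`). The
pipeline defaults to `expand` so that a diploid panel is summarised on the
2n chromosome scale — the scale on which such panels are conventionally
reported — while making no claim that the pseudo-phases are real phased
haplotypes; phases still containing three-fold codes are dropped. The run
log records the policy in force.

## Statistical-parsimony network

Haplotypes are joined pairwise in non-decreasing Hamming-distance order
(ties broken lexicographically by label); a *d*-step join inserts *d*−1
latent intermediate nodes, resolving the differing sites in ascending
column order — an arbitrary but deterministic placement. Joins whose
components were already connected within the same distance class are
recorded as `ambiguous_alternatives` rather than drawn, so every component
stays a tree; joins beyond the connection limit are refused, possibly
leaving several components.

The **connection limit** is the largest number of steps *j* for which the
probability that *j* observed differences arose without superimposed
change is at least the confidence level (0.95 by default). The package
computes this probability from the pair coalescent with Jukes–Cantor
substitution: per site the mutation count is geometric with parameter *p*,
giving a per-site difference probability `3p/(3+p)`; matching that to the
observed divergence `q = j/L` gives `p = 3q/(3−q)`, the single-mutation
probability for a differing site is `(1−p)(3+p)/3`, and the parsimony
probability for *j* differences is that quantity to the *j*-th power. The
result is deterministic in `(L, confidence)` and non-decreasing in *L*
(705 bp → 7 steps at 95%). This formulation is more conservative than the
original TCS program's published tables; `limit` can be overridden
directly where a different convention is wanted.

**Cluster purity** of a network against the resistance labelling is the
best two-block classification accuracy over candidate bipartitions: every
single-edge cut of a component (evaluated in both orientations, since
other components fall to the complement side) and every whole component
against the rest. Latent nodes carry no label and are ignored. The
analogous tree score takes the best edge-induced leaf bipartition.

## Distances and trees

The Tamura 3-parameter distance uses transition proportion *P*,
transversion proportion *Q* and `c = 2θ(1−θ)` with θ the **per-pair** mean
G+C content (the model statement leaves pooled-vs-pair open; per-pair is
the choice here, and with θ = 0.5 the distance reduces exactly to Kimura's
two-parameter formula). Sites with gaps or ambiguity codes are deleted
pairwise. Saturated pairs raise an error naming the pair rather than
returning infinity. Trees are standard Saitou–Nei neighbor joining
(`ape::nj`); negative branch lengths are clamped to zero with the deficit
moved to the sibling branch. A full maximum-likelihood search is out of
scope at desk scale — cluster recovery, not topology identity, is the
criterion the NJ stand-in is held to.

## Duplication calling

Clones are haploid by construction, so ambiguity codes in a clone are
rejected. `collapse_clones()` merges identical clones and absorbs a
haplotype seen in fewer than `min_support` clones into a better-supported
haplotype within `max_err_dist` substitutions; sweeps repeat until stable,
making the operation idempotent. Two documented settings:

* `min_support = 1, max_err_dist = 0` — the literal reading: every
  distinct clone is an allele (default);
* `min_support = 2, max_err_dist = 1` — error-aware: single-substitution
  singletons are treated as PCR/cloning artefacts.

An individual is called **duplicated** when more than two distinct
haplotypes remain — a diploid single-copy locus cannot carry three. A
single-haplotype individual is *not* evidence either way. The predicted
dosage genotype uses a dominance threshold of 0.75 on the resistant-copy
fraction, chosen so that the 3R+1S make-up of a typical duplicated
individual reads as homozygote resistant; it is configurable.

Under the error-aware setting the caller is highly specific but not
sensitive for swept duplications: resistant copies drawn from a
low-diversity pool are often within one substitution of each other and
merge with the artefact filter. The acceptance script reports both
operating characteristics rather than hiding the trade-off.

## The synthetic-data generator

`sim_config()` encodes the study conditions: a 705 bp locus with the
diagnostic site at column 397; a susceptible pool sampled from the neutral
coalescent at θ_S = 5; a resistant pool at θ_R = 0.5 descending from a
single susceptible **founder** haplotype that acquired G→A. Emulating the
sweep through a founder (rather than around the shared ancestral
background) gives the geometry a swept target-site allele actually
produces — the resistant cluster hangs off one point of the susceptible
diversity, with the founder one step away, occasionally appearing nested
beside the resistant cluster. Individuals carry 2 copies, or 4 with
probability `dup_fraction` (default 0.25; copy make-up 3R+1S, the
composition that explains dosage-typed heterozygote deficits);
non-duplicated copies are resistant with probability `p_resistant_copy`
(default 0.4, mirroring a ~40% field allele frequency). Genotype calls
are dosage predictions; exposed individuals survive with per-genotype
probabilities (default RR 0.95, GS 0.70, GG 0.05); five clones per cloned
individual receive `Poisson(pcr_error_rate)` substitutions each (default
10⁻³ per clone — high-fidelity amplification). Mutations are placed under
infinite sites on the finite column grid (distinct columns per pool;
collisions between pools are possible and harmless at these rates). There
is no recombination and no migration.

What the generator does **not** emulate: codon structure of the background
(mutations land on random columns, so synonymous/nonsynonymous proportions
are not those of a real coding region), sequencing/chromatogram noise in
direct reads, base-composition bias, TaqMan fluorescence behaviour, and
3-vs-4+ copy resolution (clone sampling cannot distinguish these and the
caller does not try). Tests passing on synthetic studies therefore
validate the statistical machinery and its wiring, not instrument-level
artefacts of real data.

Problem sizes used by the test suite and acceptance script — pools of 16
haplotypes per class, 50 sweep replicates, 1000-replicate neutrality
nulls, 200-replicate estimator-recovery runs, five 40-individual
duplication studies — are the package's chosen defaults for routine
validation; all are seeded and deterministic.

## Known limitations

* Pseudo-phase expansion is not statistical phasing; haplotype *networks*
  built from expanded diploid consensus data can contain chimeric
  haplotypes. Clone-level data avoid this entirely.
* The connection-limit formulation is deliberately simple and
  conservative; comparisons with networks from other software should be
  made at the cluster level, not edge by edge.
* Fisher's exact test requires integer (uncorrected) tables; corrected
  tables carry their p-value from the uncorrected counts.
* The coalescent machinery is for desk-scale validation (n up to ~100),
  not a general-purpose simulator.
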