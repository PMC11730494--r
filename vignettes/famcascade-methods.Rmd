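---
title: "Models and methods behind famcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind famcascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famcascade)
```

famcascade implements the computational core of a classical single-family
rare-disease gene hunt: a handful of exome-sequenced relatives, a dominant
(or recessive) co-segregation hypothesis, a cascade of variant filters, a
restriction to regions the affected relatives share identically by descent
(IBD), and a parametric linkage LOD score for the surviving candidate. This
vignette explains the models, the tunable parameters, the numerical choices,
and what the synthetic validation does and does not establish.

## The segregation filter and the cascade

Given a multi-sample VCF and a `SegregationPattern` naming affected and
unaffected relatives, a variant is a **dominant candidate** when every
affected individual is heterozygous and every unaffected one is
homozygous-reference, and a **recessive candidate** when every affected
individual is homozygous-alternate while unaffecteds are at most carriers.
A missing genotype in any pattern individual disqualifies the variant from
both sets: "shared" is read conservatively, so an uncalled site can never
manufacture a candidate. `runCascade()` then applies, in order:

1. **FILTER and consequence** — `PASS` records with a protein-altering
   consequence (missense, frameshift, nonsense, splice; controlled
   vocabulary normalised at ingestion).
2. **Rarity** — gnomAD maximum allele frequency and in-cohort allele
   frequency both at or below their thresholds (defaults 0.001 and 0.02).
   The two frequency rules form a single ledger step because they act
   together as the "rare" criterion. A variant absent from gnomAD is
   treated as frequency 0: novel variants are exactly the ones such a study
   must keep. A site with no called genotypes has an undefined cohort
   frequency and fails the step rather than raising, so batch runs never
   abort on one bad record.
3. **Deleteriousness** — CADD phred at or above the minimum (default 15);
   a missing score fails.
4. **IBD overlap** — the variant must lie in the regions shared IBD by the
   affected individuals; by default with *gene-span* semantics (the
   variant's gene interval must intersect a shared region), because
   candidate genes, not positions, are the unit of downstream
   interpretation. Position semantics are available via
   `CascadeConfig(ibdMode = "position")`.

All thresholds are inclusive. The `FilterLedger` records survivor counts
(with the het/hom split) and the survivor sets at every step; monotonicity
of the counts is enforced by the class validity, and the cascade is
idempotent on its own survivors.

`rankSurvivors()` orders the surviving genes by seed-gene membership, then
maximum CADD, then name. It is a deliberately transparent, deterministic
stand-in for network-based gene prioritisers, which are outside this
package's scope.

## IBD shared regions

`sharedRegions()` consumes pairwise IBD segments (Beagle-style `.ibd`
files) and intersects them across every unordered pair of the required
samples — the strictest, pairwise-complete reading of "shared by the
affected individuals". A `minPairs` relaxation is exposed because with more
than two samples the literature is ambiguous about whether all pairs must
support a region. Interval arithmetic is delegated to
GenomicRanges/IRanges; coordinates are 1-based inclusive at every interface
and converted only at the BED boundary (0-based half-open on disk). The
implementation is validated against a per-base membership oracle on
randomised instances with coordinates up to 10^4.

`naiveIbdScan()` is a lightweight exclusion-based scan (maximal marker runs
with at most *k* opposite homozygotes) so synthetic tests need no external
IBD caller. It is emphatically not a model-based IBD detector: no linkage
disequilibrium, no haplotype frequencies, no phasing. Window and tolerance
defaults (50 markers, 1 opposite homozygote) suit dense marker maps of
roughly 100 markers/Mb; the validation simulations use window 300 and
tolerance 2 at that density, chosen from the opposite-homozygote rate
(about 0.07 per marker for unrelated individuals at allele frequency 0.25),
which makes a false 300-marker run astronomically unlikely while a true
10 Mb tract is always long enough.

## The linkage model

`pedigreeLoglik()` evaluates the exact joint likelihood of phenotypes and
one marker under a two-locus (disease, marker) model. Each individual's
latent state is an ordered pair of haplotypes; a haplotype carries a
disease allele and a marker allele (4 haplotypes, 16 ordered states).
Founders follow Hardy-Weinberg and linkage equilibrium; each meiosis
transmits a parental haplotype intact with probability $(1-\theta)/2$ per
strand or recombinant with $\theta/2$; an individual contributes penetrance
$f_g$ if affected, $1-f_g$ if unaffected, and 1 if unknown (unknowns inform
through their genotypes only), plus an indicator matching its observed
marker genotype (missing markers contribute 1).

The sum over all joint states is evaluated by **Elston–Stewart peeling**
over the nuclear-family elimination order from `peelingOrder()`: families
are peeled leaf-first, each folding its information onto the single pivot
individual it shares with the remainder. Likelihoods are accumulated in
linear space with per-family rescaling (the running maximum is factored
into a log accumulator), so deep pedigrees cannot underflow. Pedigrees
with marriage or inbreeding loops are rejected outright rather than
approximated by loop-breaking: the target study design is loop-free, and
refusing loops keeps the implementation exactly equivalent to brute-force
enumeration — an equivalence the test suite checks on 200 random pedigrees
to $10^{-9}$ in log-likelihood (enumeration over the $16^n$ joint states is
done densely for pedigrees of up to 6 members; larger pedigrees, up to 8,
are validated through the $\theta = 0.5$ factorisation of the joint
likelihood into single-locus likelihoods, each enumerable over $3^n$
states).

The **LOD score** is $[\ell(\theta) - \ell(0.5)]/\ln 10$, evaluated at
$\theta = 0$ for the single-point test of a candidate variant against the
disease locus; `lodCurve()` evaluates a diagnostic grid but no maximisation
over $\theta$ is performed. Conversion to a p-value uses half the upper
tail of a 1-df chi-square at $2\ln(10)\,\mathrm{LOD}$ — `lodToPvalue()` —
and `tTwoTailed()` provides the two-tailed Student-t tail used for the
package's reporting utilities.

Model parameters, with defaults and rationale:

* **prevalence** $K$ (default 0.01): a moderately rare late-onset trait.
* **penetrances** $(f_0, f_1, f_2)$ (default $(0, 0.9, 0.9)$): autosomal
  dominant with penetrance 0.90 for one or two copies. The phenocopy rate
  $f_0$ defaults to 0; it matters — unaffected individuals are strong
  evidence against carriage only when $f_1$ is high and $f_0$ low — so it
  is an explicit, documented argument rather than a hidden constant.
* **disease-allele frequency**: derived from $K$ by solving
  $f_2 p^2 + 2 f_1 p (1-p) + f_0 (1-p)^2 = K$ (smaller admissible root,
  Hardy-Weinberg founders; `deriveDiseaseAlleleFreq()`), or supplied
  directly. For the default model $p \approx 0.00557$.
* **marker allele frequency** (default 0.001): an ultra-rare candidate
  variant. Single-point LODs for rare dominant variants are insensitive to
  this value over an order of magnitude, but it is user-settable because it
  is part of the likelihood.

## The simulator

`simulateFamily()` is first-class, tested code, not a fixture: it generates
the study conditions every other module is validated under. Founder
haplotypes are drawn at configured frequencies; transmission is Mendelian
gene dropping with recombination on a uniform 1 cM/Mb map (adequate because
only tract lengths and a single-point LOD are consumed downstream);
phenotypes are drawn from the penetrances given the causal genotype. Every
haplotype is stored as a mosaic of founder-haplotype segments, so truth IBD
tracts fall out of the recorded descent exactly, and Mendelian consistency
is testable (and tested) on all outputs. An unrelated cohort (default 300
samples, drawn at the same allele frequencies under Hardy-Weinberg) is
added to the emitted VCF so that the in-cohort frequency filter is
meaningful — a family of 15 alone would push any fully-segregating variant
above the 0.02 threshold.

`studyEmulationPreset()` fixes a 4-generation, 20-member pedigree with 15
genotyped members of whom exactly 6 are affected carriers of one planted
heterozygous missense variant (gnomAD-like frequency 2.6e-5, CADD 25.1)
and 9 are unaffected non-carriers. The causal-locus gene drop is
conditioned on that descent plan (each meiosis is resampled until the
planted allele goes where the plan says) and phenotypes follow carrier
status deterministically: the preset reproduces an *ascertained* family —
the configuration the study observed — not a random draw. Stochastic
penetrance remains the default everywhere else, and the 0.90 calibration
check uses the unconditioned phenotype mechanism on 10,000 carrier draws.
Designed decoy variants ride the causal founder haplotype so each cascade
step has survivors to remove: one non-protein-altering, one gnomAD-common,
one cohort-common, one low-CADD, one non-PASS, and two full-pass variants
with lower CADD than the planted one.

What the synthetic validation shows: the filter logic, the interval
algebra, the likelihood engine and the ledger bookkeeping are correct
under known truth. What it does not show: robustness to genotyping error
beyond the small error rate in the scan simulations, age-dependent
penetrance (the generator has no age-of-onset liability model), population
structure in the cohort, or the behaviour of upstream calling and
annotation — all of which are outside this package's scope.

## Numerical and design choices

* Peeling is exact; the only numerics are the per-family rescaling (no
  tolerance involved) and the quadratic root in
  `deriveDiseaseAlleleFreq()`, which falls back to the linear solution when
  the quadratic coefficient is below 1e-14 and round-trips the prevalence
  to 1e-9 by class validity.
* Survivor order everywhere is (chrom, pos, ref, alt); gene ranking breaks
  CADD ties alphabetically; the peeling order breaks ties by the
  lexicographically smallest parent couple. No output depends on hash or
  insertion order.
* Multi-allelic decomposition counts copies of the record's own alternate
  allele; the other alternate counts as reference for that record, which
  preserves the total number of non-reference observations across the
  decomposed records.
* Genotyping-rate pruning uses a strict inequality ("more than 90%"),
  carrier counting an inclusive one ("at least two").
* APOE epsilon alleles are haplotypes of rs429358 and rs7412; the double
  heterozygote is reported as e2/e4 with an `ambiguous` flag (the e1/e3
  phase is suppressed by convention), but a genotype pair that *forces*
  the rare e1 haplotype returns it honestly.
* The problem sizes in the test suite — dense enumeration to 6 members,
  200 oracle pedigrees, 200 phenotype permutations, 10,000 penetrance
  draws, per-base IBD oracles to 10^4 — were chosen so the whole
  validation runs comfortably on a laptop while keeping every check
  statistically meaningful.

## Known limitations

Only biallelic analyses; no compound-heterozygote or X-linked models; no
multipoint linkage, haplotyping or nonparametric scores; no loop-breaking;
no transcript-aware annotation (the codon arithmetic in
`describeCodingChange()` deliberately needs only the reference codon, not
the transcript). The true pedigree behind the motivating study design is
not reconstructible from published material, so printed family-specific
results are treated as conversion checks, never as simulation targets.
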