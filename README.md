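# famcascade

Variant prioritisation for single-family rare-disease studies: given a
multi-sample VCF from a handful of exome-sequenced relatives, famcascade
finds the variants that co-segregate with disease, pushes them through a
rare-damaging-variant filter cascade, restricts them to the genomic regions
the affected relatives share identically by descent (IBD), and quantifies
the evidence for each surviving candidate with a single-point parametric
linkage LOD score. It is aimed at statistical-genetics practitioners
analysing extended pedigrees — the classic design where one segregating
dominant variant must be pulled out of ~10^3 shared variants — and at
method developers who need a fully synthetic, truth-known test bed for
such pipelines.

## What it computes

**Co-segregation filter.** For affected set $A$ and unaffected set $U$, a
dominant candidate satisfies "het in every member of $A$, hom-ref in every
member of $U$"; a recessive candidate "hom-alt in every $A$, at most
carrier in every $U$". Missing genotypes among the named individuals
disqualify a variant.

**Filter cascade** (inclusive thresholds, each step recorded in a
`FilterLedger`): segregation → PASS + protein-altering consequence →
rarity (gnomAD max AF ≤ 0.001 **and** in-cohort AF ≤ 0.02) → CADD phred
≥ 15 → variant's gene overlaps an IBD region shared by all affected pairs.

**IBD intersection.** Pairwise Beagle-style segments are merged per pair
and intersected across all $\binom{k}{2}$ pairs of the required samples
(with a `minPairs` relaxation), via GenomicRanges.

**Parametric linkage.** The exact two-locus pedigree likelihood
$L(\theta)$ is computed by Elston–Stewart peeling under a penetrance model
$(f_0, f_1, f_2)$ with Hardy–Weinberg founders, and

$$\mathrm{LOD} = \log_{10} \frac{L(\theta = 0)}{L(\theta = 0.5)}, \qquad
p = \tfrac{1}{2}\,P\!\left(\chi^2_1 > 2\ln(10)\,\mathrm{LOD}\right).$$

The disease-allele frequency is derived from the prevalence $K$ by solving
$f_2 p^2 + 2 f_1 p(1-p) + f_0 (1-p)^2 = K$.

**Extras.** Coding-position codon arithmetic (`c.3215C>T` →
`p.Ala1072Val`), APOE ε-genotype calling from rs429358/rs7412, two-tailed
t tails, and a gene-dropping simulator (`simulateFamily()`) that emits
cross-consistent PED/VCF/annotation/IBD/truth files with recombination on
a 1 cM/Mb map.

## Worked example

The study-emulation preset simulates a 4-generation family with 15
genotyped members — 6 affected carriers of one planted heterozygous
missense variant, 9 unaffected non-carriers — plus decoy variants riding
the same founder haplotype and a 300-sample unrelated cohort:

```r
library(famcascade)
rpt <- runFullPipeline(list(seed = 1, input = list(simulate = "study_emulation")))
rpt
#> RunReport (famcascade 0.1.0, seed 1)
#>
#>               step n n_het n_hom
#> 1      segregation 8     8     0
#> 2 pass_consequence 6     6     0
#> 3             rare 4     4     0
#> 4             cadd 3     3     0
#> 5              ibd 3     3     0
#>
#> Linkage at final survivors:
#>              site      lod      p_value
#> 1 17:74842922:C:T 2.529090 0.0003215502
#> 2 17:76200000:G:A 2.529090 0.0003215502
#> 3 17:76600000:G:A 1.531161 0.0039604799
#>
#> Ranked genes: CAUSAL1, DK7, DK6
```

Eight variants co-segregate under the dominant pattern; the cascade peels
off the non-protein-altering, common, and low-CADD decoys; the planted
variant (`17:74842922:C:T` in gene `CAUSAL1`) survives every step, tops
the ranking, and its LOD of 2.53 (p ≈ 3e-4) says the co-segregation is
about 340 times likelier under linkage than by chance. The two decoys that
survive sit on the same founder haplotype — exactly the behaviour real
IBD-sharing candidates show.

Smaller pieces work standalone:

```r
lodToPvalue(2.070)
#> [1] 0.001009214
describeCodingChange(3215, "C", "T", refCodon = "GCC")$protein_label
#> [1] "p.Ala1072Val"
callApoe("T/C", "C/T")
#> ApoeCall: e2/e4 (phase ambiguous, e1/e3 suppressed)
```

A thin CLI over the same functions lives at `inst/scripts/fampri.R`
(subcommands `simulate`, `filter`, `linkage`, `hgvs`, `apoe`, `report`).

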