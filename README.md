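# kaspforge

Design and validation analysis of **degenerate-base KASP genotyping assays**
from a panel of resequenced genomes.

KASP (Kompetitive Allele-Specific PCR) assays interrogate one biallelic SNP
or InDel with two allele-specific primers and a common primer. Assays
designed from a single reference genome fail in diverse germplasm when
undetected polymorphism sits under a primer. kaspforge designs assays that
*carry the panel's flanking polymorphism inside the design sequence*: SNPs
segregating in the panel are written as IUPAC degenerate bases
(`Y` = C/T, `R` = A/G, ...) and small insertions/deletions as runs of `N`,
so primers can be placed to avoid or tolerate them.

For whom: breeders and genotyping-platform bioinformaticians converting
multi-genome variant panels into robust, trait-targeted marker panels, and
anyone auditing how design properties (ambiguous-base load, GC content)
relate to assay success.

## The method in brief

For each candidate site, with N panel genomes and reference allele $r$:

1. the most common alternative allele $a^\*$ becomes the target; the site is
   rejected if lines carrying neither $r$ nor $a^\*$ exceed 10% of N, or if
   all N lines carry the same non-reference allele (no polymorphism);
2. a genome is *low-covered* at a base when its depth $d < 0.1\,\bar d_g$
   (its genome-wide mean); the site is rejected when low genomes exceed 10%
   of N at the target base, or at **any single one** of the 100 flanking
   positions;
3. flanking variation must be encodable: at most 5 SNP sites per 50 bp
   flank, at most one indel site (one kind, one length, ≤ 10 bp, anchored
   > 5 bp from the target);
4. the degenerate design sequence (target base ± 50 bp) is screened for
   tandem repeats (> 5 copies of any 1–5 nt unit in **any** resolution of
   the degenerate letters, Ns removed first), for a **single best
   placement** in every reference assembly supplied (exact-seed +
   ungapped-extension search, ambiguity-aware, both strands), and for GC
   content within 35–65% in the 55 bp window centred on the target.

Designs are annotated for predicted effect (synonymous / nonsynonymous /
premature stop / stop or start loss / frameshift / nonframeshift) against
GFF3 gene models; trait-targeted panels are selected 5-per-locus
(functional first, then nearest, with a 100 bp identical-genotype
deduplication rule) and trimmed to a global quota. Genotyping runs are
analysed for call rate (validation requires > 90%), concordance with
design-time predictions, population structure (Euclidean + UPGMA
clustering), Wilcoxon comparisons of 29 design properties between
successful and failed assays, and an ambiguous-base cutoff sweep.

A fully seeded synthetic-data module (`sim_reference()`, `sim_panel()`,
`sim_genotyping()`) generates genomes, panels and genotyping runs with
*analytic ground truth*: the generator derives every planted site's
expected verdict with an independent straight-line reimplementation of the
rules, making the test suite a double-entry check of the pipeline.

## Worked example

```r
library(kaspforge)
library(dplyr)

ro <- sim_reference(seed = 42, n_chrom = 1, chrom_len = 30000,
                    n_genes = 8, n_microsat = 4, n_at_tracts = 2)
sp <- sim_panel(ro, seed = 43, n_genomes = 12, n_sites = 200)

filtered <- filter_sites(sp$panel, sites = sp$truth[, c("chrom", "pos")])
designs  <- build_designs(sp$panel, filtered,
                          assemblies = list(legacy = sp$legacy))
ann      <- annotate_designs(designs, ro$models, ro$reference)
designs  <- left_join(designs, ann$by_design, by = "pKey")

count(designs, failed_rule)
#>   failed_rule         n
#> 1 alignment           1
#> 2 flank_variation    30
#> 3 gc                 13
#> 4 none               86
#> 5 repeat             16
```

Of 200 planted candidate sites, 146 survived the frequency and coverage
filters (the other 54 fell to rare alleles, monomorphism or low coverage);
the design stage then rejected 30 for inadmissible flanking variation, 16
for tandem repeats, 1 for ambiguous placement and 13 for GC content,
leaving 86 designs. A design sequence carries the encoded polymorphism
directly, e.g. (design `K2`, truncated):

```
...ATGTTGATCTCCGTAKCAATTCCACTGATSGCGRCC...
                 ^ K = G/T          ^ R = A/G
```

Simulated validation genotyping of the 86 designs in 96 diverse samples:

```r
d <- filter(designs, !is.na(pKey)) |> mutate(marker = paste0("K", pKey))
g <- sim_genotyping(d$marker, seed = 44, n_samples = 96)
crs <- call_rate_summary(g$gm)
glance(crs)
#>   n_markers n_validated n_failed_all n_monomorphic n_polymorphic_validated
#> 1        86          71           15             1                      70

poly <- with(crs$markers, marker[validated & !monomorphic])
cl <- hierarchical_clusters(to_numeric_matrix(g$gm, markers = poly), k = 4)
rand_index(cl$labels[names(g$truth$groups)], g$truth$groups)
#> [1] 1
```

71 of 86 markers gave calls in more than 90% of samples (the generator
plants an ~16% total-failure rate, emulating observed KASP attrition), and
the 70 validated polymorphic markers recover the four planted
subpopulations perfectly (Rand index 1).

`tidy()`/`glance()` methods cover the result objects, and `autoplot()`
draws the dendrogram, the property-comparison table and the cutoff sweep.

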