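---
title: "Designing degenerate-base KASP assays from a resequenced genome panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing degenerate-base KASP assays from a resequenced genome panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspforge)
library(dplyr)
```

## The problem

Kompetitive Allele-Specific PCR (KASP) genotyping interrogates one biallelic
SNP or InDel per assay with two allele-specific primers and a common primer.
Assays designed against a single reference genome fail in diverse material
whenever undetected polymorphism sits under a primer. kaspforge implements a
design strategy that confronts this directly: candidate target variants are
discovered by comparing a panel of N resequenced genomes against a reference
assembly, and any *flanking* polymorphism segregating in the panel is encoded
into the design sequence itself — SNPs as IUPAC degenerate bases, small
insertions/deletions as runs of Ns — so that primer design can avoid or
tolerate it.

A *target variant* is an allele observed in the panel that differs from the
reference allele; the assay always interrogates the reference allele against
the most common alternative. The design sequence is the target base with
50 bp of flanking sequence on each side (101 bp total for SNP targets).

## The sequential filter cascade

Candidate sites pass through fixed-order filters; a site is attributed the
first rule that rejects it, so per-rule counts sum to the candidate total.

1. **Rare alleles and monomorphism.** The most common alternative allele at
   the site becomes the target. If lines carrying *neither* the reference
   allele nor that target exceed 10% of the panel, the site is rejected
   (`rare_allele`); at least 90% of lines must carry one of the two assayed
   alleles. Sites where every line carries the same non-reference allele
   show no polymorphism to assay and are rejected (`monomorphic`).
   Thresholds are strict: exactly 10% passes. Ties between equally common
   alternatives break lexicographically on the allele string.
2. **Target-site coverage.** A genome is *low-covered* at a base when its
   read depth there is below 0.1 x that genome's mean read depth (strict;
   depth exactly 0.1 x mean is acceptable). A site is rejected
   (`target_coverage`) when low genomes exceed 10% of the panel — calls at
   poorly covered sites are unreliable, so apparent monomorphism there may
   be missing data.
3. **Flank coverage.** The same per-base criterion is applied to every one
   of the 100 flanking positions; a single failing position rejects the site
   (`flank_coverage`), because an uncovered flank base could hide
   polymorphism that would silently end up under a primer. Targets closer
   than 50 bp to a chromosome end cannot provide a full flank and fail with
   detail `truncated flank`. We aggregate per flank base across genomes with
   the same >10% rule as filter 2; the stricter reading in which one low
   genome at any flank base suffices is available via `any_genome = TRUE`.
4. **Flank-variation admissibility** (`flank_variation`). All panel alleles
   within the flanks are collected per site. Admissible structure is: at
   most 5 SNP sites per flank; at most one indel site, carrying indels of
   one kind and one length, anchored more than 5 bp from the target, and at
   most 10 bases long. We apply the 5-SNP cap *per flank* (the per-design
   property battery distinguishes up to five ambiguous bases in each flank,
   which presumes up to five on a side); `per_flank = FALSE` gives the
   strict-total reading. A site whose single indel site carries both an
   insertion and a deletion — even of equal length — is rejected, because a
   single N-run cannot render both. A deletion whose deleted span would
   reach the target base is rejected even when its left anchor is more than
   5 bp away.

Surviving sites become design sequences: flank SNP sites become the minimal
IUPAC code covering the reference base and all observed alternatives; a
deletion of L bases becomes L Ns replacing the deleted bases (length stays
101 and coordinates stay reference-aligned); an insertion of L bases becomes
L Ns inserted after the anchor (length 101 + L). The target base keeps the
reference allele. Three further screens follow, in order:

* **Tandem repeats** (`repeat`): Ns are removed, every resolution of every
  degenerate letter is enumerated (cartesian product, capped at 4^10), and
  any resolution containing more than 5 consecutive copies of any 1–5 nt
  unit rejects the design. Exactly 5 copies passes. Maximal runs are counted
  over every unit phase.
* **Unique placement** (`alignment`): the design must have a single
  best-scoring alignment in the primary assembly and in every additional
  assembly supplied. The engine tiles exact 15-mer seeds over the
  unambiguous stretches of the query, extends each seed hit ungapped over
  the full query (match +1, mismatch −1; degenerate letters and Ns match
  any base of their set), and searches both strands. Ties in best score are
  detected exactly; a tie means no unique placement. This deterministic
  engine replaces an external local-alignment tool so that placement rules
  (best hit, full-length identity, tie means unknown) are re-expressed
  exactly and reproducibly; it does not compute gapped alignments or
  e-values, which the placement rules do not need.
* **GC content** (`gc`): the GC fraction of the 55 bp window centred on the
  target base must lie within [35%, 65%], bounds inclusive. Degenerate
  letters contribute the mean GC of their base set; N positions are excluded
  from numerator and denominator. The window is centred on the target
  because the allele-specific primers anneal there; no other placement is
  implied by the rule itself.

## Cross-referencing and annotation

`crossref_legacy()` places designs in an older assembly under the same
engine with one extra rule: a unique best hit below 90% full-length identity
is reported as unknown (exactly 90% is accepted). The result is
informational and never rejects a design. `position_ssr()` places legacy
microsatellite markers by their primer pairs: each primer aligns
independently, hits under 95% identity are discarded, and the marker is
positioned only when exactly one surviving pair lies within 10 kb on one
chromosome; `position_array_snp()` applies the cross-reference contract to
fixed-array SNP context sequences.

`annotate_variant()` classifies each target against GFF3 gene models:
intergenic, UTR, intron or CDS; CDS SNPs are classified by strand- and
phase-aware codon reconstruction (synonymous, nonsynonymous, premature
stop, stop loss, start loss) and CDS-overlapping indels by the number of
coding bases gained or lost (frameshift when not a multiple of 3).
A design's `functional` flag is true when *any* isoform in any annotated
assembly shows a protein-changing effect — the marker is then preferentially
selectable — since a single affected isoform is enough to make the marker
biologically interesting; the per-isoform records remain available.
Indels spanning an exon boundary are classified by their CDS-overlapping
portion, and only the standard nuclear genetic code is supported.

## Panel selection

`find_candidates()` collects, for each trait-target locus, the designs
within 20 kb (distance to the nearest interval edge; the observed distances
in the motivating application ranged up to just under 20 kb, and the round
20 kb bound is our documented generalisation). `select_per_target()` takes
up to 5 designs per target: functional designs first, nearest first, then
nonfunctional nearest-first; a candidate within 100 bp of an
already-selected design with an identical predicted genotype across all
panel lines is replaced by the next candidate — two such designs are
redundant for every practical cross. We apply this
proximity-deduplication rule in both the per-target stage and the quota
stage, reading the quota-stage rule as the operational definition of the
"very close proximity" preference. `trim_to_quota()` then removes, from the
lexicographically first target among those holding the most markers, the
nonfunctional marker farthest from its target, repeating until the distinct
design count meets the quota; if only functional markers remain the farthest
functional one is removed and logged as a deviation. All tie-breaks
(target id, then pKey) are deterministic, and pKeys themselves are assigned
in genomic order, so identical inputs yield byte-identical panels.

## Genotyping-run analysis

`call_rate_summary()` treats `?`, `Bad`, `Uncallable` and missing cells as
failed calls; a marker is *validated* when its call rate is strictly above
0.90. `to_numeric_matrix()` codes reference homozygotes 1, target calls 0
and heterozygotes either 0.5 or the marker-majority code; failed calls are
imputed with the marker mean (the upstream convention is silent on missing
cells, and marker-mean imputation is neutral for Euclidean distances).
`hierarchical_clusters()` is Euclidean distance + UPGMA (average linkage),
cut at k groups. `concordance()` compares calls against design-time
predictions; failed calls count as nonmatching, as do lines whose
design-time state was unresolvable. `?` calls are treated as missing
throughout, not as a third allele. For the success/failure property
analysis we equate *success* with validation (call rate > 0.90) and
*failure* with everything else including markers that failed in all
samples; `compare_properties()` exposes the grouping as an argument because
other partitions are defensible.

`design_properties()` computes the 29-property battery per design: flank
indel size and anchor distance (defined only for designs carrying a flank
indel — we read the indel properties as describing the design's rendered
N-run), ambiguous-base counts (total, per flank, flank-with-least/most),
distances from the target to the 1st–5th ambiguous base per flank plus
shortest-in-either-flank (needing n in at least one flank) and
longest-in-either-flank for n = 1, 2 (needing n in both flanks), and GC
percentages (whole design, each flank, lowest and highest flank).
`compare_properties()` runs two-sided Wilcoxon rank-sum tests per property
through `stats::wilcox.test()` (exact for small untied samples, normal
approximation with tie correction otherwise), skipping properties with
fewer than two eligible designs in either group; fully tied groups report
p = 1. `cutoff_sweep()` restricts designs by maximum per-flank
ambiguous-base count and reports inventory, median inter-design spacing and
genotyping outcome percentages per cutoff.

## The synthetic study

Everything is developed and validated on the `sim_*` generators, which are
deterministic under their seeds.

* `sim_reference()` draws background sequence at 43% GC (typical of a grass
  genome) and plants microsatellite tracts (1–4 nt units, 7–12 copies),
  AT-rich tracts, one duplicated 400 bp segment per chromosome, and
  non-overlapping multi-exon genes with complete CDSs on both strands.
* `sim_panel()` plants ~2,000 target sites across 20 genomes x 200 kb — the
  package's reference problem size, at which the whole cascade runs in
  about a minute — with scenario mixtures that place carrier counts, depth
  deserts, flank SNPs and flank indels on *both sides of every rule
  boundary* (exactly 10% alternative carriers, indel offsets 5 and 6,
  lengths 10 and 11, five and six flank SNPs, and so on). Mean read depths
  are drawn from 6–90x, spanning the realistic range for resequencing
  panels. Crucially, the generator also records the expected verdict of
  every planted site by an *independent straight-line reimplementation* of
  the rules (plain loops, a literal IUPAC table, a backreference-regex
  repeat scan), so the central test is a double-entry check: the pipeline
  must reproduce the truth table verdict-for-verdict and
  sequence-for-sequence.
* `sim_genotyping()` emulates a validation run: 178 samples from 4
  subpopulations with Beta-distributed group allele frequencies, 15.9% of
  markers failing in every sample, a small shaky-marker fraction, a 2%
  baseline per-call failure split 90/6/4 among `?`/`Bad`/`Uncallable`, and
  13 design lines whose calls are the design-time predictions perturbed at
  per-line discordance rates — most lines a few percent, one at 26% and one
  drifted line at 53.5%, emulating seed-lot divergence between the
  sequenced and genotyped accessions of the same variety.

What the generators do *not* emulate: read-level sequencing error and
alignment artefacts (variant calls are planted, not called), linkage
disequilibrium between flank variants, assay chemistry (primer Tm,
competitive ARMS mismatches), and genome-scale repeat families beyond the
planted microsatellites and one duplication. Passing tests therefore
demonstrate that the *rules* are implemented exactly and behave correctly
at their boundaries, not that the realised design yield or validation rate
on real resequencing data will match the synthetic ones.

## Numerical and degenerate-input choices

* All external coordinates are 1-based inclusive (FASTA/VCF/GFF3
  convention); indels are VCF-style left-anchored.
* Deletions are exempt from the depth < 5 load filter, which names SNPs and
  insertions; `filter_deletions = TRUE` restores the strict reading.
* Lines with no call at a site count as reference carriers
  (reference-based calling reports only differences); heterozygous source
  lines count as carrying their alternative allele, because the assay would
  detect it (`het_weight = 0.5` counts them as half).
* Sites with no surviving call after loading are reported as failures
  rather than errors.
* The ambiguity expansion in the repeat screen is capped at 4^10
  resolutions — the worst admissible design (10 flank SNP sites) cannot
  exceed it — and exceeding the cap is an internal error, not a verdict.
* Wilcoxon p-values on fully tied groups are reported as 1.
* Genotype markers with zero successful calls cannot enter the numeric
  matrix and raise an error rather than silently imputing a constant.

## Reference problem sizes

The test suite and the acceptance script run the default scenario
(2 chromosomes x 100 kb, 20 genomes, ~2,000 planted sites, 178-sample
genotyping run with 13 design lines); unit tests use scaled-down variants
(250 sites, 16 genomes) built once and shared. The placement-engine
equivalence suite runs 500 random genomes of 5–100 kb against an exhaustive
sliding-window oracle, and the annotation suite checks 1,000 random CDS
variants against a whole-protein translation oracle.

## A worked run

```{r pipeline, eval = TRUE}
ro <- sim_reference(seed = 42, n_chrom = 1, chrom_len = 30000,
                    n_genes = 8, n_microsat = 4, n_at_tracts = 2)
sp <- sim_panel(ro, seed = 43, n_genomes = 12, n_sites = 200)
filtered <- filter_sites(sp$panel, sites = sp$truth[, c("chrom", "pos")])
designs <- build_designs(sp$panel, filtered,
                         assemblies = list(legacy = sp$legacy))
ann <- annotate_designs(designs, ro$models, ro$reference)
designs <- left_join(designs, ann$by_design, by = "pKey")
count(designs, failed_rule)
```

```{r genotyping, eval = TRUE}
d <- filter(designs, !is.na(pKey)) |> mutate(marker = paste0("K", pKey))
g <- sim_genotyping(d$marker, seed = 44, n_samples = 96)
crs <- call_rate_summary(g$gm)
glance(crs)
poly <- with(crs$markers, marker[validated & !monomorphic])
cl <- hierarchical_clusters(to_numeric_matrix(g$gm, markers = poly), k = 4)
rand_index(cl$labels[names(g$truth$groups)], g$truth$groups)
```

## Command-line use

The exported functions are the primary interface; a thin wrapper script at
`inst/scripts/kaspforge` chains them for shell use (`kaspforge simulate`,
`kaspforge run --config cfg.yaml`), and `run_pipeline()` is the same entry
point from R. Stage subcommands of the wrapper map one-to-one onto
`filter_sites()`, `build_designs()`, the `position_*()` family,
`annotate_designs()`, the selection trio and the genotype-analysis
functions.

## Known limitations

* The placement engine requires at least one exact 15-mer seed; a query
  mutated at every 15th position would escape it. At the identity floors in
  use (90%/95%) this is not a practical concern, but the seed length is a
  parameter.
* Effect annotation assumes complete, in-frame CDS models; partial models
  annotate but trailing partial codons are ignored.
* `trim_to_quota()` treats a design shared by two targets as one panel
  member (distinct-design quota), which can require removing more per-target
  entries than the naive count suggests.
* The numeric genotype matrix imputes failed calls with the marker mean;
  markers with very low call rates should be excluded (validation already
  does this) or the imputation dominates.
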