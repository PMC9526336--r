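---
title: "Modeling recessive disease burden from recurrent genomic deletions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling recessive disease burden from recurrent genomic deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nahrburden)
library(dplyr)
```

## The problem

Nonallelic homologous recombination (NAHR) between directly oriented
segmental duplications repeatedly generates the same large genomic deletions
in unrelated individuals. Because the mutation rate of NAHR at a given locus
(up to ~1e-4 per generation) dwarfs per-base SNV mutation rates, these
recurrent deletions behave as unusually *common* loss-of-function alleles.
For a recessive gene inside such a deletion interval, the deletion can be the
single most important carrier allele: many affected individuals are expected
to be compound heterozygous for the deletion and a small variant on the other
chromosome. This package quantifies that contribution gene by gene.

The pipeline has four stages, each usable on its own:

1. **Map construction** (`build_nahr_map()` and friends): find candidate
   recurrent-deletion regions from a segmental-duplication annotation.
2. **Allele catalog** (`filter_clinvar()`, `filter_gnomad_sv()`,
   `filter_gnomad_lof_snv()`, `reconcile_prevalence()`,
   `assemble_gene_pool()`): assemble the carrier-allele pool of each
   recessive gene.
3. **Burden model** (`burden_report()` and the underlying closed forms):
   the Punnett-square disease model and the derived scores.
4. **Meta-analysis expectations** (`expected_category_distribution()`,
   `homozygote_enrichment()`): expected versus observed biallelic
   configuration categories in patient cohorts.

A seeded synthetic-data generator (`gen_segdup_track()`,
`gen_allele_table()`, `gen_cohort()`) emulates every input so the whole
pipeline is testable without downloads.

## The Punnett-square model

At a recessive locus with carrier alleles $A_1,\dots,A_n$ of population
frequencies $p_1,\dots,p_n$, random mating makes the probability of drawing
the unordered genotype $(A_i, A_j)$ equal to the product $p_i p_j$ (cells of
an $n \times n$ Punnett square). Each cell is classified **disease**,
**not disease**, or **lethal** by the genotype model; lethal cells (e.g.
homozygous loss of a large deletion that is incompatible with live birth)
contribute to neither affected individuals nor the conditional distribution.

With $S = \sum_i p_i$ over functional (non-hypomorphic) alleles and
the deletion allele indexed $k$:

* probability of being affected, default model:
  $P(D) = S^2 - \sum_{\text{lethal hom}} p_i^2$;
* probability of being affected *and* carrying the deletion:
  $P(A_k \cap D) = 2 p_k S - 2 p_k^2$ (lethal homozygote) or
  $2 p_k S - p_k^2$ (viable homozygote, counted once);
* fraction of the disease burden: $Fd_k = P(A_k \cap D) / P(D)$;
* fraction of the allele burden: $Fa_k = p_k / S$;
* odds of an affected individual carrying allele $k$:
  $O_k = Fd_k / (\sum_i Fd_i - Fd_k)$.

$\sum_i Fd_i$ deliberately exceeds 1 when compound heterozygotes exist: the
carrying events of the two alleles of a compound heterozygote overlap
(equivalently, the sum counts homozygous cells once and compound-heterozygous
cells twice).

The **NIRD** score compares the deletion allele with a *typical* allele of
the same gene:

$$\mathrm{NIRD} = \log_2 \frac{O_k}{O_{\text{median}}}$$

The median allele is chosen among the remaining alleles sorted by decreasing
Fd: the prefix is grown until it first reaches 90% of the remaining Fd sum
(discarding the bottom-10% tail of ultra-rare and hypothetical alleles), and
the allele at position $\lceil m/2 \rceil$ of the prefix is taken; Fd ties
break lexicographically by allele id. **AIRD** applies the identical
construction to an arbitrary focal allele, and
$\Delta \mathrm{NIRD} = \mathrm{NIRD}_{\text{population}} -
\mathrm{NIRD}_{\text{general}}$ compares allelic architectures between
populations with the deletion frequency held fixed (NAHR rates at a locus
are assumed population-invariant). A gene is classified as under
*significant* deletion burden when the deletion is expected in strictly more
than 20% of affected individuals ($Fd_{\text{NAHR}} > 0.20$).

### Special genotype models

Three deviations from the default model are supported, selected per gene:

* **Homozygous-viable deletions** (`hom_viable = TRUE` on the allele): the
  2q13-*NPHP1* and 15q13.3 BP4-BP5 deletions are compatible with live birth
  when homozygous, so the homozygous cell is disease, not lethal, and
  $P(D) = S^2$ with $P(A_k \cap D) = 2 p_k S - p_k^2$.
* **Hypomorphic alleles** (`allele_class = "hypomorphic"`): partial-function
  alleles that cause disease only in trans with a LoF allele and never when
  homozygous. Their frequency is excluded from the Fa denominator.
* **Biallelic-null-lethal loci** (`disease_model(lof_lof_lethal = TRUE)`):
  the *RBM8A*/*TBX6* compound-inheritance architecture, where every pair of
  null alleles is lethal and only LoF-with-hypomorph genotypes present as
  the disease; then $P(D) = 2\,S\,S_h$.
* **Nested deletions**: a gene contained in both a deletion and a larger
  deletion encompassing it carries two `nahr_del` alleles; the reported
  deletion Fd is the union event "carries at least one deletion allele",
  computed by inclusion-exclusion over the pair cell (the per-allele Fd
  values are also reported). The union's odds use the summed Fd of the
  non-deletion alleles as denominator, the natural generalisation of
  $O_k$'s "all other alleles" denominator.

`brute_force_punnett()` exposes the explicit genotype matrix under all of
these rules; every closed form above is tested against it to 1e-12 on
randomized pools, and the cohort sampler is tested against binomial
expectations.

### Worked example

```{r}
pool <- deletion_focused_pool("COX10",
                              deletion_frequency = 3.148e-4,
                              aggregate_burden = 5.05e-4)
glance(burden_report(pool))
```

A two-allele pool — the deletion plus one residual allele carrying the rest
of the aggregate burden — is sufficient here because the deletion-focused
quantities depend on the spectrum only through $p_k$ and $S$.

## Map construction choices

The deletion substrate is a pair of directly oriented repeats on the same
chromosome. Defaults for a qualifying pair (`pair_criteria()`): minimum
repeat length 10 kb, minimum identity 0.95, inter-repeat (inner-edge)
distance between 50 kb and 10 Mb. These are the canonical NAHR-substrate
criteria; all are configuration arguments, and the exact thresholds chosen
shift the region count substantially, which is why map acceptance is defined
by truth-table recovery on planted synthetic tracks rather than by a
particular genome-wide region count.

Pairs whose predicted deletion intervals reciprocally overlap by at least
0.5 are clustered by single linkage (transitive closure; `igraph`
components), and each cluster is reduced to one region whose breakpoints are
the weighted mean of the member intervals with weight
`repeat_length_min * identity` — longer, more identical substrates mediate
more events, so their intervals dominate the average. The merged coordinates
are therefore averages over deletion types, not breakpoint predictions for
any one patient.

The per-region `relative_prevalence_score()`
(`sum(length * identity / distance)` over member pairs) is a ranking
heuristic only; all prevalences used in the burden model are empirical
cohort estimates. Regions on sex chromosomes are flagged and excluded from
the autosomal burden analysis. Deletions whose substrate exists only on an
alternative haplotype (the 17q21.31 case) cannot be found in a
reference-haplotype scan and enter through
`patch_alt_haplotype_regions()` with a `manual_patch` provenance flag.

Coordinates are 0-based half-open internally and in BED output.

## Allele catalog choices

* ClinVar-style records are kept when pathogenic/likely pathogenic with at
  least one review star; records with no frequency estimate receive a floor
  frequency (default 1e-6, configurable) — ultra-rare curated alleles would
  otherwise drop out of the pool entirely.
* The gnomAD-SV criteria are implemented exactly as printed in their source
  (PASS + QUAL > 500; LoF or duplication-LoF flag; POPMAX < 1% with no
  homozygotes; < 80% segdup span overlap; LoF on all transcripts). The
  source's list numbering skips from (4) to (6); there are five predicates.
* The small-variant criteria likewise follow the printed list, including the
  "QUALapprox lower than 1e5" direction, which removes *high*-QUALapprox
  variants; because that direction is unusual, `invert_qualapprox` can apply
  the opposite reading.
* Prevalence reconciliation: two-sided conditional (hypergeometric) Fisher's
  exact test at alpha 0.05 between the two systematic cohorts; on
  disagreement the region-specific estimate arbitrates by smaller absolute
  log frequency ratio. Carrier prevalence in adults is used directly as the
  effective deletion allele frequency — for these rare deletions the
  distinction between carrier prevalence and allele frequency is a factor
  ~2 second-order effect relative to cohort-to-cohort variation, and the
  empirical adult prevalence already folds in fitness.
* Padding: each gene's pool is supplemented with ten hypothetical alleles,
  each carrying 1% of the overall burden $S_{\text{total}} =
  S_{\text{obs}}/0.9$, so the hypothetical load is exactly 10% of the padded
  burden. The alternative reading (1% of the observed burden each) is
  selectable. Padding represents not-yet-ascertained alleles and mainly
  affects the median-allele choice, which is also why the bottom 10% of the
  Fd distribution is discarded before selecting the median.

## The synthetic-data generator

`synthetic_spec()` fixes the study conditions: planted repeat pairs draw
lengths from 12-60 kb, identities from 0.955-0.999 and separations from
0.2-5 Mb (comfortably inside the qualifying thresholds), with decoys planted
from the four disqualifying classes (inverted, too short, too distant,
cross-chromosome). Carrier-allele spectra draw 4-30 alleles per gene with
log-uniform frequencies on [1e-7, 1e-2] — spanning the observed range from
the most common carrier alleles (~1e-3) to ultra-rare ones — and deletion
frequencies log-uniform on [1e-5, 1e-3], matching the prevalent-deletion
tier. Population tables rescale small-variant frequencies by fixed group
multipliers while the deletion frequency stays constant. `gen_cohort()`
samples families directly from the disease-conditioned Punnett distribution.

What the generator does *not* emulate: linkage disequilibrium and haplotype
structure, consanguinity (the model is random-mating by construction),
population growth or founder effects, sequence-level mutability, and
ascertainment bias. Tests passing on synthetic data therefore demonstrate
the correctness of the computations under the model's assumptions, not the
realism of those assumptions for any particular cohort.

## Numerical and scale choices

* All closed forms are polynomial in the frequencies; no iterative numerics
  are involved. Equivalence with the explicit matrix is asserted at 1e-12.
* Degenerate inputs error out rather than returning infinities: pools with
  no viable disease genotype ($P(D) = 0$), single-allele pools (no competing
  burden for odds), and zero-odds median alleles all raise informative
  errors.
* Percent outputs round half away from zero (`percent_round()`), matching
  published table formatting; raw fractions are always retained.
* Determinism: all generators take integer seeds and restore the caller's
  RNG state; map construction is fully deterministic.
* Test problem sizes — 1000 random pools of up to 100 alleles for oracle
  equivalence, 100 seeded cohorts of 1e6 genotypes for the Monte-Carlo
  consistency check, 1e4-record tables for filter-predicate equivalence —
  were chosen to exercise the combinatorics thoroughly while keeping the
  default suite fast on a laptop.

## Known limitations

* The map cannot recover substrate pairs absent from the reference
  haplotype (hence the manual patch mechanism), and the region count is
  sensitive to the (configurable) substrate thresholds.
* Carrier pools inherit the ascertainment of their sources; alleles not in
  ClinVar/gnomAD are represented only through the uniform 10% padding.
* The model ignores consanguinity; in populations with elevated
  autozygosity the homozygote categories will be enriched far beyond the
  random-mating expectation — that enrichment is precisely what
  `homozygote_enrichment()` measures.
* De novo deletion events in the proband generation are not modeled
  separately; the adult carrier prevalence is taken as the standing allele
  frequency.
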