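# nahrburden

Quantifying the contribution of NAHR-mediated recurrent genomic deletions to
autosomal recessive disease burden.

## The problem

Large recurrent deletions arise by nonallelic homologous recombination
(NAHR) between directly oriented segmental duplications. Because NAHR
re-generates the same deletion de novo at rates up to ~1e-4 per locus per
generation, these deletions are among the most frequent loss-of-function
alleles in the population — often orders of magnitude more frequent than any
single pathogenic SNV of a recessive gene inside the deleted interval. For
such genes, a large share of affected individuals is expected to be compound
heterozygous for the deletion and a small variant in trans. `nahrburden` is
for statistical and medical geneticists who want to compute that share and
use it to prioritise sequencing of deletion carriers.

The package implements, as composable tibble-in/tibble-out functions:

* **Deletion map construction** — enumerate directly oriented
  segmental-duplication pairs (`read_segdup()`,
  `enumerate_candidate_pairs()`), cluster them into recurrent-deletion
  regions with weighted-average breakpoints (`merge_pairs_to_regions()`),
  annotate gene content and pLI counts, patch alt-haplotype regions, and
  export BED (`build_nahr_map()`, `write_nahr_map()`).
* **Carrier-allele catalogs** — the published filtering rules for
  ClinVar-style (`filter_clinvar()`), gnomAD-SV-style (`filter_gnomad_sv()`)
  and gnomAD LoF small-variant (`filter_gnomad_lof_snv()`) tables;
  Fisher-exact reconciliation of cohort prevalences
  (`reconcile_prevalence()`); per-gene pool assembly with deletion alleles
  and 10% hypothetical-allele padding (`assemble_gene_pool()`,
  `carrier_burden()`).
* **The Punnett-square burden model** — for carrier alleles
  `A_1..A_n` with frequencies `p_i` and `S = sum(p_i)`:

  ```
  Fa_k = p_k / S
  P(D) = S^2 - sum(lethal-homozygote p_i^2)
  P(A_k & D) = 2 p_k S - 2 p_k^2        (lethal-homozygote deletion)
  Fd_k = P(A_k & D) / P(D)
  O_k  = Fd_k / (sum_i Fd_i - Fd_k)
  NIRD = log2(O_k / O_median)
  ```

  with the homozygous-viable deletion, hypomorphic-allele and
  biallelic-null-lethal model variants, the AIRD score for arbitrary focal
  alleles, population ΔNIRD, the `Fd > 20%` significant-burden
  classification, and an explicit genotype-matrix oracle
  (`brute_force_punnett()`). `burden_report()` wraps all of it with
  broom-style `tidy()`/`glance()` and `autoplot()` methods.
* **Meta-analysis expectations** — expected vs observed distributions of the
  three biallelic patient configurations (homozygous, SNV+SNV,
  deletion+SNV): `categorize_families()`,
  `expected_category_distribution()`, `homozygote_enrichment()`.
* **A seeded synthetic-data generator** — planted segdup tracks with truth
  tables, per-gene allele spectra with population variants, and patient
  cohorts sampled from the disease-conditioned Punnett distribution
  (`gen_segdup_track()`, `gen_allele_table()`, `gen_cohort()`).

## Worked example

The curated inputs shipped with the package include the 30 prevalent
recurrent-deletion regions and their per-gene deletion/burden pairs:

```r
library(nahrburden)

regions <- prevalent_deletion_regions()
nrow(regions)
#> [1] 30
length(recessive_gene_census(regions))
#> [1] 78
```

The deletion-focused quantities for a gene depend on the allele spectrum
only through the deletion frequency and the aggregate carrier burden, so a
two-allele pool reproduces them exactly. For *COX10* (inside the 17p12 HNPP
deletion, deletion allele frequency 3.148e-4, aggregate carrier burden
5.05e-4):

```r
pool <- deletion_focused_pool("COX10", 3.148e-4, 5.05e-4)
glance(burden_report(pool))
#> # A tibble: 1 × 10
#>   gene  population n_alleles aggregate_burden  p_disease fd_nahr
#>   <chr> <chr>          <int>            <dbl>      <dbl>   <dbl>
#> 1 COX10 general            2         0.000505   1.56e-7    0.768
#> # fd_nahr_percent nird  median_allele_id significant_nahr_burden
#> #              77 ...   COX10_residual   TRUE
```

`fd_nahr = 0.768` means ~77% of individuals affected with biallelic *COX10*
disease are expected to carry one HNPP deletion allele — the deletion, not
any single SNV, dominates the disease burden, and the gene is classified as
under significant NAHR deletion burden (Fd > 20%). The same call with
`deletion_focused_pool("NPHP1", 5.811e-3, 6.82e-3, hom_viable = TRUE)`
(homozygous deletions of 2q13 are viable) gives Fd = 98% and Fa = 85%.

End-to-end on synthetic data:

```r
track <- gen_segdup_track(synthetic_spec(seed = 7, n_regions = 5, n_decoys = 20))
build_nahr_map(track$segdup)   # recovers the 5 planted regions

tabs <- gen_allele_table(synthetic_spec(seed = 7))
pool <- dplyr::filter(tabs$general, gene == "GENE001")
fams <- gen_cohort(pool, n_families = 1000, seed = 7)
table(fams$category)
```

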