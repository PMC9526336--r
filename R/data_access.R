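#' Curated prevalent recurrent-deletion regions (GRCh38)
#'
#' The 30 autosomal recurrent-deletion regions with a maximal population
#' allele frequency over 1e-6, as curated from large population cohorts
#' (UK Biobank, the Icelandic cohort, gnomAD SV) and region-specific studies,
#' shipped as a plain-text table with the package. Frequencies are stored in
#' units of 1e-6 in the file and returned as fractions.
#'
#' @return A tibble with columns `region`, `chrom`, `start`, `end`,
#'   `population_allele_frequency`, `diagnostic_allele_frequency`,
#'   `known_recessive_genes` (list-column of gene symbols, empty when none)
#'   and `n_coding_genes`.
#' @export
#' @examples
#' regs <- prevalent_deletion_regions()
#' nrow(regs)
#' length(unique(unlist(regs$known_recessive_genes)))
prevalent_deletion_regions <- function() {
  path <- system.file("extdata", "prevalent_regions_grch38.tsv",
                      package = "nahrburden", mustWork = TRUE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  coords <- strsplit(raw$coordinates, "[:-]")
  tibble::tibble(
    region = raw$region,
    chrom = purrr::map_chr(coords, 1),
    start = as.numeric(purrr::map_chr(coords, 2)),
    end = as.numeric(purrr::map_chr(coords, 3)),
    population_allele_frequency = raw$population_allele_frequency_e6 * 1e-6,
    diagnostic_allele_frequency = raw$diagnostic_allele_frequency_e6 * 1e-6,
    known_recessive_genes = purrr::map(raw$known_recessive_genes, function(g) {
      if (g == "-") character(0) else trimws(strsplit(g, ",")[[1]])
    }),
    n_coding_genes = raw$n_coding_genes
  )
}

#' Census of known recessive genes inside prevalent deletion regions
#'
#' Deduplicates the recessive-gene annotations of
#' [prevalent_deletion_regions()]: genes appearing in overlapping/nested
#' regions are counted once.
#'
#' @param regions Output of [prevalent_deletion_regions()] (the default).
#' @return Character vector of unique gene symbols, sorted.
#' @export
recessive_gene_census <- function(regions = prevalent_deletion_regions()) {
  sort(unique(unlist(regions$known_recessive_genes)))
}

#' Curated deletion-focused gene burden inputs
#'
#' Per-gene inputs for the deletion-focused Punnett model as curated from
#' population data: the deletion allele frequency, the gene's aggregate
#' carrier allele frequency, and whether the deletion is homozygous-viable.
#'
#' @return A tibble with columns `gene`, `region`, `deletion_frequency`,
#'   `aggregate_burden`, `hom_viable`.
#' @export
deletion_gene_burden <- function() {
  path <- system.file("extdata", "deletion_gene_burden.tsv",
                      package = "nahrburden", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    gene = readr::col_character(),
                    region = readr::col_character(),
                    deletion_frequency = readr::col_double(),
                    aggregate_burden = readr::col_double(),
                    hom_viable = readr::col_logical()))
}

#' Two-allele deletion-focused pool
#'
#' The deletion-focused burden quantities (P(D), P(A_del & D), Fd, Fa of the
#' deletion) depend on the allele spectrum only through the deletion
#' frequency `p_k` and the aggregate non-hypomorphic burden `S`, so a
#' two-allele pool — the deletion plus one residual allele of frequency
#' `S - p_k` — reproduces them exactly. This is the pool used to recompute
#' published per-gene deletion contributions from their printed
#' (prevalence, aggregate burden) pairs.
#'
#' @param gene Gene symbol.
#' @param deletion_frequency Deletion allele frequency `p_k`.
#' @param aggregate_burden Aggregate carrier allele frequency `S >= p_k`.
#' @param hom_viable Whether the deletion is viable when homozygous.
#' @return A carrier pool tibble with two alleles.
#' @export
deletion_focused_pool <- function(gene, deletion_frequency, aggregate_burden,
                                  hom_viable = FALSE) {
  if (aggregate_burden < deletion_frequency) {
    rlang::abort("aggregate burden must be at least the deletion frequency")
  }
  carrier_pool(tibble::tibble(
    allele_id = c(paste0(gene, "_del"), paste0(gene, "_residual")),
    allele_class = c("nahr_del", "snv_indel"),
    frequency = c(deletion_frequency, aggregate_burden - deletion_frequency),
    hom_viable = c(hom_viable, FALSE),
    source = c("prevalence_table", "aggregate")
  ), gene = gene)
}
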