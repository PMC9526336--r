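#' Specification for the synthetic-data generator
#'
#' Collects the distributional knobs used by [gen_segdup_track()] and
#' [gen_allele_table()]. Defaults emulate the data shapes the analysis
#' consumes: repeat pairs with lengths, identities and separations in the
#' canonical NAHR-substrate range, and per-gene allele-frequency spectra that
#' are log-uniform over [1e-7, 1e-2], spanning the observed range from the
#' most common carrier alleles down to ultra-rare ones.
#'
#' @param seed Integer seed; fixed seed gives identical outputs.
#' @param n_regions Number of qualifying repeat pairs to plant.
#' @param n_decoys Number of disqualifying records to interleave.
#' @param repeat_length_range,identity_range,distance_range Ranges for planted
#'   qualifying pairs (bp, fraction, bp).
#' @param n_genes Number of genes for [gen_allele_table()].
#' @param alleles_per_gene_range Range of per-gene small-variant allele counts.
#' @param freq_bounds Log-uniform bounds for small-variant allele frequencies.
#' @param deletion_freq_bounds Bounds for deletion allele frequencies.
#' @param fraction_in_region Fraction of genes carrying an NAHR deletion allele.
#' @param fraction_hypomorphic Fraction of small-variant alleles drawn as
#'   hypomorphic (0 by default; set > 0 to exercise the compound model).
#' @param population_multipliers Named multipliers applied to small-variant
#'   frequencies per population; the deletion frequency is held constant
#'   across populations (NAHR mutation rates at a locus are assumed
#'   population-invariant).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_regions = 5L, n_decoys = 10L,
                           repeat_length_range = c(12e3, 60e3),
                           identity_range = c(0.955, 0.999),
                           distance_range = c(2e5, 5e6),
                           n_genes = 20L,
                           alleles_per_gene_range = c(4L, 30L),
                           freq_bounds = c(1e-7, 1e-2),
                           deletion_freq_bounds = c(1e-5, 1e-3),
                           fraction_in_region = 0.5,
                           fraction_hypomorphic = 0,
                           population_multipliers = c(AFR = 1.6, AMR = 0.8,
                                                      EAS = 0.5, EUR = 1.2)) {
  stopifnot(all(freq_bounds > 0), all(deletion_freq_bounds > 0),
            all(repeat_length_range > 0), all(distance_range > 0))
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic segmental-duplication track with planted regions
#'
#' Plants `n_regions` qualifying directly oriented repeat pairs on autosomes,
#' well separated so that each yields one recovered region, and interleaves
#' `n_decoys` disqualifying records (inverted orientation, too-short repeats,
#' too-distant pairs, or cross-chromosome partners). Deterministic under the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `segdup` (tibble in [read_segdup()] form) and `truth`
#'   (tibble of planted deletion intervals: `chrom`, `del_start`, `del_end`).
#' @export
gen_segdup_track <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  chroms <- paste0("chr", 1:8)
  # each plant occupies at most repeat + distance + repeat; space plants on a
  # fixed grid so they can never overlap
  slot <- 2 * max(spec$repeat_length_range) + max(spec$distance_range) + 1e6
  slots_per_chrom <- floor(2.4e8 / slot)
  if (spec$n_regions > slots_per_chrom * length(chroms)) {
    rlang::abort("requested plants exceed chromosome capacity without overlap")
  }
  local_seed(spec$seed)
  plant_one <- function(i) {
    chrom <- chroms[((i - 1) %% length(chroms)) + 1]
    base <- 1e6 + floor((i - 1) / length(chroms)) * slot
    len1 <- round(stats::runif(1, spec$repeat_length_range[1], spec$repeat_length_range[2]))
    len2 <- round(stats::runif(1, spec$repeat_length_range[1], spec$repeat_length_range[2]))
    dist <- round(stats::runif(1, spec$distance_range[1], spec$distance_range[2]))
    ident <- stats::runif(1, spec$identity_range[1], spec$identity_range[2])
    tibble::tibble(chrom = chrom, start = base, end = base + len1,
                   other_chrom = chrom, other_start = base + len1 + dist,
                   other_end = base + len1 + dist + len2,
                   strand = "+", frac_match = round(ident, 4))
  }
  planted <- dplyr::bind_rows(purrr::map(seq_len(spec$n_regions), plant_one))
  truth <- tibble::tibble(chrom = planted$chrom,
                          del_start = planted$end,
                          del_end = planted$other_start)

  decoy_one <- function(i) {
    kind <- c("inverted", "short", "distant", "cross_chrom")[((i - 1) %% 4) + 1]
    chrom <- chroms[(i %% length(chroms)) + 1]
    base <- 2.45e8 + i * 5e6  # decoy zone, clear of the planted grid
    len <- switch(kind, short = 2e3,
                  round(stats::runif(1, spec$repeat_length_range[1],
                                     spec$repeat_length_range[2])))
    dist <- switch(kind, distant = 5e7,
                   round(stats::runif(1, spec$distance_range[1],
                                      spec$distance_range[2])))
    tibble::tibble(
      chrom = chrom, start = base, end = base + len,
      other_chrom = if (kind == "cross_chrom") "chr9" else chrom,
      other_start = base + len + dist, other_end = base + len + dist + len,
      strand = if (kind == "inverted") "-" else "+",
      frac_match = round(stats::runif(1, spec$identity_range[1],
                                      spec$identity_range[2]), 4))
  }
  decoys <- if (spec$n_decoys > 0) {
    dplyr::bind_rows(purrr::map(seq_len(spec$n_decoys), decoy_one))
  } else NULL
  segdup <- dplyr::bind_rows(planted, decoys)
  segdup <- dplyr::arrange(segdup, .data$chrom, .data$start)
  list(segdup = segdup, truth = dplyr::arrange(truth, .data$chrom, .data$del_start))
}

#' Generate synthetic per-gene carrier-allele tables
#'
#' Draws a carrier-allele spectrum for each gene: a per-gene allele count,
#' log-uniform small-variant frequencies, optional hypomorphic alleles, and
#' one NAHR deletion allele for genes flagged in-region. Population-specific
#' tables scale the small-variant frequencies by the group multipliers while
#' keeping the deletion frequency constant.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `general` (carrier-allele tibble over all genes) and
#'   `populations` (named list of tibbles, one per population label).
#' @export
gen_allele_table <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_seed(spec$seed + 1L)
  genes <- sprintf("GENE%03d", seq_len(spec$n_genes))
  in_region <- seq_len(spec$n_genes) <= round(spec$fraction_in_region * spec$n_genes)

  one_gene <- function(g, has_del) {
    k <- sample(seq(spec$alleles_per_gene_range[1],
                    spec$alleles_per_gene_range[2]), 1)
    freq <- exp(stats::runif(k, log(spec$freq_bounds[1]), log(spec$freq_bounds[2])))
    hyp <- stats::runif(k) < spec$fraction_hypomorphic
    tbl <- tibble::tibble(
      gene = g,
      allele_id = sprintf("%s_snv_%03d", g, seq_len(k)),
      allele_class = ifelse(hyp, "hypomorphic", "snv_indel"),
      frequency = freq,
      hom_viable = FALSE,
      source = "gnomad_snv")
    if (has_del) {
      del_freq <- exp(stats::runif(1, log(spec$deletion_freq_bounds[1]),
                                   log(spec$deletion_freq_bounds[2])))
      tbl <- dplyr::bind_rows(tbl, tibble::tibble(
        gene = g, allele_id = paste0(g, "_del"),
        allele_class = "nahr_del", frequency = del_freq,
        hom_viable = FALSE, source = "prevalence_table"))
    }
    tbl
  }
  general <- dplyr::bind_rows(purrr::map2(genes, in_region, one_gene))
  populations <- purrr::imap(as.list(spec$population_multipliers), function(m, lab) {
    out <- general
    small <- out$allele_class != "nahr_del"
    out$frequency[small] <- pmin(out$frequency[small] * m, 0.05)
    out
  })
  list(general = general, populations = populations)
}

#' Sample a synthetic patient cohort from the conditioned Punnett square
#'
#' Draws `n_families` unordered biallelic genotypes with probability
#' proportional to the Punnett-cell disease mass (lethal and non-disease
#' cells excluded), i.e. from the distribution of genotypes among affected
#' individuals, and labels each family with its configuration category.
#'
#' @inheritParams brute_force_punnett
#' @param n_families Number of families to sample.
#' @param seed Integer seed.
#' @return A tibble with one row per family: `family_id`, `gene`,
#'   `allele_1`, `allele_2`, `category` (`HMZ` / `SNV_SNV` / `NAHRdel_SNV`,
#'   with deletion homozygotes labelled `HMZ`).
#' @export
gen_cohort <- function(pool, model = NULL, n_families = 1000, seed = 1L) {
  model <- as_disease_model(model)
  pool <- carrier_pool(pool)
  pm <- brute_force_punnett(pool, model)
  if (pm$p_disease <= 0) rlang::abort("no viable disease genotype: P(D) = 0")
  n <- nrow(pool)
  # unordered genotype masses: diagonal once, upper triangle doubled
  idx <- which(upper.tri(pm$prob, diag = TRUE) & pm$status == "disease",
               arr.ind = TRUE)
  if (nrow(idx) == 0) rlang::abort("no viable disease genotype: P(D) = 0")
  mass <- pm$prob[idx] * ifelse(idx[, 1] == idx[, 2], 1, 2)
  local_seed(seed)
  draw <- sample.int(nrow(idx), n_families, replace = TRUE, prob = mass)
  i <- idx[draw, 1]; j <- idx[draw, 2]
  is_del <- pool$allele_class == "nahr_del"
  tibble::tibble(
    family_id = sprintf("fam%06d", seq_len(n_families)),
    gene = pool$gene[1],
    allele_1 = pool$allele_id[i],
    allele_2 = pool$allele_id[j],
    category = dplyr::case_when(
      i == j ~ "HMZ",
      is_del[i] | is_del[j] ~ "NAHRdel_SNV",
      TRUE ~ "SNV_SNV"
    )
  )
}

# Seed the session RNG locally and deterministically (restores the caller's
# RNG state when the calling function exits).
local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed %% .Machine$integer.max),
                    .local_envir = env)
  invisible(seed)
}
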