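#' Normalise a curated patient-family table into configuration categories
#'
#' Every family affected with a biallelic recessive condition falls into one
#' of three configurations: `HMZ` (homozygous small variant), `SNV_SNV`
#' (compound-heterozygous small variants), or `NAHRdel_SNV` (recurrent
#' deletion in trans with a small variant). Counting rules: a homozygous
#' variant is counted once per family; each compound-heterozygous small
#' variant receives one count per family. Rows whose partner allele is a
#' non-NAHR gross deletion/insertion larger than 50 bp are excluded with a
#' reason (such events are outside the small-variant curation scope).
#'
#' @param records A tibble with columns `gene`, `family_id`, `zygosity`
#'   (`"hom"`/`"comp_het"`), `allele_1`, `allele_2` (NA for homozygotes),
#'   `partner_class` (class of `allele_2`: `"snv"`, `"nahr_del"`, or
#'   `"gross_sv"`), and optionally `partner_size_bp` for SV partners.
#' @param exclude_genes Genes dropped from the analysis (e.g. a gene whose
#'   literature cohort does not represent the natural allele composition).
#' @return A tibble of family records with `category`, plus an `"excluded"`
#'   attribute listing dropped rows and reasons.
#' @export
categorize_families <- function(records, exclude_genes = character()) {
  records <- tibble::as_tibble(records)
  records <- records[!records$gene %in% exclude_genes, ]
  is_hom <- records$zygosity == "hom"
  partner <- ifelse(is.na(records$partner_class), "snv", records$partner_class)
  size <- if ("partner_size_bp" %in% names(records)) records$partner_size_bp else NA_real_
  bad_sv <- !is_hom & partner == "gross_sv" &
    (is.na(size) | size > 50)
  excluded <- records[bad_sv, ]
  records <- records[!bad_sv, ]
  is_hom <- records$zygosity == "hom"
  partner <- ifelse(is.na(records$partner_class), "snv", records$partner_class)

  out <- tibble::tibble(
    gene = records$gene,
    family_id = records$family_id,
    category = dplyr::case_when(
      is_hom ~ "HMZ",
      partner == "nahr_del" ~ "NAHRdel_SNV",
      TRUE ~ "SNV_SNV"
    ),
    allele_1 = records$allele_1,
    allele_2 = ifelse(is_hom, NA_character_, records$allele_2),
    # counting rule: hom = one allele count; compound het = one per allele
    n_allele_counts = ifelse(is_hom, 1L, 2L)
  )
  attr(out, "excluded") <- dplyr::mutate(excluded, reason = "gross_sv_partner_over_50bp")
  out
}

#' Expected distribution of biallelic configuration categories
#'
#' Partitions the viable disease mass of the Punnett square into the three
#' patient configurations: `HMZ` = disease-causing homozygous cells (any
#' allele class, so a homozygous-viable deletion homozygote counts here),
#' `NAHRdel_SNV` = off-diagonal disease cells involving at least one NAHR
#' deletion allele, `SNV_SNV` = remaining off-diagonal disease cells. The
#' fractions always sum to 1.
#'
#' @inheritParams brute_force_punnett
#' @return A one-row tibble: `gene`, `hmz`, `snv_snv`, `nahrdel_snv`
#'   (fractions of P(D)) and `ratio_del_vs_snv` (`nahrdel_snv / snv_snv`,
#'   `Inf` when no compound-het SNV mass exists).
#' @export
expected_category_distribution <- function(pool, model = NULL) {
  model <- as_disease_model(model)
  pool <- carrier_pool(pool)
  pm <- brute_force_punnett(pool, model)
  if (pm$p_disease <= 0) rlang::abort("no viable disease genotype: P(D) = 0")
  disease <- pm$status == "disease"
  is_del <- pool$allele_class == "nahr_del"
  diag_mask <- diag(TRUE, nrow(pool)) > 0
  del_cell <- outer(is_del, is_del, `|`)

  hmz <- sum(pm$prob[disease & diag_mask])
  nahrdel_snv <- sum(pm$prob[disease & !diag_mask & del_cell])
  snv_snv <- sum(pm$prob[disease & !diag_mask & !del_cell])
  tibble::tibble(
    gene = pool$gene[1],
    hmz = hmz / pm$p_disease,
    snv_snv = snv_snv / pm$p_disease,
    nahrdel_snv = nahrdel_snv / pm$p_disease,
    ratio_del_vs_snv = ifelse(snv_snv > 0, nahrdel_snv / snv_snv, Inf)
  )
}

#' Fold enrichment of observed over expected category fractions
#'
#' Compares observed per-gene category fractions with the model expectation,
#' typically for the homozygote category (an excess of homozygotes indicates
#' ascertainment from populations with elevated autozygosity).
#'
#' @param expected A tibble with columns `gene` and the expected fraction
#'   column named by `category` (as from [expected_category_distribution()],
#'   lowercase column names).
#' @param observed A tibble of family records with `gene` and `category`
#'   columns (as from [categorize_families()]), or a pre-aggregated tibble
#'   with `gene`, `observed_fraction`.
#' @param category Category to compare, default `"HMZ"`.
#' @return A list with `per_gene` (tibble: gene, expected_fraction,
#'   observed_fraction, fold; genes with zero expected and nonzero observed
#'   are flagged `infinite_fold` and excluded from the summary) and `summary`
#'   (min, median, max fold over genes).
#' @export
homozygote_enrichment <- function(expected, observed, category = "HMZ") {
  col <- tolower(category)
  stopifnot(col %in% names(expected))
  if ("category" %in% names(observed)) {
    obs <- observed |>
      dplyr::count(.data$gene, .data$category) |>
      dplyr::group_by(.data$gene) |>
      dplyr::mutate(observed_fraction = .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$category == !!category) |>
      dplyr::select("gene", "observed_fraction")
    # genes with zero observed in the focal category
    all_genes <- unique(observed$gene)
    missing <- setdiff(all_genes, obs$gene)
    if (length(missing) > 0) {
      obs <- dplyr::bind_rows(obs, tibble::tibble(gene = missing,
                                                  observed_fraction = 0))
    }
  } else {
    obs <- dplyr::select(observed, "gene", "observed_fraction")
  }
  per_gene <- expected |>
    dplyr::select("gene", expected_fraction = dplyr::all_of(col)) |>
    dplyr::inner_join(obs, by = "gene") |>
    dplyr::mutate(
      infinite_fold = .data$expected_fraction == 0 & .data$observed_fraction > 0,
      fold = dplyr::case_when(
        .data$infinite_fold ~ Inf,
        .data$observed_fraction == 0 ~ 0,
        TRUE ~ .data$observed_fraction / .data$expected_fraction
      )
    )
  finite <- per_gene$fold[!per_gene$infinite_fold]
  list(per_gene = per_gene,
       summary = tibble::tibble(min_fold = min(finite),
                                median_fold = stats::median(finite),
                                max_fold = max(finite)))
}
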