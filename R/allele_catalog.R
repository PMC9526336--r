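#' Filter ClinVar-style records to high-quality pathogenic alleles
#'
#' Keeps records with a pathogenic or likely pathogenic classification and at
#' least a one-star review status, and emits them as `snv_indel` carrier
#' alleles. Records lacking any population frequency receive a configurable
#' floor frequency (ultra-rare alleles curated in ClinVar are frequently
#' absent from frequency databases).
#'
#' @param records A tibble with columns `gene`, `allele_id`,
#'   `clinical_significance`, `review_status` (either an integer star count or
#'   a ClinVar review-status string) and `frequency` (NA allowed).
#' @param floor_frequency Frequency assigned to records without an estimate,
#'   default 1e-6.
#' @return A carrier-allele tibble (`gene`, `allele_id`, `allele_class`,
#'   `frequency`, `hom_viable`, `source`). Records missing a gene symbol are
#'   skipped with a warning.
#' @export
filter_clinvar <- function(records, floor_frequency = 1e-6) {
  records <- tibble::as_tibble(records)
  no_gene <- is.na(records$gene) | records$gene == ""
  if (any(no_gene)) {
    rlang::warn(sprintf("skipping %d ClinVar record(s) without a gene symbol",
                        sum(no_gene)))
    records <- records[!no_gene, ]
  }
  keep <- is_pathogenic(records$clinical_significance) &
    clinvar_stars(records$review_status) >= 1
  kept <- records[keep, ]
  freq <- kept$frequency
  freq[is.na(freq)] <- floor_frequency
  carrier_pool_rows(kept$gene, kept$allele_id, "snv_indel", freq, "clinvar")
}

is_pathogenic <- function(x) {
  x <- tolower(as.character(x))
  grepl("pathogenic", x) & !grepl("conflicting", x) & !grepl("benign", x)
}

#' Map ClinVar review-status labels to star counts
#'
#' @param x Integer star counts (returned unchanged) or ClinVar
#'   `CLNREVSTAT`-style strings.
#' @return Integer star counts (0-4).
#' @export
clinvar_stars <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  s <- tolower(gsub("[ _]", "", as.character(x)))
  dplyr::case_when(
    grepl("noassertion", s) ~ 0L,
    grepl("practiceguideline", s) ~ 4L,
    grepl("expertpanel", s) ~ 3L,
    grepl("multiplesubmitters,noconflicts", s) ~ 2L,
    grepl("criteriaprovided", s) ~ 1L,
    TRUE ~ 0L
  )
}

carrier_pool_rows <- function(gene, allele_id, allele_class, frequency, source) {
  tibble::tibble(gene = as.character(gene),
                 allele_id = as.character(allele_id),
                 allele_class = allele_class,
                 frequency = as.numeric(frequency),
                 hom_viable = FALSE,
                 source = source)
}

#' Filter gnomAD-SV-style records to loss-of-function deletion alleles
#'
#' A structural variant is kept only when all of the following hold:
#' (1) PASS filter with quality score over 500; (2) a protein-coding LoF or
#' duplication-LoF flag; (3) POPMAX allele frequency below 1% with no
#' homozygote counts; (4) less than 80% of the span overlapping segmental
#' duplications; and the LoF consequence affects all RefSeq transcripts of
#' the gene. (The source criteria list numbers these (1)-(4) and (6); five
#' predicates in total.) Records missing a required field are rejected with a
#' reason code rather than silently kept; rejection reasons are attached as
#' the `"rejections"` attribute of the result.
#'
#' @param records A tibble with columns `gene`, `allele_id`, `filter`, `qual`,
#'   `protein_coding_lof`, `protein_coding_dup_lof` (logicals), `popmax_af`,
#'   `nhomalt`, `chrom`, `start`, `end`, `af`, `lof_all_transcripts`
#'   (logical).
#' @param segdup_track Tibble with `chrom`, `start`, `end` giving segmental
#'   duplication intervals (0-based half-open) used for the span-overlap
#'   criterion.
#' @param max_segdup_overlap Maximum tolerated overlapping span fraction,
#'   default 0.8 (strict).
#' @return A carrier-allele tibble of class `sv_lof` alleles.
#' @export
filter_gnomad_sv <- function(records, segdup_track = NULL,
                             max_segdup_overlap = 0.8) {
  records <- tibble::as_tibble(records)
  required <- c("gene", "allele_id", "filter", "qual", "protein_coding_lof",
                "protein_coding_dup_lof", "popmax_af", "nhomalt", "chrom",
                "start", "end", "af", "lof_all_transcripts")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("gnomAD-SV table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  overlap <- segdup_overlap_fraction(records, segdup_track)
  reason <- dplyr::case_when(
    is.na(records$filter) | is.na(records$qual) | is.na(records$popmax_af) |
      is.na(records$nhomalt) | is.na(records$lof_all_transcripts) ~ "missing_field",
    records$filter != "PASS" | records$qual <= 500 ~ "filter_or_quality",
    !(records$protein_coding_lof | records$protein_coding_dup_lof) ~ "not_lof",
    records$popmax_af >= 0.01 | records$nhomalt > 0 ~ "too_common_or_homozygous",
    overlap >= max_segdup_overlap ~ "segdup_overlap",
    !records$lof_all_transcripts ~ "partial_transcript_lof",
    TRUE ~ NA_character_
  )
  kept <- records[is.na(reason), ]
  out <- carrier_pool_rows(kept$gene, kept$allele_id, "sv_lof", kept$af,
                           "gnomad_sv")
  attr(out, "rejections") <- tibble::tibble(
    allele_id = records$allele_id[!is.na(reason)],
    reason = reason[!is.na(reason)])
  out
}

segdup_overlap_fraction <- function(records, segdup_track) {
  if (is.null(segdup_track) || nrow(segdup_track) == 0) {
    return(rep(0, nrow(records)))
  }
  purrr::pmap_dbl(list(records$chrom, records$start, records$end),
                  function(ch, s, e) {
    hit <- segdup_track[segdup_track$chrom == ch &
                          segdup_track$start < e & segdup_track$end > s, ]
    if (nrow(hit) == 0) return(0)
    # union of overlapping segdup bases within [s, e)
    iv <- dplyr::arrange(
      tibble::tibble(s = pmax(hit$start, s), e = pmin(hit$end, e)), s)
    covered <- 0
    cur_s <- iv$s[1]; cur_e <- iv$e[1]
    for (k in seq_len(nrow(iv))[-1]) {
      if (iv$s[k] <= cur_e) cur_e <- max(cur_e, iv$e[k])
      else { covered <- covered + (cur_e - cur_s); cur_s <- iv$s[k]; cur_e <- iv$e[k] }
    }
    covered <- covered + (cur_e - cur_s)
    covered / (e - s)
  })
}

#' Filter gnomAD-style small variants to high-confidence LoF alleles
#'
#' A small variant is kept only when all six criteria hold: (1) PASS filter;
#' (2) outside low-complexity regions; (3) QUALapprox score lower than 1e5;
#' (4) sequenced in over 7.5e4 alleles; (5) population allele frequency below
#' 1% with no homozygous counts; (6) marked as a high-confidence LoF by
#' LOFTEE. Criterion (3) is implemented exactly as stated (it removes
#' variants with *high* QUALapprox); set `invert_qualapprox = TRUE` to apply
#' the opposite direction instead.
#'
#' @param records A tibble with columns `gene`, `allele_id`, `filter`,
#'   `chrom`, `pos`, `qualapprox`, `an`, `af`, `nhomalt`, `loftee`.
#' @param lcr_track Tibble with `chrom`, `start`, `end` low-complexity-region
#'   intervals (0-based half-open); a variant whose position falls inside one
#'   is excluded.
#' @param qualapprox_max QUALapprox threshold, default 1e5.
#' @param invert_qualapprox Apply `qualapprox >= qualapprox_max` instead.
#' @param max_af,min_an Frequency and allele-number thresholds (defaults 1%
#'   and 7.5e4, both strict).
#' @return A carrier-allele tibble of `snv_indel` alleles, with a
#'   `"rejections"` attribute as in [filter_gnomad_sv()].
#' @export
filter_gnomad_lof_snv <- function(records, lcr_track = NULL,
                                  qualapprox_max = 1e5,
                                  invert_qualapprox = FALSE,
                                  max_af = 0.01, min_an = 7.5e4) {
  records <- tibble::as_tibble(records)
  required <- c("gene", "allele_id", "filter", "chrom", "pos", "qualapprox",
                "an", "af", "nhomalt", "loftee")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("gnomAD small-variant table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  in_lcr <- position_in_track(records, lcr_track)
  qual_ok <- if (invert_qualapprox) records$qualapprox >= qualapprox_max
             else records$qualapprox < qualapprox_max
  reason <- dplyr::case_when(
    is.na(records$filter) | is.na(records$qualapprox) | is.na(records$an) |
      is.na(records$af) | is.na(records$nhomalt) | is.na(records$loftee) ~ "missing_field",
    records$filter != "PASS" ~ "non_pass",
    in_lcr ~ "low_complexity_region",
    !qual_ok ~ "qualapprox",
    records$an <= min_an ~ "insufficient_allele_number",
    records$af >= max_af | records$nhomalt > 0 ~ "too_common_or_homozygous",
    toupper(records$loftee) != "HC" ~ "not_high_confidence_lof",
    TRUE ~ NA_character_
  )
  kept <- records[is.na(reason), ]
  out <- carrier_pool_rows(kept$gene, kept$allele_id, "snv_indel", kept$af,
                           "gnomad_snv")
  attr(out, "rejections") <- tibble::tibble(
    allele_id = records$allele_id[!is.na(reason)],
    reason = reason[!is.na(reason)])
  out
}

position_in_track <- function(records, track) {
  if (is.null(track) || nrow(track) == 0) return(rep(FALSE, nrow(records)))
  purrr::map2_lgl(records$chrom, records$pos, function(ch, p) {
    any(track$chrom == ch & track$start <= p & p < track$end)
  })
}

#' Reconcile deletion-prevalence estimates across cohorts
#'
#' The two largest systematic population cohorts (UK-Biobank-style and
#' Iceland-style) are compared first with a two-sided Fisher's exact test on
#' the 2x2 carrier-by-cohort table. When the estimates do not differ
#' significantly (p > alpha), the larger cohort's (UK Biobank) estimate is
#' taken. Otherwise, the region-specific cohort's estimate is compared with
#' both (smaller absolute log frequency ratio = closer match) and the closer
#' cohort's estimate is chosen.
#'
#' @param estimates A tibble with columns `cohort` (labels containing
#'   `"ukbiobank"`, `"iceland"`, and optionally `"region_specific"`),
#'   `carrier_count`, `cohort_size`, and optionally `allele_frequency`
#'   (derived as `carrier_count / cohort_size` when absent: the empirical
#'   carrier prevalence in adults is used directly as the effective deletion
#'   allele frequency in the burden model).
#' @param alpha Significance level for the Fisher test, default 0.05.
#' @return A one-row tibble: the chosen estimate plus `decision` (a trace of
#'   the rule applied) and `p_value` (NA when no test was performed).
#' @export
reconcile_prevalence <- function(estimates, alpha = 0.05) {
  estimates <- tibble::as_tibble(estimates)
  if (!"allele_frequency" %in% names(estimates)) {
    estimates$allele_frequency <- NA_real_
  }
  derive <- is.na(estimates$allele_frequency)
  estimates$allele_frequency[derive] <-
    estimates$carrier_count[derive] / estimates$cohort_size[derive]

  ukb <- estimates[grepl("ukbiobank", estimates$cohort, ignore.case = TRUE), ]
  ice <- estimates[grepl("iceland", estimates$cohort, ignore.case = TRUE), ]
  if (nrow(ukb) == 0 && nrow(estimates) == 1) {
    return(dplyr::mutate(estimates, decision = "single source", p_value = NA_real_))
  }
  if (nrow(ukb) == 0) rlang::abort("a UK-Biobank-labeled estimate is required")
  ukb <- ukb[1, ]
  if (nrow(ice) == 0) {
    return(dplyr::mutate(ukb, decision = "single source", p_value = NA_real_))
  }
  ice <- ice[1, ]
  counts <- c(ukb$carrier_count, ukb$cohort_size, ice$carrier_count, ice$cohort_size)
  if (anyNA(counts)) {
    rlang::abort("Fisher reconciliation requires carrier and cohort counts")
  }
  tab <- matrix(c(ukb$carrier_count, ukb$cohort_size - ukb$carrier_count,
                  ice$carrier_count, ice$cohort_size - ice$carrier_count),
                nrow = 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  if (p > alpha) {
    return(dplyr::mutate(ukb, decision = "concordant: UK Biobank taken",
                         p_value = p))
  }
  rs <- estimates[grepl("region", estimates$cohort, ignore.case = TRUE), ]
  if (nrow(rs) == 0) {
    rlang::abort("cohorts differ significantly but no region-specific estimate supplied")
  }
  rs <- rs[1, ]
  d_ukb <- abs(log(rs$allele_frequency / ukb$allele_frequency))
  d_ice <- abs(log(rs$allele_frequency / ice$allele_frequency))
  chosen <- if (d_ukb <= d_ice) ukb else ice
  dplyr::mutate(chosen,
                decision = sprintf("discordant (p=%.3g): %s closer to region-specific",
                                   p, chosen$cohort),
                p_value = p)
}

#' Assemble the carrier-allele pool of one gene
#'
#' Combines the filtered small-variant and SV alleles of a recessive gene,
#' attaches the NAHR deletion allele(s) of every deletion region containing
#' the gene at the curated region allele frequency (a gene inside two nested
#' deletions receives two deletion alleles), and optionally pads the pool
#' with ten hypothetical alleles representing not-yet-ascertained variants.
#'
#' With the default padding policy (`"of_total"`), the ten hypothetical
#' alleles each carry 1% of the overall burden `S_total = S_observed / 0.9`,
#' so that together they make up exactly 10% of the padded burden. The
#' alternative reading `"of_observed"` gives each 1% of the observed burden.
#'
#' @param gene Gene symbol.
#' @param alleles Carrier-allele tibble (observed alleles of the gene; rows
#'   for other genes are dropped). Duplicated `allele_id`s are collapsed to
#'   the first occurrence.
#' @param nahr_regions Optional region tibble with `region_id`,
#'   `allele_frequency`, `hom_viable` and a `genes` list-column (or
#'   comma-separated `genes` character column).
#' @param padding `"of_total"` (default), `"of_observed"`, or `"none"`.
#' @param n_padding_alleles Number of hypothetical alleles, default 10.
#' @return A carrier pool tibble (see [carrier_pool()]) with attributes
#'   `padding_applied` and `low_confidence` (no observed alleles).
#' @export
assemble_gene_pool <- function(gene, alleles = NULL, nahr_regions = NULL,
                               padding = c("of_total", "of_observed", "none"),
                               n_padding_alleles = 10) {
  padding <- match.arg(padding)
  obs <- if (is.null(alleles)) carrier_pool_rows(character(), character(),
                                                 character(), numeric(), character())
         else tibble::as_tibble(alleles)
  if (nrow(obs) > 0) {
    obs <- obs[is.na(obs$gene) | obs$gene == gene, ]
    obs$gene <- gene
    obs <- dplyr::distinct(obs, .data$allele_id, .keep_all = TRUE)
  }
  if (!is.null(nahr_regions) && nrow(nahr_regions) > 0) {
    containing <- purrr::map_lgl(seq_len(nrow(nahr_regions)), function(i) {
      g <- nahr_regions$genes[[i]]
      if (is.character(g) && length(g) == 1 && grepl(",", g)) {
        g <- strsplit(g, ",")[[1]]
      }
      gene %in% trimws(g)
    })
    reg <- nahr_regions[containing, ]
    if (nrow(reg) > 2) rlang::abort("a gene can lie in at most two nested deletion regions")
    if (nrow(reg) > 0) {
      hv <- if ("hom_viable" %in% names(reg)) reg$hom_viable else FALSE
      del <- tibble::tibble(gene = gene,
                            allele_id = reg$region_id,
                            allele_class = "nahr_del",
                            frequency = reg$allele_frequency,
                            hom_viable = as.logical(hv),
                            source = "prevalence_table")
      obs <- dplyr::bind_rows(obs, del)
    }
  }
  low_confidence <- nrow(obs) == 0
  s_obs <- sum(obs$frequency[obs$allele_class != "hypomorphic"])

  if (padding != "none") {
    s_total <- if (padding == "of_total") s_obs / 0.9 else s_obs
    pad_freq <- 0.01 * s_total
    pad <- tibble::tibble(gene = gene,
                          allele_id = sprintf("%s_hypothetical_%02d", gene,
                                              seq_len(n_padding_alleles)),
                          allele_class = "snv_indel",
                          frequency = pad_freq,
                          hom_viable = FALSE,
                          source = "hypothetical")
    obs <- dplyr::bind_rows(obs, pad)
  }
  pool <- carrier_pool(obs, gene = gene)
  attr(pool, "padding_applied") <- padding != "none"
  attr(pool, "low_confidence") <- low_confidence
  if (low_confidence) {
    rlang::warn(sprintf("gene %s has no observed alleles; padding-only pool flagged low-confidence",
                        gene))
  }
  pool
}

#' Aggregate carrier allele burden of a pool
#'
#' The sum of the unique alleles' population frequencies. Hypomorphic alleles
#' (which do not in themselves cause disease) are excluded, matching the
#' denominator of the Fa statistic.
#'
#' @param pool A carrier pool tibble.
#' @param include_padding Count hypothetical padding alleles, default `TRUE`.
#' @return The summed frequency.
#' @export
carrier_burden <- function(pool, include_padding = TRUE) {
  if (nrow(pool) == 0) return(0)
  pool <- dplyr::distinct(tibble::as_tibble(pool), .data$allele_id,
                          .keep_all = TRUE)
  keep <- pool$allele_class != "hypomorphic"
  if (!include_padding) keep <- keep & pool$source != "hypothetical"
  sum(pool$frequency[keep])
}
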