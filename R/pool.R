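#' Construct a carrier-allele pool
#'
#' A pool is the complete spectrum of pathogenic/carrier alleles segregating at
#' one autosomal recessive locus, the input to the Punnett-square disease
#' model. It is an ordinary tibble with one row per unique allele, so it can be
#' built, filtered and joined with dplyr verbs; `carrier_pool()` only validates
#' and normalises the columns.
#'
#' @param alleles A data frame with at least `allele_id` and `frequency`.
#'   Optional columns (filled with defaults when absent):
#'   * `gene` — gene symbol (default `NA`).
#'   * `allele_class` — one of `"nahr_del"`, `"snv_indel"`, `"sv_lof"`,
#'     `"hypomorphic"` (default `"snv_indel"`).
#'   * `hom_viable` — logical; for an NAHR deletion allele, whether the
#'     homozygous deletion is compatible with live birth (default `FALSE`;
#'     `TRUE` for the 2q13-NPHP1 and 15q13.3 BP4-BP5 deletions).
#'   * `source` — provenance label (default `"unspecified"`).
#' @param gene Optional gene symbol overriding/filling the `gene` column.
#'
#' @return A tibble with columns `gene`, `allele_id`, `allele_class`,
#'   `frequency`, `hom_viable`, `source` (plus any extra input columns),
#'   one row per unique `allele_id`.
#' @export
#' @examples
#' carrier_pool(data.frame(allele_id = c("del", "snv"),
#'                         allele_class = c("nahr_del", "snv_indel"),
#'                         frequency = c(1e-3, 2e-3)), gene = "TOY")
carrier_pool <- function(alleles, gene = NULL) {
  stopifnot(is.data.frame(alleles))
  alleles <- tibble::as_tibble(alleles)
  if (!all(c("allele_id", "frequency") %in% names(alleles))) {
    rlang::abort("pool requires `allele_id` and `frequency` columns")
  }
  if (!"gene" %in% names(alleles)) alleles$gene <- NA_character_
  if (!is.null(gene)) alleles$gene <- gene
  if (!"allele_class" %in% names(alleles)) alleles$allele_class <- "snv_indel"
  if (!"hom_viable" %in% names(alleles)) alleles$hom_viable <- FALSE
  if (!"source" %in% names(alleles)) alleles$source <- "unspecified"

  bad_class <- setdiff(unique(alleles$allele_class), allele_classes())
  if (length(bad_class) > 0) {
    rlang::abort(paste0("unknown allele_class: ", paste(bad_class, collapse = ", ")))
  }
  if (anyNA(alleles$frequency) || any(alleles$frequency < 0 | alleles$frequency > 1)) {
    rlang::abort("allele frequencies must lie in [0, 1]")
  }
  if (anyDuplicated(alleles$allele_id)) {
    rlang::abort("allele_id values must be unique within a pool")
  }
  alleles$hom_viable <- as.logical(alleles$hom_viable) & !is.na(alleles$hom_viable)
  dplyr::relocate(alleles, "gene", "allele_id", "allele_class", "frequency",
                  "hom_viable", "source")
}

allele_classes <- function() c("nahr_del", "snv_indel", "sv_lof", "hypomorphic")

#' Genotype disease model for a recessive locus
#'
#' Encodes how each unordered pair of carrier alleles is classified:
#' `disease`, `not_disease`, or `lethal` (incompatible with live birth, so the
#' genotype contributes neither to affected individuals nor to the conditional
#' disease distribution).
#'
#' The default model is the one used for most recurrent-deletion loci:
#' * NAHR deletion homozygotes are lethal, unless the allele is flagged
#'   `hom_viable` (2q13-NPHP1, 15q13.3 BP4-BP5), in which case they cause
#'   disease;
#' * hypomorphic alleles cause disease only in trans with a loss-of-function
#'   allele, never when homozygous;
#' * all other biallelic combinations cause disease.
#'
#' Setting `lof_lof_lethal = TRUE` selects the RBM8A/TBX6-style compound
#' inheritance model in which biallelic null genotypes (any pair of
#' non-hypomorphic alleles, including the deletion) are lethal, so that only
#' LoF-in-trans-with-hypomorph genotypes present as disease.
#'
#' @param lof_lof_lethal Logical; classify every pair of non-hypomorphic
#'   alleles as lethal rather than disease.
#' @param description Optional label carried in outputs.
#' @return An object of class `disease_model`.
#' @export
disease_model <- function(lof_lof_lethal = FALSE, description = NULL) {
  if (is.null(description)) {
    description <- if (lof_lof_lethal) "hypomorph-required (biallelic null lethal)" else "standard"
  }
  structure(list(lof_lof_lethal = lof_lof_lethal, description = description),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat("<disease_model>", x$description, "\n")
  invisible(x)
}

as_disease_model <- function(model) {
  if (is.null(model)) return(disease_model())
  if (!inherits(model, "disease_model")) rlang::abort("`model` must be a disease_model()")
  model
}

# Per-allele helper flags used by both the closed forms and the brute-force
# enumeration. A diagonal (homozygous) cell is lethal for a non-viable NAHR
# deletion and, under the biallelic-null-lethal model, for every
# non-hypomorphic allele.
pool_flags <- function(pool, model) {
  hyp <- pool$allele_class == "hypomorphic"
  lethal_diag <- !hyp & ((pool$allele_class == "nahr_del" & !pool$hom_viable) |
                           model$lof_lof_lethal)
  list(hyp = hyp, lethal_diag = lethal_diag)
}
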