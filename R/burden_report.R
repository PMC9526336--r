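#' Full burden report for one gene
#'
#' Runs the complete Punnett-square analysis for one carrier pool: per-allele
#' Fa, Fd and odds, the disease probability P(D), the NAHR deletion Fd (union
#' event over nested deletions), NIRD, per-allele AIRD, and the
#' significant-burden classification.
#'
#' @inheritParams brute_force_punnett
#' @param population Label attached to the report (e.g. `"general"`, `"AFR"`).
#' @param aird Logical; also compute the AIRD score for every allele (requires
#'   one median selection per allele, so can be disabled for large pools).
#' @param significance_threshold Strict Fd threshold for the significant-burden
#'   call, default 0.20.
#' @return An object of class `burden_report`; see [tidy.burden_report()] and
#'   [glance.burden_report()] for tabular views.
#' @export
#' @examples
#' pool <- carrier_pool(data.frame(
#'   allele_id = c("del", "a", "b"),
#'   allele_class = c("nahr_del", "snv_indel", "snv_indel"),
#'   frequency = c(1e-3, 4e-4, 1e-4)), gene = "TOY")
#' rep <- burden_report(pool)
#' glance(rep)
burden_report <- function(pool, model = NULL, population = "general",
                          aird = TRUE, significance_threshold = 0.20) {
  model <- as_disease_model(model)
  pool <- carrier_pool(pool)
  fd <- all_fd(pool, model)
  pd <- disease_probability(pool, model)
  fa <- vapply(pool$allele_id, function(id) fraction_of_allele_burden(pool, id),
               numeric(1))
  fd_sum <- sum(fd)
  odds <- ifelse(fd_sum - fd > 0, fd / (fd_sum - fd), NA_real_)

  alleles <- tibble::tibble(
    gene = pool$gene,
    allele_id = pool$allele_id,
    allele_class = pool$allele_class,
    frequency = pool$frequency,
    fa = unname(fa),
    fd = unname(fd),
    odds = unname(odds)
  )
  if (aird && nrow(pool) >= 2) {
    alleles$aird <- vapply(pool$allele_id, function(id) {
      tryCatch(aird_score(pool, id, model), error = function(e) NA_real_)
    }, numeric(1))
  }

  nahr_ids <- pool$allele_id[pool$allele_class == "nahr_del"]
  nird <- fd_nahr <- NA_real_
  median_allele_id <- NA_character_
  if (length(nahr_ids) > 0) {
    fd_nahr <- union_disease_intersection(pool, nahr_ids, model) / pd
    sc <- tryCatch(impact_score(pool, nahr_ids, model), error = function(e) NULL)
    if (!is.null(sc)) {
      nird <- sc$score
      median_allele_id <- sc$median_allele_id
    }
  }

  structure(list(
    gene = pool$gene[1],
    population = population,
    model = model,
    alleles = alleles,
    p_disease = pd,
    nahr_ids = nahr_ids,
    fd_nahr = fd_nahr,
    nird = nird,
    median_allele_id = median_allele_id,
    significant_nahr_burden = isTRUE(classify_significant_burden(
      fd_nahr, significance_threshold))
  ), class = "burden_report")
}

#' @export
print.burden_report <- function(x, ...) {
  cat("<burden_report>", x$gene, "(", x$population, ")\n")
  cat("  alleles:", nrow(x$alleles), " P(D):", format(x$p_disease, digits = 4), "\n")
  if (length(x$nahr_ids) > 0) {
    cat("  NAHR Fd:", sprintf("%.3f", x$fd_nahr),
        " NIRD:", sprintf("%.2f", x$nird),
        " significant burden:", x$significant_nahr_burden, "\n")
  }
  invisible(x)
}

#' Tidy a burden report into a per-allele tibble
#'
#' @param x A [burden_report()].
#' @param ... Unused.
#' @return A tibble with one row per allele: gene, allele_id, allele_class,
#'   frequency, `fa`, `fd`, `odds` and (when computed) `aird`.
#' @exportS3Method generics::tidy
tidy.burden_report <- function(x, ...) {
  dplyr::arrange(x$alleles, dplyr::desc(.data$fd))
}

#' One-row summary of a burden report
#'
#' @param x A [burden_report()].
#' @param ... Unused.
#' @return A one-row tibble: gene, population, n_alleles, aggregate carrier
#'   burden, P(D), NAHR Fd (as fraction and integer percent, rounded
#'   half-away-from-zero to match conventional table formatting), NIRD, the
#'   median reference allele and the significant-burden flag.
#' @exportS3Method generics::glance
glance.burden_report <- function(x, ...) {
  tibble::tibble(
    gene = x$gene,
    population = x$population,
    n_alleles = nrow(x$alleles),
    aggregate_burden = sum(x$alleles$frequency[x$alleles$allele_class != "hypomorphic"]),
    p_disease = x$p_disease,
    fd_nahr = x$fd_nahr,
    fd_nahr_percent = percent_round(x$fd_nahr),
    nird = x$nird,
    median_allele_id = x$median_allele_id,
    significant_nahr_burden = x$significant_nahr_burden
  )
}

#' Round a fraction to integer percent, half away from zero
#'
#' `round()` in R rounds half to even; published percentage tables round half
#' away from zero, so 0.975 prints as 98, not 97.
#'
#' @param x Fraction(s) in `[0, 1]` (or `NA`).
#' @return Integer percent value(s).
#' @export
percent_round <- function(x) {
  # tiny epsilon so exact halves stored inexactly in binary still round up
  sign(x) * floor(abs(x) * 100 + 0.5 + sqrt(.Machine$double.eps))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot the allelic architecture of a burden report
#'
#' Bar chart of per-allele Fd (fraction of affected individuals carrying each
#' allele), NAHR deletion alleles highlighted.
#'
#' @param object A [burden_report()].
#' @param top_n Show at most this many alleles by descending Fd.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.burden_report <- function(object, top_n = 20, ...) {
  df <- dplyr::slice_max(tidy(object), .data$fd, n = top_n)
  df$allele_id <- stats::reorder(df$allele_id, df$fd)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fd, y = .data$allele_id,
                                   fill = .data$allele_class == "nahr_del")) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey55"),
                               labels = c(`TRUE` = "NAHR deletion", `FALSE` = "other"),
                               name = NULL) +
    ggplot2::labs(x = "Fd (fraction of affected individuals carrying allele)",
                  y = NULL,
                  title = paste0(object$gene, " allelic architecture (",
                                 object$population, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of population-specific delta-NIRD scores
#'
#' @param delta_tbl A tibble with columns `gene`, `population`, `delta_nird`,
#'   e.g. the output of mapping [delta_nird()] over population-specific pools.
#' @return A ggplot heatmap (genes by populations).
#' @export
plot_delta_nird <- function(delta_tbl) {
  stopifnot(all(c("gene", "population", "delta_nird") %in% names(delta_tbl)))
  ggplot2::ggplot(delta_tbl,
                  ggplot2::aes(x = .data$population, y = .data$gene,
                               fill = .data$delta_nird)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  midpoint = 0, name = expression(Delta * "NIRD")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
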