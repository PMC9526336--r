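#' Read a segmental-duplication annotation table
#'
#' Reads a genomicSuperDups-style tab-separated table into the internal
#' per-record form: each row describes one repeat copy and its partner copy.
#' Both the compact dialect (`chrom start end other_chrom other_start
#' other_end strand frac_match`) and UCSC genomicSuperDups column names
#' (`chrom chromStart chromEnd strand otherChrom otherStart otherEnd
#' fracMatch`) are accepted; coordinates are kept 0-based half-open
#' throughout.
#'
#' The strand column gives the orientation of the partner copy relative to
#' this copy: `"+"` means the pair is directly oriented (the NAHR deletion
#' substrate), `"-"` inverted.
#'
#' @param path Path to a TSV file with a header row.
#' @param genome_build Label recorded as an attribute (e.g. `"GRCh38"`).
#' @return A tibble with columns `chrom`, `start`, `end`, `other_chrom`,
#'   `other_start`, `other_end`, `orientation` (`"direct"`/`"inverted"`),
#'   `frac_match`.
#' @export
read_segdup <- function(path, genome_build = "GRCh38") {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  ucsc <- c(chromStart = "start", chromEnd = "end", otherChrom = "other_chrom",
            otherStart = "other_start", otherEnd = "other_end",
            fracMatch = "frac_match")
  for (nm in names(ucsc)) {
    if (nm %in% names(raw)) names(raw)[names(raw) == nm] <- ucsc[[nm]]
  }
  needed <- c("chrom", "start", "end", "other_chrom", "other_start",
              "other_end", "strand", "frac_match")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("segdup table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  raw <- raw[needed]
  num_cols <- c("start", "end", "other_start", "other_end", "frac_match")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !is.na(raw[[cc]]))
    if (length(bad) > 0 || anyNA(v)) {
      line <- if (length(bad) > 0) bad[1] else which(is.na(v))[1]
      rlang::abort(sprintf("segdup parse error: non-numeric `%s` at data line %d",
                           cc, line))
    }
    raw[[cc]] <- v
  }
  bad <- which(raw$start >= raw$end | raw$other_start >= raw$other_end)
  if (length(bad) > 0) {
    rlang::abort(sprintf("segdup parse error: start >= end at data line %d", bad[1]))
  }
  bad <- which(!raw$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    rlang::abort(sprintf("segdup parse error: unknown strand '%s' at data line %d",
                         raw$strand[bad[1]], bad[1]))
  }
  bad <- which(raw$frac_match < 0 | raw$frac_match > 1)
  if (length(bad) > 0) {
    rlang::abort(sprintf("segdup parse error: frac_match outside [0,1] at data line %d",
                         bad[1]))
  }
  out <- tibble::tibble(
    chrom = as.character(raw$chrom),
    start = as.integer(raw$start), end = as.integer(raw$end),
    other_chrom = as.character(raw$other_chrom),
    other_start = as.integer(raw$other_start),
    other_end = as.integer(raw$other_end),
    orientation = ifelse(raw$strand == "+", "direct", "inverted"),
    frac_match = raw$frac_match
  )
  attr(out, "genome_build") <- genome_build
  out
}

#' Candidate-pair selection criteria
#'
#' Thresholds defining which directly oriented repeat pairs are plausible NAHR
#' deletion substrates. Defaults are the canonical NAHR-substrate criteria:
#' repeats of at least 10 kb at >= 95% sequence identity, separated by 50 kb
#' to 10 Mb.
#'
#' @param min_repeat_length Minimum length of the shorter repeat copy (bp).
#' @param min_identity Minimum sequence identity fraction.
#' @param min_distance,max_distance Bounds on the inter-repeat (inner-edge)
#'   distance in bp.
#' @return A list of class `pair_criteria`.
#' @export
pair_criteria <- function(min_repeat_length = 10e3, min_identity = 0.95,
                          min_distance = 50e3, max_distance = 10e6) {
  structure(list(min_repeat_length = min_repeat_length,
                 min_identity = min_identity,
                 min_distance = min_distance,
                 max_distance = max_distance),
            class = "pair_criteria")
}

#' Enumerate candidate NAHR deletion substrates
#'
#' Filters a segmental-duplication table down to same-chromosome, directly
#' oriented, non-overlapping repeat pairs passing the [pair_criteria()]
#' thresholds. The predicted deletion interval spans the inner edges of the
#' two repeats. Palindromic duplicate rows (the same pair listed from each
#' copy) are collapsed.
#'
#' @param records Output of [read_segdup()] (or an equivalent tibble).
#' @param criteria A [pair_criteria()].
#' @return A tibble of candidate pairs sorted by (`chrom`, `del_start`):
#'   `chrom`, `proximal_start/end`, `distal_start/end`, `del_start`,
#'   `del_end`, `repeat_length_min`, `inter_repeat_distance`, `identity`.
#' @export
enumerate_candidate_pairs <- function(records, criteria = pair_criteria()) {
  stopifnot(inherits(criteria, "pair_criteria"))
  records <- tibble::as_tibble(records)
  if (!"orientation" %in% names(records) && "strand" %in% names(records)) {
    records$orientation <- ifelse(records$strand == "+", "direct", "inverted")
  }
  if (nrow(records) == 0) return(empty_pairs())

  cand <- dplyr::filter(records,
                        .data$orientation == "direct",
                        .data$chrom == .data$other_chrom)
  if (nrow(cand) == 0) return(empty_pairs())

  prox_first <- cand$start <= cand$other_start
  pairs <- tibble::tibble(
    chrom = cand$chrom,
    proximal_start = ifelse(prox_first, cand$start, cand$other_start),
    proximal_end = ifelse(prox_first, cand$end, cand$other_end),
    distal_start = ifelse(prox_first, cand$other_start, cand$start),
    distal_end = ifelse(prox_first, cand$other_end, cand$end),
    identity = cand$frac_match
  )
  pairs <- dplyr::mutate(
    pairs,
    repeat_length_min = pmin(.data$proximal_end - .data$proximal_start,
                             .data$distal_end - .data$distal_start),
    inter_repeat_distance = .data$distal_start - .data$proximal_end,
    del_start = .data$proximal_end,
    del_end = .data$distal_start
  )
  pairs <- dplyr::filter(
    pairs,
    .data$proximal_end <= .data$distal_start,  # overlapping copies are not a substrate
    .data$repeat_length_min >= criteria$min_repeat_length,
    .data$identity >= criteria$min_identity,
    .data$inter_repeat_distance >= criteria$min_distance,
    .data$inter_repeat_distance <= criteria$max_distance
  )
  pairs <- dplyr::distinct(
    pairs, .data$chrom, .data$proximal_start, .data$proximal_end,
    .data$distal_start, .data$distal_end, .keep_all = TRUE)
  pairs <- dplyr::arrange(pairs, .data$chrom, .data$del_start, .data$del_end)
  dplyr::relocate(pairs, "chrom", "proximal_start", "proximal_end",
                  "distal_start", "distal_end", "del_start", "del_end",
                  "repeat_length_min", "inter_repeat_distance", "identity")
}

empty_pairs <- function() {
  tibble::tibble(chrom = character(), proximal_start = numeric(),
                 proximal_end = numeric(), distal_start = numeric(),
                 distal_end = numeric(), del_start = numeric(),
                 del_end = numeric(), repeat_length_min = numeric(),
                 inter_repeat_distance = numeric(), identity = numeric())
}

#' Weighted-average breakpoints of a pair cluster
#'
#' The merged region's coordinates are the weighted mean of the member pairs'
#' deletion intervals, with weight `repeat_length_min * identity`: longer and
#' more identical repeat pairs mediate more events, so their interval
#' dominates the average. The result is not a precise prediction for any
#' single deletion but the average over all deletion types collapsed into the
#' merged region.
#'
#' @param cluster Tibble of candidate pairs (one cluster).
#' @return Named numeric vector `c(start, end)`, rounded to integer bases.
#' @export
weighted_breakpoints <- function(cluster) {
  if (nrow(cluster) == 0) rlang::abort("empty cluster")
  w <- cluster$repeat_length_min * cluster$identity
  if (all(w == 0)) w <- rep(1, nrow(cluster))
  c(start = round(stats::weighted.mean(cluster$del_start, w)),
    end = round(stats::weighted.mean(cluster$del_end, w)))
}

#' Merge candidate pairs into recurrent-deletion regions
#'
#' Different repeat pairs can mediate deletions of essentially the same
#' genomic interval; such pairs are clustered (single linkage: transitive
#' closure over pairwise reciprocal overlap of the deletion intervals at or
#' above `overlap_fraction`) and each cluster is reduced to one region with
#' weighted-average breakpoints.
#'
#' @param pairs Output of [enumerate_candidate_pairs()].
#' @param overlap_fraction Reciprocal-overlap threshold in (0, 1], default 0.5.
#' @return A tibble of regions: `region_id`, `chrom`, `start`, `end`,
#'   `n_pairs`, `relative_prevalence_score`, `sex_chromosome`, `manual_patch`,
#'   and a `pairs` list-column holding the member pairs. Every input pair
#'   belongs to exactly one region.
#' @export
merge_pairs_to_regions <- function(pairs, overlap_fraction = 0.5) {
  stopifnot(overlap_fraction > 0, overlap_fraction <= 1)
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(region_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_pairs = integer(),
                          relative_prevalence_score = numeric(),
                          sex_chromosome = logical(), manual_patch = logical(),
                          pairs = list()))
  }
  comp <- dplyr::mutate(pairs, .component = cluster_components(pairs, overlap_fraction))
  regions <- comp |>
    dplyr::group_by(.data$.component) |>
    dplyr::group_map(function(df, key) {
      bp <- weighted_breakpoints(df)
      tibble::tibble(
        chrom = df$chrom[1],
        start = bp[["start"]], end = bp[["end"]],
        n_pairs = nrow(df),
        relative_prevalence_score = relative_prevalence_score(df),
        pairs = list(df)
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
  regions$region_id <- sprintf("nahr_%s_%d_%d", regions$chrom,
                               regions$start, regions$end)
  regions$sex_chromosome <- grepl("^(chr)?[XY]$", regions$chrom)
  regions$manual_patch <- FALSE
  dplyr::relocate(regions, "region_id", "chrom", "start", "end", "n_pairs",
                  "relative_prevalence_score", "sex_chromosome", "manual_patch")
}

# connected components of the reciprocal-overlap graph, via igraph
cluster_components <- function(pairs, overlap_fraction) {
  n <- nrow(pairs)
  if (n == 1) return(1L)
  edges <- integer(0)
  ord <- order(pairs$chrom, pairs$del_start)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in seq((a + 1), n)) {
      j <- ord[b]
      if (pairs$chrom[i] != pairs$chrom[j]) break
      if (pairs$del_start[j] >= pairs$del_end[i]) break
      if (reciprocal_overlap(pairs$del_start[i], pairs$del_end[i],
                             pairs$del_start[j], pairs$del_end[j]) >=
          overlap_fraction) {
        edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  as.integer(igraph::components(g)$membership)
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  if (ov == 0) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Relative-prevalence score of a region
#'
#' A unitless heuristic summarising how active an NAHR substrate is expected
#' to be: the per-pair score `repeat_length_min * identity /
#' inter_repeat_distance` (longer, more identical, closer repeat pairs
#' recombine more often), summed over member pairs. The score is used only to
#' rank regions; empirical cohort prevalences, not this score, enter the
#' burden model.
#'
#' @param cluster Tibble of member pairs of one region.
#' @return A single nonnegative score.
#' @export
relative_prevalence_score <- function(cluster) {
  if (nrow(cluster) == 0) return(0)
  sum(cluster$repeat_length_min * cluster$identity /
        pmax(cluster$inter_repeat_distance, 1))
}

#' Annotate regions with gene content and pLI counts
#'
#' Attaches the genes overlapping each region's breakpoint interval, counting
#' coding genes and those intolerant to haploinsufficiency (pLI above the
#' threshold). Genes with a missing pLI are counted as not-high.
#'
#' @param regions Output of [merge_pairs_to_regions()].
#' @param genes Gene annotation tibble with columns `gene`, `chrom`, `start`,
#'   `end` and `pli`.
#' @param pli_threshold Strict pLI threshold for the high-pLI count,
#'   default 0.9.
#' @return `regions` with added columns `genes` (list of overlapping gene
#'   symbols), `n_coding_genes`, `n_high_pli_genes`.
#' @export
annotate_regions <- function(regions, genes, pli_threshold = 0.9) {
  stopifnot(all(c("gene", "chrom", "start", "end", "pli") %in% names(genes)))
  ann <- purrr::pmap(list(regions$chrom, regions$start, regions$end),
                     function(ch, s, e) {
    hit <- genes[genes$chrom == ch & genes$start < e & genes$end > s, ]
    list(genes = hit$gene,
         n_coding = nrow(hit),
         n_high_pli = sum(!is.na(hit$pli) & hit$pli > pli_threshold))
  })
  regions$genes <- purrr::map(ann, "genes")
  regions$n_coding_genes <- purrr::map_int(ann, ~ as.integer(.x$n_coding))
  regions$n_high_pli_genes <- purrr::map_int(ann, ~ as.integer(.x$n_high_pli))
  regions
}

#' Patch manually curated regions into a map
#'
#' Recurrent deletions occurring only on alternative haplotypes (the
#' 17q21.31 deletion is the known case: its substrate is represented only on
#' an alt contig) cannot be recovered from the reference segdup track and are
#' appended from a hand-curated patch table, flagged `manual_patch`.
#'
#' @param regions A region tibble.
#' @param patch A tibble with `region_id`, `chrom`, `start`, `end` and
#'   optionally `replace` (logical) and `genes` columns, or a path to such a
#'   TSV file.
#' @return The region tibble with patch rows appended; a patch row whose
#'   `region_id` collides with an existing region replaces it only when its
#'   `replace` flag is set, otherwise an error is raised.
#' @export
patch_alt_haplotype_regions <- function(regions, patch) {
  if (is.character(patch)) {
    patch <- readr::read_tsv(patch, show_col_types = FALSE, progress = FALSE)
  }
  patch <- tibble::as_tibble(patch)
  if (nrow(patch) == 0) return(regions)
  if (!"replace" %in% names(patch)) patch$replace <- FALSE
  patch$replace[is.na(patch$replace)] <- FALSE

  clash <- patch$region_id %in% regions$region_id
  if (any(clash & !patch$replace)) {
    rlang::abort(paste0("patch region id already present (set `replace`): ",
                        paste(patch$region_id[clash & !patch$replace],
                              collapse = ", ")))
  }
  regions <- regions[!regions$region_id %in% patch$region_id[clash], ]
  add <- tibble::tibble(
    region_id = patch$region_id,
    chrom = as.character(patch$chrom),
    start = as.numeric(patch$start), end = as.numeric(patch$end),
    n_pairs = 0L,
    relative_prevalence_score = NA_real_,
    sex_chromosome = grepl("^(chr)?[XY]$", patch$chrom),
    manual_patch = TRUE,
    pairs = replicate(nrow(patch), empty_pairs(), simplify = FALSE)
  )
  extra <- intersect(names(regions), names(patch))
  extra <- setdiff(extra, names(add))
  for (cc in extra) add[[cc]] <- patch[[cc]]
  out <- dplyr::bind_rows(regions, add)
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' Build an NAHR recurrent-deletion map in one call
#'
#' Convenience pipeline: [read_segdup()] (when given a path) ->
#' [enumerate_candidate_pairs()] -> [merge_pairs_to_regions()], optionally
#' annotated and patched. Deterministic: identical inputs and criteria give an
#' identical map.
#'
#' @param segdup A segdup tibble or path to a segdup TSV.
#' @param criteria A [pair_criteria()].
#' @param overlap_fraction Reciprocal-overlap clustering threshold.
#' @param genes Optional gene annotation for [annotate_regions()].
#' @param patch Optional patch table for [patch_alt_haplotype_regions()].
#' @return A region tibble.
#' @export
build_nahr_map <- function(segdup, criteria = pair_criteria(),
                           overlap_fraction = 0.5, genes = NULL, patch = NULL) {
  if (is.character(segdup)) segdup <- read_segdup(segdup)
  pairs <- enumerate_candidate_pairs(segdup, criteria)
  regions <- merge_pairs_to_regions(pairs, overlap_fraction)
  if (!is.null(genes)) regions <- annotate_regions(regions, genes)
  if (!is.null(patch)) regions <- patch_alt_haplotype_regions(regions, patch)
  regions
}

#' Write a region map as BED plus a metrics sidecar
#'
#' @param regions A region tibble.
#' @param out_prefix Output path prefix; writes `<prefix>.bed` (0-based
#'   half-open: chrom, start, end, region_id) and `<prefix>.metrics.tsv`.
#' @return Invisibly, the two file paths.
#' @export
write_nahr_map <- function(regions, out_prefix) {
  bed <- dplyr::select(regions, "chrom", "start", "end", "region_id")
  bed_path <- paste0(out_prefix, ".bed")
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  metrics <- dplyr::select(regions, -dplyr::any_of(c("pairs", "genes")))
  if ("genes" %in% names(regions)) {
    metrics$genes <- purrr::map_chr(regions$genes, paste, collapse = ",")
  }
  tsv_path <- paste0(out_prefix, ".metrics.tsv")
  readr::write_tsv(metrics, tsv_path)
  invisible(c(bed = bed_path, metrics = tsv_path))
}
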