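#' Punnett-square enumeration of biallelic genotypes
#'
#' Builds the explicit n-by-n genotype matrix for a carrier-allele pool under
#' random mating: cell (i, j) has probability p_i * p_j and a disease status
#' from the genotype model. This is the enumeration the closed-form quantities
#' summarise, and it serves as the equivalence oracle for them in the test
#' suite.
#'
#' @param pool A carrier-allele pool, see [carrier_pool()].
#' @param model A [disease_model()]; `NULL` selects the default model.
#' @return A list with elements `prob` (n-by-n numeric matrix of genotype
#'   probabilities, dimnames = allele ids), `status` (matching character matrix
#'   with values `"disease"`, `"not_disease"`, `"lethal"`), and `p_disease`
#'   (the total disease mass).
#' @export
brute_force_punnett <- function(pool, model = NULL) {
  model <- as_disease_model(model)
  pool <- carrier_pool(pool)
  n <- nrow(pool)
  p <- pool$frequency
  fl <- pool_flags(pool, model)

  prob <- outer(p, p)
  status <- matrix("disease", n, n)
  # off-diagonal rules
  both_hyp <- outer(fl$hyp, fl$hyp, `&`)
  status[both_hyp] <- "not_disease"
  if (model$lof_lof_lethal) {
    both_lof <- outer(!fl$hyp, !fl$hyp, `&`)
    status[both_lof] <- "lethal"
  }
  # diagonal rules override
  diag_status <- ifelse(fl$hyp, "not_disease",
                        ifelse(fl$lethal_diag, "lethal", "disease"))
  diag(status) <- diag_status
  dimnames(prob) <- dimnames(status) <- list(pool$allele_id, pool$allele_id)
  list(prob = prob, status = status,
       p_disease = sum(prob[status == "disease"]))
}

# shared closed-form ingredients
pool_sums <- function(pool, model) {
  fl <- pool_flags(pool, model)
  p <- pool$frequency
  list(S = sum(p[!fl$hyp]), S_h = sum(p[fl$hyp]),
       lethal_sq = sum(p[fl$lethal_diag]^2), flags = fl)
}

#' Fraction of the carrier allele burden (Fa)
#'
#' The share of a gene's summed carrier-allele frequency contributed by one
#' allele: `Fa_k = p_k / sum(p_i)`, where the denominator runs over the
#' functional (non-hypomorphic) alleles. Hypomorphic alleles, which do not in
#' themselves cause disease, are excluded from the denominator and receive
#' `NA`.
#'
#' @inheritParams brute_force_punnett
#' @param allele_id Focal allele identifier present in the pool.
#' @return A single fraction in `[0, 1]` (or `NA` for a hypomorphic focal
#'   allele).
#' @export
fraction_of_allele_burden <- function(pool, allele_id) {
  pool <- carrier_pool(pool)
  idx <- match_allele(pool, allele_id)
  hyp <- pool$allele_class == "hypomorphic"
  S <- sum(pool$frequency[!hyp])
  if (S <= 0) rlang::abort("pool has zero non-hypomorphic allele burden")
  if (hyp[idx]) return(NA_real_)
  pool$frequency[idx] / S
}

match_allele <- function(pool, allele_id) {
  idx <- match(allele_id, pool$allele_id)
  if (anyNA(idx)) {
    rlang::abort(paste0("allele not in pool: ",
                        paste(allele_id[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Probability of being affected, P(D)
#'
#' Total mass of viable disease genotypes in the Punnett square. Under the
#' default model this is `S^2` minus the squared frequencies of lethal
#' homozygotes (the NAHR deletion unless homozygous-viable), plus the cross
#' terms between hypomorphic and LoF alleles when hypomorphs are present.
#' Under the biallelic-null-lethal model only LoF-by-hypomorph genotypes
#' remain: `P(D) = 2 * S * S_h`.
#'
#' @inheritParams brute_force_punnett
#' @return A probability.
#' @export
disease_probability <- function(pool, model = NULL) {
  model <- as_disease_model(model)
  pool <- carrier_pool(pool)
  ps <- pool_sums(pool, model)
  pd <- if (model$lof_lof_lethal) {
    2 * ps$S * ps$S_h
  } else {
    ps$S^2 - ps$lethal_sq + 2 * ps$S * ps$S_h
  }
  if (pd < -1e-15) rlang::abort("internal error: negative disease probability")
  max(pd, 0)
}

#' Probability of being affected and carrying an allele, P(Ak & D)
#'
#' Mass of viable disease genotypes that include the focal allele. For a
#' lethal-homozygote allele this is `2*p_k*S - 2*p_k^2`; for a
#' viable-homozygote disease allele the homozygous cell is counted once,
#' `2*p_k*S - p_k^2`; for a hypomorphic allele only the LoF-in-trans cells
#' count, `2*p_h*S`.
#'
#' @inheritParams fraction_of_allele_burden
#' @param model A [disease_model()].
#' @return A probability.
#' @export
allele_disease_intersection <- function(pool, allele_id, model = NULL) {
  model <- as_disease_model(model)
  pool <- carrier_pool(pool)
  idx <- match_allele(pool, allele_id)
  ps <- pool_sums(pool, model)
  p_k <- pool$frequency[idx]
  if (ps$flags$hyp[idx]) return(2 * p_k * ps$S)
  if (model$lof_lof_lethal) return(2 * p_k * ps$S_h)
  base <- 2 * p_k * ps$S + 2 * p_k * ps$S_h
  if (ps$flags$lethal_diag[idx]) base - 2 * p_k^2 else base - p_k^2
}

# disease mass of the single cell pairing two distinct alleles (for
# inclusion-exclusion over a union of focal alleles)
pair_disease_mass <- function(pool, i, j, model) {
  fl <- pool_flags(pool, model)
  if (fl$hyp[i] && fl$hyp[j]) return(0)
  if (model$lof_lof_lethal && !fl$hyp[i] && !fl$hyp[j]) return(0)
  2 * pool$frequency[i] * pool$frequency[j]
}

union_disease_intersection <- function(pool, allele_ids, model) {
  idx <- match_allele(pool, allele_ids)
  total <- sum(vapply(allele_ids, allele_disease_intersection,
                      numeric(1), pool = pool, model = model))
  if (length(idx) > 1) {
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq((a + 1), length(idx))) {
        total <- total - pair_disease_mass(pool, idx[a], idx[b], model)
      }
    }
  }
  total
}

#' Fraction of the disease burden (Fd)
#'
#' The probability that an affected individual carries the focal allele:
#' `Fd_k = P(Ak | D) = P(Ak & D) / P(D)`. Note that Fd summed over alleles
#' exceeds 1 whenever compound heterozygotes exist, because the carrying
#' events of the two alleles of a compound heterozygote overlap.
#'
#' @inheritParams allele_disease_intersection
#' @return A fraction in `[0, 1]`.
#' @export
fraction_of_disease_burden <- function(pool, allele_id, model = NULL) {
  pd <- disease_probability(pool, model)
  if (pd <= 0) rlang::abort("no viable disease genotype: P(D) = 0")
  allele_disease_intersection(pool, allele_id, model) / pd
}

all_fd <- function(pool, model) {
  pd <- disease_probability(pool, model)
  if (pd <= 0) rlang::abort("no viable disease genotype: P(D) = 0")
  vapply(pool$allele_id, function(id) {
    allele_disease_intersection(pool, id, model)
  }, numeric(1)) / pd
}

#' Odds that an affected individual carries an allele
#'
#' `O_k = Fd_k / (sum_i Fd_i - Fd_k)`: the focal allele's share of disease
#' burden against the combined share of all other alleles of the gene.
#'
#' @inheritParams allele_disease_intersection
#' @return A nonnegative real number.
#' @export
allele_odds <- function(pool, allele_id, model = NULL) {
  model <- as_disease_model(model)
  pool <- carrier_pool(pool)
  fd <- all_fd(pool, model)
  idx <- match_allele(pool, allele_id)
  denom <- sum(fd) - fd[idx]
  if (denom <= 0) rlang::abort("degenerate pool: no competing disease burden")
  unname(fd[idx] / denom)
}

#' Median-contribution allele selection
#'
#' Given the Fd values of the alleles competing with a focal allele, the
#' reference allele is the midpoint of the alleles that make up the top 90% of
#' the competing Fd sum: alleles are sorted by decreasing Fd, the prefix is
#' grown until its cumulative Fd first reaches 90% of the total (discarding
#' the long tail of ultra-rare and hypothetical alleles in the bottom 10%),
#' and the allele at position `ceiling(m/2)` of the prefix is returned. Ties
#' in Fd are broken by lexicographic allele id.
#'
#' @inheritParams brute_force_punnett
#' @param exclude_allele_id Allele id(s) to exclude (the focal allele or the
#'   set of NAHR deletion alleles).
#' @return The selected allele id.
#' @export
select_median_allele <- function(pool, exclude_allele_id, model = NULL) {
  model <- as_disease_model(model)
  pool <- carrier_pool(pool)
  fd <- all_fd(pool, model)
  keep <- !(pool$allele_id %in% exclude_allele_id)
  if (!any(keep)) rlang::abort("no remaining alleles to select a median from")
  tbl <- tibble::tibble(allele_id = pool$allele_id[keep], fd = unname(fd[keep]))
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$fd), .data$allele_id)
  total <- sum(tbl$fd)
  if (total <= 0) rlang::abort("remaining alleles carry no disease burden")
  m <- which(cumsum(tbl$fd) >= 0.9 * total - 1e-15)[1]
  tbl$allele_id[ceiling(m / 2)]
}

# Shared engine for NIRD and AIRD: odds of the focal event (single allele or
# union of NAHR alleles) against the odds of the median remaining allele.
impact_score <- function(pool, focal_ids, model) {
  model <- as_disease_model(model)
  pool <- carrier_pool(pool)
  fd <- all_fd(pool, model)
  focal_idx <- match_allele(pool, focal_ids)
  pd <- disease_probability(pool, model)
  fd_focal <- union_disease_intersection(pool, focal_ids, model) / pd
  rest <- setdiff(seq_len(nrow(pool)), focal_idx)
  denom <- sum(fd[rest])
  if (denom <= 0) rlang::abort("degenerate pool: no competing disease burden")
  o_focal <- fd_focal / denom

  med_id <- select_median_allele(pool, exclude_allele_id = focal_ids, model = model)
  med_idx <- match_allele(pool, med_id)
  o_med <- fd[med_idx] / (sum(fd) - fd[med_idx])
  if (o_med <= 0) {
    rlang::abort("median allele has zero odds; impact score undefined")
  }
  list(score = unname(log2(o_focal / o_med)), o_focal = unname(o_focal),
       o_median = unname(o_med), median_allele_id = med_id,
       fd_focal = unname(fd_focal))
}

#' NAHR deletion Impact to Recessive Disease (NIRD)
#'
#' Log2 ratio of the NAHR deletion allele's odds of being carried by an
#' affected individual to the odds of the median-contribution allele of the
#' same gene. When a gene lies inside two nested recurrent deletions, the
#' focal event is "carries at least one NAHR deletion allele"
#' (inclusion-exclusion union over the deletion alleles).
#'
#' A positive NIRD predicts the deletion plays an above-typical role among the
#' gene's carrier alleles; a negative NIRD, a below-typical role.
#'
#' @inheritParams brute_force_punnett
#' @param nahr_ids Allele ids of the NAHR deletion allele(s); defaults to all
#'   alleles of class `"nahr_del"`.
#' @return A single numeric score (log2 odds ratio).
#' @export
nird_score <- function(pool, model = NULL, nahr_ids = NULL) {
  pool <- carrier_pool(pool)
  if (is.null(nahr_ids)) nahr_ids <- pool$allele_id[pool$allele_class == "nahr_del"]
  if (length(nahr_ids) == 0) rlang::abort("pool contains no NAHR deletion allele")
  impact_score(pool, nahr_ids, model)$score
}

#' Allelic Impact to Recessive Disease (AIRD)
#'
#' The NIRD construction applied to an arbitrary focal allele: log2 ratio of
#' the focal allele's odds to the median remaining allele's odds. For the NAHR
#' deletion allele itself, AIRD coincides with NIRD.
#'
#' @inheritParams fraction_of_allele_burden
#' @param model A [disease_model()].
#' @return A single numeric score (log2 odds ratio).
#' @export
aird_score <- function(pool, allele_id, model = NULL) {
  if (length(allele_id) != 1) rlang::abort("AIRD takes a single focal allele")
  impact_score(carrier_pool(pool), allele_id, model)$score
}

#' Population-specific NIRD difference
#'
#' `delta_nird = NIRD(population pool) - NIRD(general pool)` for the same gene
#' and the same deletion allele frequency; positive values indicate an even
#' higher deletion contribution to recessive disease in that population.
#'
#' @param pool_population,pool_general Carrier pools sharing the gene and the
#'   NAHR deletion frequency, differing in small-variant frequencies.
#' @param model A [disease_model()].
#' @return A single numeric score.
#' @export
delta_nird <- function(pool_population, pool_general, model = NULL) {
  nird_score(pool_population, model) - nird_score(pool_general, model)
}

#' Classify a gene as under significant NAHR deletion burden
#'
#' A gene is classified as under significant deletion burden when the
#' recurrent deletion is expected in more than 20% of all affected
#' individuals, i.e. `Fd_NAHR > 0.20` (strict).
#'
#' @param fd_nahr Fd of the NAHR deletion event (fraction).
#' @param threshold Strict lower threshold, default 0.20.
#' @return Logical.
#' @export
classify_significant_burden <- function(fd_nahr, threshold = 0.20) {
  fd_nahr > threshold
}
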