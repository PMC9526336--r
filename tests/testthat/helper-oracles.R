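# Shared fixtures and independent oracles used across the suite.

# Random carrier pool with log-uniform frequencies in [1e-7, 1e-2].
random_pool <- function(n_alleles, n_del = 1, hom_viable = FALSE,
                        n_hyp = 0, gene = "SYN") {
  n_snv <- n_alleles - n_del - n_hyp
  stopifnot(n_snv >= 0)
  freq <- exp(runif(n_alleles, log(1e-7), log(1e-2)))
  carrier_pool(tibble::tibble(
    allele_id = sprintf("a%03d", seq_len(n_alleles)),
    allele_class = c(rep("nahr_del", n_del), rep("hypomorphic", n_hyp),
                     rep("snv_indel", n_snv)),
    frequency = freq,
    hom_viable = c(rep(hom_viable, n_del), rep(FALSE, n_alleles - n_del))
  ), gene = gene)
}

# Independent disease/lethal classification of one unordered genotype,
# written directly from the genotype rules (no reuse of package internals).
genotype_status_oracle <- function(class_i, class_j, viable_i, viable_j,
                                   lof_lof_lethal = FALSE) {
  hyp_i <- class_i == "hypomorphic"; hyp_j <- class_j == "hypomorphic"
  same <- identical(class_i, class_j) && identical(viable_i, viable_j)
  if (hyp_i && hyp_j) return("not_disease")
  if (xor(hyp_i, hyp_j)) return("disease")
  # both non-hypomorphic
  if (lof_lof_lethal) return("lethal")
  "disease"
}

# Oracle for the deletion-focused quantities by summing an explicitly
# enumerated genotype matrix (built here, independent of the closed forms).
enumerate_quantities <- function(pool, lof_lof_lethal = FALSE) {
  n <- nrow(pool)
  p <- pool$frequency
  hyp <- pool$allele_class == "hypomorphic"
  status <- matrix("", n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) {
      status[i, j] <- if (hyp[i]) "not_disease"
        else if ((pool$allele_class[i] == "nahr_del" && !pool$hom_viable[i]) ||
                 lof_lof_lethal) "lethal"
        else "disease"
    } else {
      status[i, j] <- if (hyp[i] && hyp[j]) "not_disease"
        else if (hyp[i] || hyp[j]) "disease"
        else if (lof_lof_lethal) "lethal"
        else "disease"
    }
  }
  prob <- outer(p, p)
  disease <- status == "disease"
  p_d <- sum(prob[disease])
  inter <- vapply(seq_len(n), function(k) {
    mask <- matrix(FALSE, n, n); mask[k, ] <- TRUE; mask[, k] <- TRUE
    sum(prob[disease & mask])
  }, numeric(1))
  list(p_disease = p_d, intersections = inter,
       fd = if (p_d > 0) inter / p_d else rep(NA_real_, n))
}

# Brute-force connected components of the reciprocal-overlap graph.
components_oracle <- function(pairs, overlap_fraction) {
  n <- nrow(pairs)
  adj <- matrix(FALSE, n, n)
  rec_ov <- function(s1, e1, s2, e2) {
    ov <- max(0, min(e1, e2) - max(s1, s2))
    if (ov == 0) return(0)
    min(ov / (e1 - s1), ov / (e2 - s2))
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- pairs$chrom[i] == pairs$chrom[j] &&
      rec_ov(pairs$del_start[i], pairs$del_end[i],
             pairs$del_start[j], pairs$del_end[j]) >= overlap_fraction
  }
  # transitive closure by repeated squaring of reachability
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  membership <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      comp <- comp + 1L
      membership[reach[i, ]] <- comp
    }
  }
  membership
}

# Two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins, summing the probabilities not exceeding the
# observed table's.
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x_range <- max(0, k - n):min(k, m)
  probs <- dhyper(x_range, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
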