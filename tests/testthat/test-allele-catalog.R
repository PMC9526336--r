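test_that("ClinVar filter keeps P/LP with at least one-star review", {
  records <- tibble::tibble(
    gene = c("G1", "G1", "G1", "G2", NA),
    allele_id = paste0("v", 1:5),
    clinical_significance = c("Pathogenic", "Pathogenic", "Likely pathogenic",
                              "Benign", "Pathogenic"),
    review_status = c("criteria_provided,_multiple_submitters,_no_conflicts",
                      "no_assertion_criteria_provided",
                      "criteria_provided,_single_submitter",
                      "reviewed_by_expert_panel",
                      "criteria_provided,_single_submitter"),
    frequency = c(1e-4, 1e-4, NA, 1e-3, 1e-4))
  expect_warning(kept <- filter_clinvar(records), "without a gene symbol")
  expect_setequal(kept$allele_id, c("v1", "v3"))
  # missing frequency gets the floor
  expect_equal(kept$frequency[kept$allele_id == "v3"], 1e-6)
  expect_true(all(kept$allele_class == "snv_indel"))
})

test_that("ClinVar filter equals an independent predicate scan on random tables", {
  withr::local_seed(31)
  n <- 100
  records <- tibble::tibble(
    gene = sample(c("G1", "G2", "G3"), n, replace = TRUE),
    allele_id = sprintf("v%03d", 1:n),
    clinical_significance = sample(c("Pathogenic", "Likely pathogenic",
                                     "Benign", "Uncertain significance",
                                     "Conflicting interpretations of pathogenicity"),
                                   n, replace = TRUE),
    review_status = sample(c("no_assertion_criteria_provided",
                             "criteria_provided,_single_submitter",
                             "criteria_provided,_multiple_submitters,_no_conflicts",
                             "reviewed_by_expert_panel"), n, replace = TRUE),
    frequency = ifelse(runif(n) < 0.3, NA, 10^runif(n, -6, -3)))
  kept <- filter_clinvar(records)
  manual <- records$allele_id[
    records$clinical_significance %in% c("Pathogenic", "Likely pathogenic") &
      records$review_status != "no_assertion_criteria_provided"]
  expect_setequal(kept$allele_id, manual)
})

sv_record <- function(allele_id = "sv1", filter = "PASS", qual = 600,
                      lof = TRUE, dup_lof = FALSE, popmax = 0.001,
                      nhomalt = 0, start = 1e6, end = 1.5e6,
                      all_tx = TRUE, af = 5e-4) {
  tibble::tibble(gene = "G1", allele_id = allele_id, filter = filter,
                 qual = qual, protein_coding_lof = lof,
                 protein_coding_dup_lof = dup_lof, popmax_af = popmax,
                 nhomalt = nhomalt, chrom = "chr1", start = start, end = end,
                 af = af, lof_all_transcripts = all_tx)
}

test_that("gnomAD-SV filter applies each printed criterion in isolation", {
  segdup <- tibble::tibble(chrom = "chr1", start = 1e6, end = 1.05e6)
  expect_equal(nrow(filter_gnomad_sv(sv_record(), segdup)), 1)
  expect_equal(nrow(filter_gnomad_sv(sv_record(qual = 400), segdup)), 0)
  expect_equal(nrow(filter_gnomad_sv(sv_record(filter = "LOW_CALL_RATE"), segdup)), 0)
  expect_equal(nrow(filter_gnomad_sv(sv_record(lof = FALSE), segdup)), 0)
  expect_equal(nrow(filter_gnomad_sv(sv_record(lof = FALSE, dup_lof = TRUE),
                                     segdup)), 1)
  expect_equal(nrow(filter_gnomad_sv(sv_record(popmax = 0.02), segdup)), 0)
  expect_equal(nrow(filter_gnomad_sv(sv_record(nhomalt = 2), segdup)), 0)
  expect_equal(nrow(filter_gnomad_sv(sv_record(all_tx = FALSE), segdup)), 0)
  # 90% of the span inside segdup
  wide_segdup <- tibble::tibble(chrom = "chr1", start = 1e6, end = 1.45e6)
  expect_equal(nrow(filter_gnomad_sv(sv_record(), wide_segdup)), 0)
  # a record missing a required value is rejected with a reason, not kept
  out <- filter_gnomad_sv(sv_record(qual = NA), segdup)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "rejections")$reason, "missing_field")
})

snv_record <- function(allele_id = "snv1", filter = "PASS", pos = 5e6,
                       qualapprox = 5e4, an = 1.5e5, af = 1e-4,
                       nhomalt = 0, loftee = "HC") {
  tibble::tibble(gene = "G1", allele_id = allele_id, filter = filter,
                 chrom = "chr1", pos = pos, qualapprox = qualapprox,
                 an = an, af = af, nhomalt = nhomalt, loftee = loftee)
}

test_that("gnomAD LoF small-variant filter applies all six criteria", {
  lcr <- tibble::tibble(chrom = "chr1", start = 1e6, end = 2e6)
  expect_equal(nrow(filter_gnomad_lof_snv(snv_record(), lcr)), 1)
  expect_equal(nrow(filter_gnomad_lof_snv(snv_record(filter = "AC0"), lcr)), 0)
  expect_equal(nrow(filter_gnomad_lof_snv(snv_record(pos = 1.5e6), lcr)), 0)
  expect_equal(nrow(filter_gnomad_lof_snv(snv_record(qualapprox = 2e5), lcr)), 0)
  expect_equal(nrow(filter_gnomad_lof_snv(snv_record(an = 5e4), lcr)), 0)
  expect_equal(nrow(filter_gnomad_lof_snv(snv_record(af = 0.02), lcr)), 0)
  expect_equal(nrow(filter_gnomad_lof_snv(snv_record(nhomalt = 1), lcr)), 0)
  expect_equal(nrow(filter_gnomad_lof_snv(snv_record(loftee = "LC"), lcr)), 0)
  # direction switch for the QUALapprox rule
  expect_equal(nrow(filter_gnomad_lof_snv(snv_record(qualapprox = 2e5), lcr,
                                          invert_qualapprox = TRUE)), 1)
})

test_that("both gnomAD filters equal independent conjunction scans on random tables", {
  withr::local_seed(37)
  n <- 500
  segdup <- tibble::tibble(chrom = "chr1",
                           start = seq(0, 9.9e6, by = 2e5),
                           end = seq(0, 9.9e6, by = 2e5) + 1e5)
  sv <- tibble::tibble(
    gene = "G1", allele_id = sprintf("sv%03d", 1:n),
    filter = sample(c("PASS", "FAIL"), n, replace = TRUE, prob = c(0.8, 0.2)),
    qual = runif(n, 100, 1000),
    protein_coding_lof = runif(n) < 0.6,
    protein_coding_dup_lof = runif(n) < 0.2,
    popmax_af = 10^runif(n, -5, -1.5),
    nhomalt = rbinom(n, 1, 0.2),
    chrom = "chr1",
    start = round(runif(n, 0, 9e6)))
  sv$end <- sv$start + round(runif(n, 1e4, 1e6))
  sv$af <- sv$popmax_af / 2
  sv$lof_all_transcripts <- runif(n) < 0.8
  kept <- filter_gnomad_sv(sv, segdup)
  ov <- vapply(seq_len(n), function(i) {
    s <- sv$start[i]; e <- sv$end[i]
    hits <- segdup[segdup$start < e & segdup$end > s, ]
    if (nrow(hits) == 0) return(0)
    sum(pmin(hits$end, e) - pmax(hits$start, s)) / (e - s)  # track is disjoint
  }, numeric(1))
  manual <- sv$allele_id[sv$filter == "PASS" & sv$qual > 500 &
                           (sv$protein_coding_lof | sv$protein_coding_dup_lof) &
                           sv$popmax_af < 0.01 & sv$nhomalt == 0 &
                           ov < 0.8 & sv$lof_all_transcripts]
  expect_setequal(kept$allele_id, manual)

  lcr <- tibble::tibble(chrom = "chr1", start = c(1e6, 4e6), end = c(1.2e6, 4.5e6))
  snv <- tibble::tibble(
    gene = "G1", allele_id = sprintf("s%03d", 1:n),
    filter = sample(c("PASS", "AC0"), n, replace = TRUE, prob = c(0.85, 0.15)),
    chrom = "chr1", pos = round(runif(n, 0, 9e6)),
    qualapprox = 10^runif(n, 3, 6),
    an = round(runif(n, 1e4, 2e5)),
    af = 10^runif(n, -6, -1.5),
    nhomalt = rbinom(n, 1, 0.15),
    loftee = sample(c("HC", "LC", "OS"), n, replace = TRUE))
  kept2 <- filter_gnomad_lof_snv(snv, lcr)
  in_lcr <- (snv$pos >= 1e6 & snv$pos < 1.2e6) | (snv$pos >= 4e6 & snv$pos < 4.5e6)
  manual2 <- snv$allele_id[snv$filter == "PASS" & !in_lcr &
                             snv$qualapprox < 1e5 & snv$an > 7.5e4 &
                             snv$af < 0.01 & snv$nhomalt == 0 &
                             snv$loftee == "HC"]
  expect_setequal(kept2$allele_id, manual2)
})

test_that("prevalence reconciliation follows the Fisher decision rule", {
  est <- tibble::tibble(
    cohort = c("ukbiobank", "iceland"),
    carrier_count = c(100, 24),
    cohort_size = c(421268, 101655))
  chosen <- reconcile_prevalence(est)
  expect_equal(chosen$cohort, "ukbiobank")
  expect_gt(chosen$p_value, 0.05)
  expect_match(chosen$decision, "UK Biobank")

  est2 <- tibble::tibble(
    cohort = c("ukbiobank", "iceland", "region_specific"),
    carrier_count = c(10, 40, 35),
    cohort_size = c(400000, 100000, 100000))
  chosen2 <- reconcile_prevalence(est2)
  expect_lt(chosen2$p_value, 0.05)
  expect_equal(chosen2$cohort, "iceland")  # closer in log frequency to region cohort
  expect_match(chosen2$decision, "closer")

  single <- reconcile_prevalence(tibble::tibble(
    cohort = "ukbiobank", carrier_count = 5, cohort_size = 1e5))
  expect_equal(single$decision, "single source")
  expect_error(reconcile_prevalence(tibble::tibble(
    cohort = c("ukbiobank", "iceland"), carrier_count = c(NA, 3),
    cohort_size = c(1e5, 1e5))), "counts")
})

test_that("Fisher p-values agree with exact hypergeometric enumeration", {
  withr::local_seed(41)
  for (i in 1:20) {
    a <- rpois(1, 15); c_ <- rpois(1, 8)
    nb <- sample(500:5000, 1); nd <- sample(500:5000, 1)
    tab <- matrix(c(a, nb, c_, nd), nrow = 2)
    p_pkg <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    p_orc <- fisher_p_oracle(a, nb, c_, nd)
    expect_equal(p_pkg, p_orc, tolerance = 1e-8)
  }
})

test_that("pool assembly attaches deletions, pads 10%, and deduplicates", {
  alleles <- tibble::tibble(gene = "G1",
                            allele_id = c("v1", "v2", "v2"),
                            allele_class = "snv_indel",
                            frequency = c(4e-4, 5e-4, 5e-4),
                            hom_viable = FALSE, source = "clinvar")
  regions <- tibble::tibble(region_id = "del_A",
                            allele_frequency = 1e-4,
                            hom_viable = FALSE,
                            genes = list(c("G1", "G2")))
  pool <- assemble_gene_pool("G1", alleles, regions)
  # observed burden 9e-4 + deletion 1e-4 = 1e-3; S_total = 1e-3/0.9
  pads <- pool[pool$source == "hypothetical", ]
  expect_equal(nrow(pads), 10)
  expect_equal(unique(pads$frequency), 0.01 * 1e-3 / 0.9)
  expect_equal(sum(pads$frequency) / carrier_burden(pool), 0.1,
               tolerance = 1e-9)
  expect_equal(sum(pool$allele_class == "nahr_del"), 1)

  # assembling twice from the same inputs is idempotent
  expect_identical(pool, assemble_gene_pool("G1", alleles, regions))

  # padding disabled: burden is the plain observed sum
  plain <- assemble_gene_pool("G1", alleles, regions, padding = "none")
  expect_equal(carrier_burden(plain), 1e-3)
})

test_that("a gene inside two nested deletions receives two deletion alleles", {
  nested <- tibble::tibble(
    region_id = c("del_BP4_BP5", "del_BP3_BP5"),
    allele_frequency = c(9.97e-5, 2.374e-6),
    hom_viable = c(TRUE, FALSE),
    genes = list(c("OTUD7A", "FAN1"), c("OTUD7A", "FAN1", "NSMCE3")))
  pool <- assemble_gene_pool("OTUD7A", NULL, nested, padding = "none")
  expect_equal(sum(pool$allele_class == "nahr_del"), 2)
  expect_equal(pool$hom_viable[pool$allele_id == "del_BP4_BP5"], TRUE)
})

test_that("carrier burden sums unique non-hypomorphic frequencies", {
  pool <- carrier_pool(tibble::tibble(allele_id = c("a", "b", "c"),
                                      frequency = c(1e-3, 2e-3, 3e-3)))
  expect_equal(carrier_burden(pool), 6e-3)
  expect_equal(carrier_burden(pool[0, ]), 0)
  # reproduces a published aggregate from its parts
  nphp1 <- deletion_focused_pool("NPHP1", 5.811e-3, 6.82e-3, hom_viable = TRUE)
  expect_equal(carrier_burden(nphp1), 6.82e-3)
})
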