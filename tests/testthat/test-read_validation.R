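test_that("read usability rules differ by platform, role and tissue", {
  obs <- data.table::rbindlist(list(
    ev_row("p1", "G", platform = "HIFI", tissue = "CELL_LINE"),   # child cell line
    ev_row("p1", "G", platform = "ONT", tissue = "CELL_LINE", mapq = 58),
    ev_row("p1", "G", platform = "ILLUMINA", mapq = 5, base_qual = 30),
    ev_row("p1", "G", platform = "HIFI", base_qual = 9),           # discarded
    ev_row("p1", "G", platform = "HIFI", base_qual = 15)))         # LOW tier
  child <- usable_reads(obs, "child")
  expect_equal(nrow(child), 2L)
  expect_true(all(child$platform %in% c("ILLUMINA", "HIFI")))
  ill <- child[child$platform == "ILLUMINA", ]
  expect_equal(ill$tier, "HIGH")  # no mapq filter for short reads
  expect_equal(child[child$base_qual == 15, ]$tier, "LOW")
  # parental HiFi cell-line reads are retained
  parent <- usable_reads(obs, "parent")
  expect_true(any(parent$tissue == "CELL_LINE" & parent$platform == "HIFI"))
})

test_that("per-platform verdicts implement the parental cleanliness caps", {
  # HiFi: parents clean, child supported
  expect_equal(platform_verdict_snv("HIFI", 20L, 3L, 0L, 0L, 0L, 0L),
               "DENOVO")
  # one high-quality parental alt read is disqualifying on HiFi
  expect_equal(platform_verdict_snv("HIFI", 20L, 3L, 1L, 0L, 0L, 0L),
               "INHERITED")
  # two low-quality parental alt reads are disqualifying on HiFi
  expect_equal(platform_verdict_snv("HIFI", 20L, 3L, 0L, 2L, 0L, 0L),
               "INHERITED")
  # ONT tolerates one high-quality parental alt read
  expect_equal(platform_verdict_snv("ONT", 20L, 5L, 1L, 0L, 0L, 0L),
               "DENOVO")
  expect_equal(platform_verdict_snv("ONT", 20L, 5L, 2L, 0L, 0L, 0L),
               "INHERITED")
  expect_equal(platform_verdict_snv("ONT", 20L, 5L, 0L, 3L, 0L, 0L),
               "INHERITED")
  # no usable child reads
  expect_equal(platform_verdict_snv("HIFI", 0L, 0L, 0L, 0L, 0L, 0L),
               "NODATA")
})

test_that("verdict combination needs two supporting platforms and no inherited signal", {
  expect_equal(combine_verdicts(c("DENOVO", "DENOVO", "NODATA")),
               "VALIDATED")
  expect_equal(combine_verdicts(c("DENOVO", "INHERITED", "DENOVO")),
               "INHERITED")
  expect_equal(combine_verdicts(c("DENOVO", "NODATA", "NODATA")),
               "FAILED_SUPPORT")
  expect_equal(combine_verdicts(c("DENOVO", "NOSUPPORT", "DENOVO")),
               "VALIDATED")
})

test_that("monotonicity: relaxing parental alt-read caps never removes support", {
  set.seed(21)
  verdict_with_caps <- function(hq_cap, lq_cap, fh, fl, mh, ml) {
    clean <- fh <= hq_cap & fl <= lq_cap & mh <= hq_cap & ml <= lq_cap
    ifelse(clean, "DENOVO", "INHERITED")
  }
  for (rep in 1:50) {
    fh <- rpois(1, 1); fl <- rpois(1, 1)
    mh <- rpois(1, 1); ml <- rpois(1, 1)
    strict <- verdict_with_caps(0L, 1L, fh, fl, mh, ml)
    loose <- verdict_with_caps(1L, 2L, fh, fl, mh, ml)
    expect_false(strict == "DENOVO" && loose == "INHERITED")
  }
})

test_that("cohort recurrence counts unrelated carriers, with the TR allowance", {
  ped <- validate_pedigree(data.table::rbindlist(list(
    quad_pedigree(),
    data.table::data.table(family_id = "f2",
                           sample_id = c("fa2", "mo2", "p2"),
                           father_id = c(NA, NA, "fa2"),
                           mother_id = c(NA, NA, "mo2"),
                           sex = c("M", "F", "F"),
                           role = c("father", "mother", "proband"),
                           father_age_at_birth = c(NA, NA, 40),
                           mother_age_at_birth = c(NA, NA, 38)))))
  cand <- data.table::data.table(chrom = "chr1",
                                 pos = c(5000L, 6000L, 7000L),
                                 alt = "G", child_id = "p1",
                                 family_id = "f1")
  ev <- validate_evidence(data.table::rbindlist(list(
    ev_row("p1", "G", pos = 5000),
    ev_row("p2", "G", pos = 5000),   # unrelated carrier
    ev_row("p1", "G", pos = 6000),
    ev_row("p2", "G", pos = 6000),   # unrelated carrier, but in a TR
    ev_row("p1", "G", pos = 7000),
    ev_row("s1", "G", pos = 7000)))) # sibling: related, never counts
  tr <- data.table::data.table(chrom = "chr1", start = 5990L, end = 6010L,
                               feature_class = "TR",
                               pct_identity = NA_real_)
  pass <- cohort_recurrence_filter(cand, ev, ped, tr)
  expect_equal(pass, c(FALSE, TRUE, TRUE))
})

test_that("repeat-context AB thresholds follow the TR/RepeatMasker rules", {
  expect_equal(repeat_ab_filters(mean(c(0.04, 0.05, 0.03)), TRUE, FALSE),
               "tr_ab")
  expect_equal(repeat_ab_filters(0.09, FALSE, TRUE), "pass")
  expect_equal(repeat_ab_filters(0.09, TRUE, TRUE), "rm_ab")
  expect_equal(repeat_ab_filters(0.02, FALSE, FALSE), "pass")
  expect_equal(repeat_ab_filters(NA_real_, FALSE, FALSE), "nodata")
})

test_that("the homopolymer filter removes run-base substitutions at run edges", {
  # A>T extending an AAAAA run: fails
  expect_false(homopolymer_filter("A", "T", "CGTCGGCGTCAAAAACTGACT"))
  # same run, but neither allele is the run base: passes
  expect_true(homopolymer_filter("C", "G", "CGTCGGCGTCCAAAATGACTG"))
  # run base allele but 3 bp away from the AAAA run: passes
  expect_true(homopolymer_filter("A", "G", "CGTCGGCGTCATGCAAAATGA"))
  # within 1 bp of the run with the run base as alternate: fails
  expect_false(homopolymer_filter("C", "A", "CGTCGGCGTACAAAACTGACT"))
  # brute-force distance rule on constructed contexts
  for (gap in 0:4) {
    ctx <- paste0(paste(rep("C", 10), collapse = ""), "A",
                  paste(rep("G", gap), collapse = ""),
                  paste(rep("A", 4), collapse = ""),
                  paste(rep("T", 6 - gap), collapse = ""))
    expect_equal(homopolymer_filter("A", "T", ctx), gap >= 1,
                 label = paste("gap", gap))
  }
  expect_warning(res <- homopolymer_filter("A", "T", "ACT"), "context")
  expect_true(res)
})

test_that("indel validation enforces spanning reads and the two-platform rule", {
  ped <- quad_pedigree()
  variant <- list(chrom = "chr1", pos = 5000L, ref = "A", alt = "AGG",
                  child_id = "p1")
  base <- list(
    ev_row("p1", "AGG", platform = "HIFI"),
    ev_row("p1", "AGG", platform = "ILLUMINA"),
    ev_row("p1", "A", platform = "ONT"))
  ev <- validate_evidence(data.table::rbindlist(base))
  expect_equal(validate_indel(variant, ev, ped)$status, "VALIDATED")

  # HiFi-only support fails the two-platform rule
  ev2 <- validate_evidence(data.table::rbindlist(base[c(1, 3)]))
  expect_equal(validate_indel(variant, ev2, ped)$status, "FAILED_SUPPORT")

  # a sibling carrier on any platform marks the call inherited
  ev3 <- validate_evidence(data.table::rbindlist(c(base, list(
    ev_row("s1", "AGG", platform = "ONT", tissue = "CELL_LINE")))))
  expect_equal(validate_indel(variant, ev3, ped)$status, "INHERITED")

  # reads with < 10 bp flank or mapq < 60 are not usable
  ev4 <- validate_evidence(data.table::rbindlist(list(
    ev_row("p1", "AGG", platform = "HIFI", flank_right = 8),
    ev_row("p1", "AGG", platform = "ILLUMINA", mapq = 59),
    ev_row("p1", "AGG", platform = "ONT"))))
  expect_equal(validate_indel(variant, ev4, ped)$status, "FAILED_SUPPORT")
})

test_that("the multi-allele screen needs two supported third alleles to fail", {
  mk <- function(alleles) data.table::data.table(allele = alleles)
  expect_true(multiallele_filter(mk(c("A", "A", "AGG", "AGG")), "A", "AGG"))
  expect_false(multiallele_filter(
    mk(c("A", "AGG", "AT", "AT", "AT", "ACC", "ACC", "ACC")), "A", "AGG"))
  # one stray third allele on a single read is tolerated
  expect_true(multiallele_filter(mk(c("A", "AGG", "AT")), "A", "AGG"))
  # one supported third allele is still tolerated
  expect_true(multiallele_filter(mk(c("A", "AGG", "AT", "AT")), "A", "AGG"))
})

test_that("validation filters are pure predicates: the driver agrees with each filter", {
  co <- small_cohort()
  res <- small_result()
  rec <- res$records
  # recompute the individual predicates on the records and check the driver
  # combined them with short-circuit provenance only (same VALIDATED set
  # under any order)
  tr <- co$features[co$features$feature_class == "TR", ]
  rm_ <- co$features[co$features$feature_class == "RM", ]
  recur <- cohort_recurrence_filter(rec, co$evidence, co$pedigree, tr)
  ab <- repeat_ab_filters(rec$mean_ab,
                          trioscope:::points_in_track(rec$chrom, rec$pos, tr),
                          trioscope:::points_in_track(rec$chrom, rec$pos, rm_))
  ctx <- co$context[rec[, c("chrom", "pos")], on = c("chrom", "pos"),
                    mult = "first"]$context
  hp <- homopolymer_filter(rec$ref, rec$alt, ctx)
  ok <- rec$support == "VALIDATED" & recur & ab == "pass" & hp &
    rec$noisy_platforms < 2
  expect_equal(rec$validation_status == "VALIDATED", ok)
})

test_that("validation on the simulated cohort removes confounders and keeps true mutations", {
  res <- small_result()
  ev <- res$evaluation
  expect_gte(ev$germline_sensitivity, 0.95)
  expect_equal(ev$confounders$inherited_artifact[["in_callset"]], 0L)
  rec <- ev$confounders$recurrent_error
  expect_lte(rec[["in_callset"]], 0.01 * max(1, rec[["n"]]))
  expect_equal(ev$confounders$homopolymer_error[["in_callset"]], 0L)
})
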