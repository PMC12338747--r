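make_calls <- function(rows) {
  # rows: list of list(pos, gt_fa, gt_mo, gt_p1, gq_p1, caller)
  data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(
      chrom = "chr1", pos = as.integer(r$pos), ref = "A", alt = "G",
      caller_id = r$caller %||% "gatk",
      sample_id = c("fa", "mo", "p1"),
      gt = c(r$gt_fa, r$gt_mo, r$gt_p1),
      gq = c(99, 99, r$gq_p1 %||% 50))
  }))
}

test_that("caller union deduplicates sites and keeps provenance", {
  a <- make_calls(list(list(pos = 100, gt_fa = "0/0", gt_mo = "0/0",
                            gt_p1 = "0/1"),
                       list(pos = 200, gt_fa = "0/0", gt_mo = "0/0",
                            gt_p1 = "0/1"),
                       list(pos = 300, gt_fa = "0/0", gt_mo = "0/0",
                            gt_p1 = "0/1")))
  b <- make_calls(list(list(pos = 300, gt_fa = "0/0", gt_mo = "0/0",
                            gt_p1 = "0/1", caller = "dv"),
                       list(pos = 400, gt_fa = "0/0", gt_mo = "0/0",
                            gt_p1 = "0/1", caller = "dv"),
                       list(pos = 500, gt_fa = "0/0", gt_mo = "0/0",
                            gt_p1 = "0/1", caller = "dv")))
  u <- union_callsets(list(a, b))
  expect_equal(attr(u, "n_unique_sites"), 5L)
  # idempotence
  expect_equal(attr(union_callsets(list(a, a)), "n_unique_sites"), 3L)
  cand <- select_candidate_snvs(u, quad_pedigree())
  expect_equal(cand[cand$pos == 300, ]$callers, "dv,gatk")
})

test_that("candidate selection applies the trio genotype pattern and the child GQ bound", {
  calls <- make_calls(list(
    list(pos = 100, gt_fa = "0/0", gt_mo = "0/0", gt_p1 = "0/1",
         gq_p1 = 30),                               # kept
    list(pos = 200, gt_fa = "0/1", gt_mo = "0/0", gt_p1 = "0/1"),  # parent has alt
    list(pos = 300, gt_fa = "0/0", gt_mo = "0/0", gt_p1 = "0/1",
         gq_p1 = 19),                               # below GQ bound
    list(pos = 400, gt_fa = "0/0", gt_mo = "0/0", gt_p1 = "0/1",
         gq_p1 = 20),                               # exactly at the bound
    list(pos = 500, gt_fa = "0/0", gt_mo = "0/0", gt_p1 = "1/1")))  # hom alt child
  cand <- select_candidate_snvs(calls, quad_pedigree())
  expect_equal(sort(cand$pos), c(100L, 400L, 500L))
  expect_true(all(cand$child_id == "p1"))
  expect_true(all(cand$category == "SNV"))
})

test_that("cluster filter matches its definition on the worked examples", {
  mk <- function(pos) data.table::data.table(chrom = "chr1",
                                             pos = as.integer(pos),
                                             child_id = "p1")
  r1 <- cluster_filter(mk(c(100, 500, 900)))
  expect_equal(nrow(r1$kept), 0L)
  expect_equal(nrow(r1$clustered), 3L)

  r2 <- cluster_filter(mk(c(100, 1200)))
  expect_equal(nrow(r2$clustered), 0L)

  r3 <- cluster_filter(mk(c(100, 600, 1099, 2500)))
  expect_equal(sort(r3$clustered$pos), c(100L, 600L, 1099L))
  expect_equal(r3$kept$pos, 2500L)

  # two children sharing positions are filtered independently
  two <- data.table::rbindlist(list(mk(c(100, 500)),
                                    data.table::data.table(
                                      chrom = "chr1", pos = 900L,
                                      child_id = "s1")))
  r4 <- cluster_filter(two)
  expect_equal(nrow(r4$clustered), 0L)
})

test_that("cluster filter equals the brute-force window scan", {
  set.seed(99)
  for (rep in 1:25) {
    pos <- sort(sample(1:10000, sample(3:15, 1)))
    cand <- data.table::data.table(chrom = "chr1", pos = pos,
                                   child_id = "p1")
    res <- cluster_filter(cand)
    oracle <- oracle_cluster_flags(pos)
    expect_equal(sort(res$clustered$pos), sort(pos[oracle]),
                 label = paste("positions", paste(pos, collapse = ",")))
    # partition is exhaustive and disjoint
    expect_equal(sort(c(res$kept$pos, res$clustered$pos)), pos)
  }
})

test_that("sex-chromosome candidate logic is ploidy-aware", {
  ped <- quad_pedigree()  # p1 male, s1 female
  rows <- data.table::rbindlist(list(
    # male X: child allele differs from mother -> candidate
    data.table::data.table(chrom = "chrX", pos = 100L, ref = "A", alt = "G",
                           caller_id = "gatk",
                           sample_id = c("fa", "mo", "p1", "s1"),
                           gt = c("0", "0/0", "1", "0/0"),
                           gq = c(60, 60, 60, 60)),
    # male Y: child matches father -> not a candidate
    data.table::data.table(chrom = "chrY", pos = 200L, ref = "C", alt = "T",
                           caller_id = "gatk",
                           sample_id = c("fa", "mo", "p1", "s1"),
                           gt = c("1", NA, "1", NA), gq = c(60, NA, 60, NA)),
    # male Y: child differs from father -> candidate
    data.table::data.table(chrom = "chrY", pos = 300L, ref = "C", alt = "T",
                           caller_id = "gatk",
                           sample_id = c("fa", "mo", "p1", "s1"),
                           gt = c("0", NA, "1", NA), gq = c(60, NA, 60, NA)),
    # female X: mother 0/0, father hemizygous ref, child het -> candidate
    data.table::data.table(chrom = "chrX", pos = 400L, ref = "G", alt = "A",
                           caller_id = "gatk",
                           sample_id = c("fa", "mo", "p1", "s1"),
                           gt = c("0", "0/0", "0", "0/1"),
                           gq = c(60, 60, 60, 60))))
  cand <- select_sex_candidates(rows, ped)
  expect_equal(nrow(cand), 3L)
  expect_equal(cand[cand$child_id == "p1" & cand$chrom == "chrX",
                    ]$sex_chrom_mode, "MALE_X")
  expect_equal(cand[cand$child_id == "p1" & cand$chrom == "chrY", ]$pos,
               300L)
  expect_equal(cand[cand$child_id == "s1", ]$sex_chrom_mode, "FEMALE_X")

  # pseudoautosomal exclusion removes candidates inside the PAR track
  par_bed <- data.table::data.table(chrom = "chrX", start = 0L, end = 150L)
  cand2 <- select_sex_candidates(rows, ped, par_track = par_bed)
  expect_false(100L %in% cand2$pos)

  # diploid chrY genotype for a male is an input error
  bad <- data.table::copy(rows)
  bad[chrom == "chrY" & sample_id == "p1", gt := "0/1"]
  expect_error(select_sex_candidates(bad, ped), "diploid chrY")
})

test_that("indels are categorized as TR subunit events or plain indels", {
  tr <- data.table::data.table(chrom = "chr1", start = 990L, end = 1020L,
                               feature_class = "TR", pct_identity = NA_real_,
                               motif = "AT")
  # +AT insertion inside an (AT)n repeat: whole-motif expansion
  expect_equal(classify_indel_category("A", "AAT", "chr1", 1000L, tr),
               "INDEL_TR")
  # +G insertion: not a motif multiple
  expect_equal(classify_indel_category("A", "AG", "chr1", 1000L, tr),
               "INDEL_NONTR")
  # deletion of two AT units
  expect_equal(classify_indel_category("AATAT", "A", "chr1", 1000L, tr),
               "INDEL_TR")
  # outside any TR
  expect_equal(classify_indel_category("AACGT", "A", "chr1", 5000L, tr),
               "INDEL_NONTR")
})
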