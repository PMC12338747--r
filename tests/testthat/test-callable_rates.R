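test_that("callable mask requires homozygous-reference parents and trio coverage", {
  ped <- quad_pedigree()
  gts <- data.table::rbindlist(lapply(1:5, function(p) {
    data.table::data.table(chrom = "chr1", pos = p,
                           sample_id = c("fa", "mo", "p1"),
                           gt = c(if (p == 3) "0/1" else "0/0", "0/0",
                                  "0/0"))
  }))
  mk_read <- function(sid, pos, tissue = "BLOOD", bq = 30L) {
    ev_row(sid, "A", pos = pos, tissue = tissue, base_qual = bq)
  }
  ev <- data.table::rbindlist(c(
    lapply(1:5, function(p) mk_read("fa", p, tissue = "CELL_LINE")),
    lapply(1:5, function(p) mk_read("mo", p)),
    lapply(1:4, function(p) mk_read("p1", p)),
    # child covered at site 5 only by cell-line HiFi: not callable
    list(mk_read("p1", 5, tissue = "CELL_LINE"))))
  mask <- compute_callable_mask(gts, validate_evidence(ev), ped, "p1")
  # sites 1,2,4 callable; 3 fails the parental 0/0 rule; 5 lacks child
  # blood coverage
  expect_equal(mask$start, c(0L, 3L))
  expect_equal(mask$end, c(2L, 4L))
  expect_equal(unname(attr(mask, "total_bp")["autosome"]), 3)
})

test_that("male sex chromosomes drop the parental genotype restriction", {
  ped <- quad_pedigree()  # p1 is male
  gts <- data.table::data.table(chrom = "chrY", pos = 1:2,
                                sample_id = "fa", gt = c("1", "0"))
  gts <- data.table::rbindlist(list(
    gts, data.table::data.table(chrom = "chrY", pos = 1:2,
                                sample_id = "p1", gt = "0")))
  ev <- data.table::rbindlist(list(
    ev_row("fa", "A", chrom = "chrY", pos = 1),
    ev_row("p1", "A", chrom = "chrY", pos = 1),
    ev_row("mo", "A", chrom = "chrY", pos = 2),
    ev_row("p1", "A", chrom = "chrY", pos = 2)))
  mask <- compute_callable_mask(gts, validate_evidence(ev), ped, "p1")
  # site 1: father hemizygous alt but covered -> callable; site 2 lacks
  # paternal coverage (maternal reads are ignored on chrY)
  expect_equal(mask$start, 0L)
  expect_equal(mask$end, 1L)
  expect_equal(unname(attr(mask, "total_bp")["chrY"]), 1)
})

test_that("mutation rate is count over ploidy-adjusted callable length", {
  mask <- data.table::data.table(child_id = "p1", chrom = "chr1",
                                 start = 0L, end = 2.5e9)
  dnms <- data.table::data.table(chrom = "chr1", pos = seq_len(100),
                                 child_id = "p1")
  r <- mutation_rate(dnms, mask, 2, bootstrap_reps = 10)
  expect_equal(r$rate, 2.0e-8)
  expect_equal(r$n_mutations, 100L)

  r0 <- mutation_rate(dnms[0], mask, 2, bootstrap_reps = 10)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_low, 0)

  expect_error(mutation_rate(dnms, mask[0], 2), "zero|callable")

  # bootstrap interval brackets the point estimate
  set.seed(2)
  mask73 <- data.table::data.table(child_id = sprintf("c%02d", 1:20),
                                   chrom = "chr1", start = 0L, end = 5e7)
  dn <- data.table::data.table(
    chrom = "chr1",
    pos = seq_len(20 * 30),
    child_id = rep(sprintf("c%02d", 1:20), each = 30))
  r2 <- mutation_rate(dn, mask73, 2, bootstrap_reps = 500)
  expect_lte(r2$ci_low, r2$rate)
  expect_gte(r2$ci_high, r2$rate)
})

test_that("feature rates use 0-based half-open intersection", {
  mask <- data.table::data.table(child_id = "p1", chrom = "chr1",
                                 start = 0L, end = 2e7)
  feats <- data.table::data.table(chrom = "chr1", start = 0L, end = 1e7,
                                  feature_class = "SD",
                                  pct_identity = 99.5)
  dnms <- data.table::data.table(chrom = "chr1", pos = c(5e6, 7e6),
                                 child_id = "p1")
  fr <- feature_rate(dnms, mask, feats, "SD")
  expect_equal(fr$rate, 2 / (2 * 1e7))
  # a DNM at the feature boundary base (BED end-exclusive) is not counted
  dn2 <- data.table::data.table(chrom = "chr1", pos = c(1e7 + 1), # 0-based 1e7
                                child_id = "p1")
  fr2 <- feature_rate(dn2, mask, feats, "SD")
  expect_equal(fr2$n, 0L)
  # ... but the last base inside the interval is
  dn3 <- data.table::data.table(chrom = "chr1", pos = 1e7, child_id = "p1")
  expect_equal(feature_rate(dn3, mask, feats, "SD")$n, 1L)
  # empty intersection reports an undefined rate
  feats2 <- data.table::data.table(chrom = "chr2", start = 0L, end = 100L,
                                   feature_class = "SD",
                                   pct_identity = 99.5)
  expect_true(is.na(feature_rate(dnms, mask, feats2, "SD")$rate))
})

test_that("identity bins stratify segmental duplication rates", {
  mask <- data.table::data.table(child_id = "p1", chrom = "chr1",
                                 start = 0L, end = 3e7)
  feats <- data.table::data.table(chrom = "chr1",
                                  start = c(0L, 1e7, 2e7),
                                  end = c(1e7, 2e7, 3e7),
                                  feature_class = "SD",
                                  pct_identity = c(97, 98.5, 99.5))
  dnms <- data.table::data.table(chrom = "chr1",
                                 pos = c(5e6, 2.5e7, 2.6e7, 2.7e7),
                                 child_id = "p1")
  fr <- feature_rate(dnms, mask, feats, "SD", id_bins = c(90, 98, 99, 100))
  expect_equal(nrow(fr), 3L)
  top <- fr[grepl("99", fr$bin) & grepl("100", fr$bin), ]
  expect_equal(top$n, 3L)
})

test_that("paired rate comparison detects enrichment and is null on equality", {
  set.seed(8)
  kids <- sprintf("c%02d", 1:40)
  genome <- data.table::data.table(child_id = kids,
                                   rate = rnorm(40, 1e-8, 5e-10))
  equal <- data.table::data.table(feature = "LINE", child_id = kids,
                                  rate = genome$rate)
  enriched <- data.table::data.table(feature = "SD", child_id = kids,
                                     rate = genome$rate * 2 +
                                       rnorm(40, 0, 5e-10))
  res <- compare_rates(rbind(equal, enriched), genome)
  expect_equal(res[res$feature == "LINE", ]$p, 1)
  expect_equal(res[res$feature == "LINE", ]$t, 0)
  expect_lt(res[res$feature == "SD", ]$p_BH, 0.05)
  expect_error(compare_rates(equal[1], genome[1]), "2 samples")
})

test_that("pipeline rate summary matches the count arithmetic on the simulated genome", {
  res <- small_result()
  co <- small_cohort()
  s <- res$summary
  n_children <- s$n_children
  glen <- co$genome$length[1]
  expect_equal(s$germline_rate,
               s$n_germline / (2 * n_children * glen))
  expect_equal(s$pzm_rate, s$n_pzm / (2 * n_children * glen))
})
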