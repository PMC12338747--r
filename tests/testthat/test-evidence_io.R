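test_that("pedigree reader validates family structure and ages", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(quad_pedigree(), tmp)
  ped <- read_pedigree(tmp)
  expect_equal(nrow(ped), 4L)
  expect_equal(sort(ped$role), c("father", "mother", "proband", "sibling"))

  bad <- data.table::copy(quad_pedigree())
  bad$mother_id[3] <- NA
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(bad, tmp2, sep = "\t", na = ".")
  expect_error(read_pedigree(tmp2), "p1.*mother|mother.*p1")

  dup <- data.table::copy(quad_pedigree())
  dup$sample_id[4] <- "p1"
  expect_error(validate_pedigree(dup), "duplicate")
})

test_that("calibrated pedigree has 157 individuals in 42 families", {
  set.seed(1)
  ped <- trioscope:::sim_pedigree(calibrated_preset())
  expect_equal(nrow(ped), 157L)
  expect_equal(data.table::uniqueN(ped$family_id), 42L)
  expect_equal(nrow(pedigree_children(ped)), 73L)
})

test_that("trio VCF parsing recodes genotypes, splits multiallelics and keeps haploid calls", {
  ped <- quad_pedigree()
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gatk",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="q">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "fa", "mo", "p1", "s1"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:GQ\t0/0:50\t0/0:50\t0/1:50\t0/0:50",
    "chr1\t200\t.\tC\tG,T\t.\tPASS\t.\tGT:GQ\t0/0:50\t0/1:50\t0/2:44\t0/0:50",
    "chrY\t300\t.\tG\tA\t.\tPASS\t.\tGT:GQ\t0:60\t./.:.\t1:60\t./.:."),
    tmp)
  calls <- read_trio_vcf(tmp, ped)
  expect_equal(unique(calls$caller_id), "gatk")
  # biallelic het child
  r1 <- calls[calls$pos == 100 & calls$sample_id == "p1", ]
  expect_equal(r1$gt, "0/1")
  expect_equal(r1$gq, 50)
  # multiallelic split: two biallelic records, child 0/2 recoded per alt
  r2 <- calls[calls$pos == 200 & calls$sample_id == "p1", ]
  expect_equal(nrow(r2), 2L)
  expect_equal(r2[r2$alt == "G", ]$gt, "0/0")
  expect_equal(r2[r2$alt == "T", ]$gt, "0/1")
  # haploid chrY preserved; missing GQ becomes 0 and is counted
  r3 <- calls[calls$pos == 300 & calls$sample_id == "p1", ]
  expect_equal(r3$gt, "1")
  expect_true(attr(calls, "n_missing_gq") >= 1)

  bad_ped <- quad_pedigree()[1:3, ]
  expect_error(read_trio_vcf(tmp, validate_pedigree(bad_ped)), "absent")
})

test_that("read-evidence TSV round-trips and parses tagging SNPs", {
  ev <- data.table::rbindlist(list(
    ev_row("p1", "G", tag_snps = "1000:A;1400:G", read_id = "r1"),
    ev_row("p1", "A", tag_snps = ".", read_id = "r2"),
    ev_row("fa", "A", platform = "ONT", tissue = "CELL_LINE",
           read_id = "r3")))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_read_evidence(ev, tmp)
  back <- read_read_evidence(tmp)
  expect_equal(nrow(back), 3L)
  data.table::setorder(back, read_id)
  tags <- parse_tag_snps(back$tag_snps)
  expect_equal(nrow(tags), 2L)
  expect_equal(tags$snp_pos, c(1000L, 1400L))
  expect_equal(tags$allele, c("A", "G"))
  expect_equal(nrow(parse_tag_snps(".")), 0L)

  bad <- data.table::copy(ev)
  bad$platform[2] <- "PACBIO"
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(bad[, trioscope:::EVIDENCE_COLS, with = FALSE], tmp2,
                     sep = "\t")
  expect_error(read_read_evidence(tmp2), "platform.*row|row.*platform")
})

test_that("DNM table writer is deterministic, sorted and lossless", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_dnm_table(data.table::data.table(), tmp)
  empty <- readLines(tmp)
  expect_length(empty, 1L)  # header only

  rec <- data.table::data.table(
    chrom = "chr1", pos = c(500L, 500L), ref = "A", alt = "G",
    child_id = c("k2", "k1"), family_id = "f1", variant_type = "SNV",
    validation_status = "VALIDATED", phase = "PATERNAL",
    origin = "GERMLINE")
  write_dnm_table(rec, tmp)
  back <- read_dnm_table(tmp)
  expect_equal(back$child_id, c("k1", "k2"))  # sorted by chrom,pos,child
  expect_equal(back$validation_status, rep("VALIDATED", 2L))
})

test_that("feature BED reader enforces classes and identity bounds", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  bed <- data.table::data.table(chrom = "chr1", start = c(0L, 100L),
                                end = c(50L, 400L),
                                feature_class = c("TR", "SD"),
                                pct_identity = c(NA, 99.5))
  write_feature_bed(bed, tmp)
  back <- read_feature_bed(tmp)
  expect_equal(back$feature_class, c("TR", "SD"))
  expect_equal(back$pct_identity, c(NA, 99.5))

  writeLines("chr1\t10\t20\tBOGUS", tmp)
  expect_error(read_feature_bed(tmp), "feature class")
  writeLines("chr1\t10\t20\tSD\t80", tmp)
  expect_error(read_feature_bed(tmp), "pct_identity")
})

test_that("interval algebra conserves length under the 0-based half-open convention", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    start <- sample(0:1000, n)
    dt <- data.table::data.table(chrom = "c", start = start,
                                 end = start + sample(1:50, n, TRUE))
    red <- trioscope:::reduce_intervals(dt)
    # covered positions identical before/after normalization
    cover <- function(d) sort(unique(unlist(Map(function(s, e) (s + 1):e,
                                                d$start, d$end))))
    expect_equal(cover(red), cover(dt))
    expect_true(all(red$start < red$end))
    # a point is in the track iff strictly inside [start, end)
    expect_true(trioscope:::points_in_track("c", red$start[1] + 1L, red))
    expect_false(trioscope:::points_in_track("c", red$end[nrow(red)] + 1L,
                                             red))
  }
})

test_that("simulated cohort round-trips through its on-disk formats", {
  cfg <- small_preset(seed = 11L)
  cfg$n_families <- 2L
  cfg$n_quads <- 1L
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cfg, out_dir = dir)
  back <- read_cohort(dir)
  expect_equal(back$pedigree$sample_id, co$pedigree$sample_id)
  ev_a <- data.table::as.data.table(co$evidence)
  ev_b <- data.table::as.data.table(back$evidence)
  data.table::setorder(ev_a, chrom, pos, sample_id, platform, read_id)
  data.table::setorder(ev_b, chrom, pos, sample_id, platform, read_id)
  expect_equal(ev_b, ev_a, ignore_attr = TRUE)
  expect_equal(back$truth, co$truth, ignore_attr = TRUE)
  # calls: same genotypes per (site, caller, sample)
  key <- c("chrom", "pos", "ref", "alt", "caller_id", "sample_id")
  a <- data.table::setorderv(co$calls[, c(key, "gt", "gq"), with = FALSE],
                             key)
  b <- data.table::setorderv(back$calls[, c(key, "gt", "gq"), with = FALSE],
                             key)
  expect_equal(b, a, ignore_attr = TRUE)
})
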