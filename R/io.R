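# Readers and writers for all pipeline inputs and outputs.
#
# Conventions enforced at this boundary:
#   * VCF and read-evidence positions are 1-based.
#   * BED feature tracks and callable masks are 0-based half-open.
#   * All tables are returned as data.tables with fixed column order.

PLATFORMS <- c("HIFI", "ONT", "ILLUMINA")
TISSUES <- c("BLOOD", "CELL_LINE")
FEATURE_CLASSES <- c("TR", "RM", "HOMOPOLYMER", "ALU", "LINE", "SINE", "SD",
                     "CENTROMERE", "EXON")

EVIDENCE_COLS <- c("sample_id", "platform", "tissue", "chrom", "pos",
                   "read_id", "mapq", "base_qual", "allele",
                   "flank_left", "flank_right", "tag_snps")

PEDIGREE_COLS <- c("family_id", "sample_id", "father_id", "mother_id",
                   "sex", "role", "father_age_at_birth", "mother_age_at_birth")

# --- pedigree ---------------------------------------------------------------

#' Read and validate a pedigree table
#'
#' The pedigree TSV carries one row per individual with columns
#' `family_id, sample_id, father_id, mother_id, sex, role,
#' father_age_at_birth, mother_age_at_birth`. Parents have missing
#' (`.` or empty) parent ids and ages; children must reference a father and
#' mother present in the same family and carry both parental ages at birth.
#'
#' @param path path to a tab-separated pedigree file with header.
#' @return a validated `data.table` (class `trio_pedigree`), one row per
#'   individual.
#' @export
read_pedigree <- function(path) {
  ped <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = 1:6),
                           na.strings = c(".", "", "NA"))
  missing_cols <- setdiff(PEDIGREE_COLS, names(ped))
  if (length(missing_cols)) {
    stop("pedigree file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ped <- ped[, PEDIGREE_COLS, with = FALSE]
  validate_pedigree(ped)
}

#' @rdname read_pedigree
#' @param ped a pedigree data.table to validate (internal rows checked
#'   against family-structure invariants).
#' @export
validate_pedigree <- function(ped) {
  ped <- data.table::as.data.table(ped)
  if (anyDuplicated(ped$sample_id)) {
    stop_row("duplicate sample_id in pedigree",
             which(duplicated(ped$sample_id))[1L])
  }
  bad_role <- which(!ped$role %in% c("father", "mother", "proband", "sibling"))
  if (length(bad_role)) stop_row("unknown role in pedigree", bad_role[1L])
  bad_sex <- which(!ped$sex %in% c("M", "F"))
  if (length(bad_sex)) stop_row("sex must be M or F", bad_sex[1L])

  is_child <- ped$role %in% c("proband", "sibling")
  for (i in which(is_child)) {
    if (is.na(ped$father_id[i]) || !ped$father_id[i] %in% ped$sample_id ||
        ped$family_id[match(ped$father_id[i], ped$sample_id)] != ped$family_id[i]) {
      stop_row(sprintf("child %s is missing its father in the family",
                       ped$sample_id[i]), i)
    }
    if (is.na(ped$mother_id[i]) || !ped$mother_id[i] %in% ped$sample_id ||
        ped$family_id[match(ped$mother_id[i], ped$sample_id)] != ped$family_id[i]) {
      stop_row(sprintf("child %s is missing its mother in the family",
                       ped$sample_id[i]), i)
    }
    ages <- c(ped$father_age_at_birth[i], ped$mother_age_at_birth[i])
    if (any(is.na(ages)) || any(ages <= 0) || any(ages >= 100)) {
      stop_row(sprintf("child %s has malformed parental ages", ped$sample_id[i]), i)
    }
  }
  fam_check <- ped[, list(
    n_father = sum(role == "father"), n_mother = sum(role == "mother"),
    n_child = sum(role %in% c("proband", "sibling"))), by = family_id]
  bad <- fam_check[fam_check$n_father != 1L | fam_check$n_mother != 1L |
                     fam_check$n_child < 1L, ]
  if (nrow(bad)) {
    stop(sprintf("family %s must have exactly one father, one mother and >=1 child",
                 bad$family_id[1L]), call. = FALSE)
  }
  data.table::setattr(ped, "class", c("trio_pedigree", class(ped)))
  ped[]
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  out <- data.table::as.data.table(ped)[, PEDIGREE_COLS, with = FALSE]
  data.table::fwrite(out, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' Children of a pedigree, with linked parents
#' @param ped a pedigree table.
#' @return data.table with child sample ids, their parents and ages.
#' @export
pedigree_children <- function(ped) {
  ped <- data.table::as.data.table(ped)
  ped[role %in% c("proband", "sibling"),
      list(family_id, child_id = sample_id, father_id, mother_id, sex,
           father_age_at_birth, mother_age_at_birth)]
}

# --- VCF --------------------------------------------------------------------

#' Read a trio/family VCF into a long call table
#'
#' Parses a VCF 4.2 file with per-sample GT and GQ, returning one row per
#' site x alternate allele x sample. Multiallelic records are split into
#' biallelic calls before any downstream rule is applied: allele codes equal
#' to the extracted alternate become 1, all other non-reference codes are
#' recoded to 0. Haploid genotypes ("0", "1") are preserved as written.
#'
#' @param path path to a VCF file.
#' @param pedigree a pedigree table; every VCF sample must appear in it.
#' @param caller_id provenance label stored with each call (defaults to the
#'   VCF `source` header or the file name).
#' @return data.table with columns chrom, pos, ref, alt, caller_id,
#'   sample_id, gt, gq. Records lacking GQ carry `gq = 0` and are counted in
#'   the `n_missing_gq` attribute.
#' @export
read_trio_vcf <- function(path, pedigree, caller_id = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- data.table::as.data.table(vcfR::getFIX(vcf))
  samples <- colnames(vcf@gt)[-1L]
  ped_ids <- data.table::as.data.table(pedigree)$sample_id
  unknown <- setdiff(samples, ped_ids)
  if (length(unknown)) {
    stop("VCF sample(s) absent from pedigree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(caller_id)) {
    src <- grep("^##source=", vcf@meta, value = TRUE)
    caller_id <- if (length(src)) sub("^##source=", "", src[1L]) else basename(path)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ",
                                          as.numeric = TRUE))
  if (is.null(gq)) {
    gq <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  }
  gt <- gt[, samples, drop = FALSE]
  gq <- gq[, samples, drop = FALSE]
  n_missing_gq <- sum(is.na(gq))
  gq[is.na(gq)] <- 0
  ns <- length(samples)
  nv <- nrow(fix)

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  parts <- vector("list", 2L)
  if (any(!multi)) {
    # fast path: biallelic records need no allele recoding
    bi <- which(!multi)
    parts[[1L]] <- data.table::data.table(
      chrom = rep(fix$CHROM[bi], each = ns),
      pos = rep(as.integer(fix$POS[bi]), each = ns),
      ref = rep(toupper(fix$REF[bi]), each = ns),
      alt = rep(toupper(fix$ALT[bi]), each = ns),
      caller_id = caller_id,
      sample_id = rep(samples, times = length(bi)),
      gt = as.vector(t(gt[bi, , drop = FALSE])),
      gq = as.numeric(as.vector(t(gq[bi, , drop = FALSE]))))
  }
  if (any(multi)) {
    out <- vector("list", 0L)
    for (i in which(multi)) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
      for (k in seq_along(alts)) {
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
          ref = toupper(fix$REF[i]), alt = toupper(alts[k]),
          caller_id = caller_id, sample_id = samples,
          gt = recode_gt_for_alt(gt[i, samples], k),
          gq = as.numeric(gq[i, samples]))
      }
    }
    parts[[2L]] <- data.table::rbindlist(out)
  }
  calls <- data.table::rbindlist(Filter(Negate(is.null), parts))
  data.table::setorder(calls, chrom, pos, alt, sample_id)
  data.table::setattr(calls, "n_missing_gq", n_missing_gq)
  calls[]
}

#' Recode GT strings against one extracted alternate allele
#' @keywords internal
recode_gt_for_alt <- function(gt, alt_index) {
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_character_)
    sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
    a <- strsplit(g, "[/|]")[[1L]]
    a2 <- vapply(a, function(x) {
      if (x == ".") return(".")
      code <- as.integer(x)
      if (code == alt_index) "1" else "0"
    }, character(1))
    paste(a2, collapse = if (length(a2) > 1L) sep else "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write a long call table as a minimal VCF 4.2 file
#'
#' Used by the synthetic cohort generator. Sites are emitted biallelic with
#' per-sample GT:GQ.
#'
#' @param calls long call table (chrom, pos, ref, alt, sample_id, gt, gq).
#' @param path output path.
#' @param sample_order sample column order; defaults to sorted unique ids.
#' @param source_id value for the `##source=` header line.
#' @param contigs optional data.table (chrom, length) for contig headers.
#' @export
write_trio_vcf <- function(calls, path, sample_order = NULL,
                           source_id = "trioscope", contigs = NULL) {
  calls <- data.table::as.data.table(calls)
  if (is.null(sample_order)) sample_order <- sort(unique(calls$sample_id))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=", source_id),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">')
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", contigs$chrom,
                          as.integer(contigs$length)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", sample_order),
                      collapse = "\t"))
  if (nrow(calls) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  data.table::setorder(calls, chrom, pos, ref, alt, sample_id)
  wide <- data.table::dcast(calls, chrom + pos + ref + alt ~ sample_id,
                            value.var = c("gt", "gq"))
  data.table::setorder(wide, chrom, pos, ref, alt)
  body_cols <- vapply(sample_order, function(s) {
    g <- wide[[paste0("gt_", s)]]
    q <- wide[[paste0("gq_", s)]]
    ifelse(is.na(g), "./.:.", paste0(g, ":", as.integer(q)))
  }, character(nrow(wide)))
  if (is.null(dim(body_cols))) body_cols <- matrix(body_cols, nrow = nrow(wide))
  body <- paste(wide$chrom, wide$pos, ".", wide$ref, wide$alt, ".", "PASS",
                ".", "GT:GQ", apply(body_cols, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# --- read evidence ----------------------------------------------------------

#' Read a per-read allele-observation table
#'
#' The read-evidence TSV carries one row per read per interrogated site:
#' `sample_id, platform, tissue, chrom, pos, read_id, mapq, base_qual,
#' allele, flank_left, flank_right, tag_snps`. `tag_snps` is a
#' semicolon-joined list of `pos:allele` entries for informative-SNP sites
#' spanned by the read, or `.` when the read spans none.
#'
#' @param path path to the TSV (header required).
#' @return data.table keyed by (chrom, pos).
#' @export
read_read_evidence <- function(path) {
  ev <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c(
                            "sample_id", "platform", "tissue", "chrom",
                            "read_id", "allele", "tag_snps")))
  missing_cols <- setdiff(EVIDENCE_COLS, names(ev))
  if (length(missing_cols)) {
    stop("read-evidence file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ev <- ev[, EVIDENCE_COLS, with = FALSE]
  validate_evidence(ev)
}

#' @rdname read_read_evidence
#' @param ev evidence data.table to validate.
#' @export
validate_evidence <- function(ev) {
  ev <- data.table::as.data.table(ev)
  bad <- which(!ev$platform %in% PLATFORMS)
  if (length(bad)) {
    stop_row(sprintf("unknown platform token '%s'", ev$platform[bad[1L]]),
             bad[1L] + 1L)  # +1: header line
  }
  bad <- which(!ev$tissue %in% TISSUES)
  if (length(bad)) {
    stop_row(sprintf("unknown tissue token '%s'", ev$tissue[bad[1L]]),
             bad[1L] + 1L)
  }
  stopifnot(all(ev$mapq >= 0 & ev$mapq <= 60), all(ev$base_qual >= 0),
            all(ev$flank_left >= 0), all(ev$flank_right >= 0))
  data.table::setkey(ev, chrom, pos)
  ev[]
}

#' @rdname read_read_evidence
#' @export
write_read_evidence <- function(ev, path) {
  out <- data.table::as.data.table(ev)[, EVIDENCE_COLS, with = FALSE]
  data.table::setorder(out, chrom, pos, sample_id, platform, read_id)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Parse semicolon-joined tag-SNP strings into a long table
#'
#' @param tag_snps character vector ("1000:A;1400:G" or ".").
#' @return data.table with `read_row` (index into the input), `snp_pos`,
#'   `allele`. Empty for reads with no tags.
#' @export
parse_tag_snps <- function(tag_snps) {
  has <- !is.na(tag_snps) & tag_snps != "." & nzchar(tag_snps)
  if (!any(has)) {
    return(data.table::data.table(read_row = integer(), snp_pos = integer(),
                                  allele = character()))
  }
  parts <- strsplit(tag_snps[has], ";", fixed = TRUE)
  n <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  colon <- regexpr(":", flat, fixed = TRUE)
  data.table::data.table(
    read_row = rep(which(has), n),
    snp_pos = as.integer(substr(flat, 1L, colon - 1L)),
    allele = substr(flat, colon + 1L, nchar(flat)))
}

#' Serialize tagging SNPs back to the TSV dialect
#' @keywords internal
format_tag_snps <- function(pos, allele) {
  if (length(pos) == 0L) return(".")
  paste(paste0(pos, ":", allele), collapse = ";")
}

# --- feature tracks ---------------------------------------------------------

#' Read a feature BED track
#'
#' BED with 0-based half-open intervals; column 4 is the feature class
#' (TR, RM, HOMOPOLYMER, ALU, LINE, SINE, SD, CENTROMERE, EXON), optional
#' column 5 the percent identity (segmental duplications).
#'
#' @param path BED path (no header).
#' @return data.table(chrom, start, end, feature_class, pct_identity).
#' @export
read_feature_bed <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(bed) < 4L) stop("feature BED needs >=4 columns", call. = FALSE)
  data.table::setnames(bed, seq_len(min(5L, ncol(bed))),
                       c("chrom", "start", "end", "feature_class",
                         "pct_identity")[seq_len(min(5L, ncol(bed)))])
  if (!"pct_identity" %in% names(bed)) bed[, pct_identity := NA_real_]
  bed[, pct_identity := suppressWarnings(as.numeric(pct_identity))]
  bed[, chrom := as.character(chrom)]
  bad <- which(!bed$feature_class %in% FEATURE_CLASSES)
  if (length(bad)) {
    stop_row(sprintf("unknown feature class '%s'", bed$feature_class[bad[1L]]),
             bad[1L])
  }
  stopifnot(all(bed$start < bed$end))
  ok_id <- is.na(bed$pct_identity) |
    (bed$pct_identity >= 90 & bed$pct_identity <= 100)
  if (!all(ok_id)) stop_row("pct_identity outside [90,100]", which(!ok_id)[1L])
  bed[, list(chrom, start = as.integer(start), end = as.integer(end),
             feature_class, pct_identity = as.numeric(pct_identity))]
}

#' @rdname read_feature_bed
#' @param bed feature table to write.
#' @export
write_feature_bed <- function(bed, path) {
  out <- data.table::as.data.table(bed)
  data.table::setorder(out, chrom, start)
  out <- out[, list(chrom, start, end, feature_class,
                    pct_identity = ifelse(is.na(pct_identity), ".",
                                          as.character(pct_identity)))]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- DNM result table -------------------------------------------------------

DNM_TABLE_COLS <- c(
  "chrom", "pos", "ref", "alt", "child_id", "family_id", "variant_type",
  "validation_status", "phase", "origin",
  "nref_HIFI", "nalt_HIFI", "nref_ONT", "nalt_ONT",
  "nref_ILLUMINA", "nalt_ILLUMINA", "mean_ab",
  "hap_nref_HIFI", "hap_nalt_HIFI", "hap_nref_ONT", "hap_nalt_ONT",
  "phase_HIFI", "phase_ONT", "ab_concordant", "ab_p", "pooled_p",
  "ab_prediction", "first_fail")

#' Write the DNM result table
#'
#' Deterministic column order, sorted by (chrom, pos, child_id). All filter
#' provenance (validation status, first failing filter, per-platform counts,
#' phase and origin intermediates) is preserved.
#'
#' @param records DNM record table.
#' @param path output TSV path.
#' @export
write_dnm_table <- function(records, path) {
  rec <- data.table::as.data.table(records)
  if (nrow(rec) == 0L) {
    rec <- data.table::as.data.table(
      stats::setNames(rep(list(character(0)), length(DNM_TABLE_COLS)),
                      DNM_TABLE_COLS))
  }
  for (cc in setdiff(DNM_TABLE_COLS, names(rec))) rec[, (cc) := NA]
  rec <- rec[, DNM_TABLE_COLS, with = FALSE]
  data.table::setorder(rec, chrom, pos, child_id)
  data.table::fwrite(rec, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' @rdname write_dnm_table
#' @export
read_dnm_table <- function(path) {
  rec <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = ".")
  data.table::setorder(rec, chrom, pos, child_id)
  rec[]
}

# --- truth and context tables -----------------------------------------------

#' @rdname write_dnm_table
#' @param truth truth table from the simulator.
#' @export
write_truth_table <- function(truth, path) {
  out <- data.table::as.data.table(truth)
  data.table::setorder(out, chrom, pos, child_id)
  data.table::fwrite(out, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' @rdname write_dnm_table
#' @export
read_truth_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = ".")
}

#' Read/write local reference context strings
#'
#' One row per site: chrom, pos, context. The context string is centered on
#' the variant position (odd length), uppercase DNA.
#' @param path TSV path.
#' @export
read_context_table <- function(path) {
  ctx <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("chrom", "context")))
  data.table::setkey(ctx, chrom, pos)
  ctx[]
}

#' @rdname read_context_table
#' @param ctx context table.
#' @export
write_context_table <- function(ctx, path) {
  out <- data.table::as.data.table(ctx)[, list(chrom, pos, context)]
  data.table::setorder(out, chrom, pos)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
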