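# Three-platform read-evidence validation of candidate de novo variants:
# per-read usability rules, per-platform parent-cleanliness verdicts, the
# two-platform support rule, cohort recurrence, repeat-context allele
# balance filters, the homopolymer filter and cross-platform noise.

#' Filter read observations to those usable for SNV validation
#'
#' Long reads (HiFi, ONT) require mapping quality >= 59; short reads are
#' not filtered on mapping quality. A child's HiFi reads must come from
#' blood; parental HiFi may come from blood or cell lines. Reads with base
#' quality < 10 at the site are discarded, the rest are tiered HIGH
#' (base quality > 20) or LOW (10-20).
#'
#' @param obs evidence data.table rows at the variant site.
#' @param role "child" or "parent".
#' @return the usable subset with a `tier` column.
#' @export
usable_reads <- function(obs, role = c("child", "parent")) {
  role <- match.arg(role)
  obs <- data.table::as.data.table(obs)
  keep <- obs$base_qual >= 10 &
    (obs$platform == "ILLUMINA" | obs$mapq >= 59)
  if (role == "child") {
    keep <- keep & !(obs$platform == "HIFI" & obs$tissue != "BLOOD")
  }
  out <- obs[keep]
  out[, tier := ifelse(base_qual > 20, "HIGH", "LOW")]
  out[]
}

# vectorized usability predicate used by the drivers
usable_flag <- function(platform, tissue, mapq, base_qual, is_child) {
  base_qual >= 10 &
    (platform == "ILLUMINA" | mapq >= 59) &
    !(is_child & platform == "HIFI" & tissue != "BLOOD")
}

#' Per-platform de novo verdict for a candidate SNV
#'
#' A parent is clean when it has fewer than one high-quality and fewer
#' than two low-quality reads with the de novo allele (HiFi, Illumina), or
#' fewer than two high-quality and fewer than three low-quality reads
#' (ONT, which is noisier). The verdict is DENOVO when both parents are
#' clean and the child has at least one read with the de novo allele;
#' INHERITED when either parent is not clean; NODATA when the child has no
#' usable reads; NOSUPPORT when the child has usable reads but none with
#' the de novo allele.
#'
#' @param platform "HIFI", "ONT" or "ILLUMINA" (vectorized).
#' @param child_usable,child_alt usable child read count and usable child
#'   reads carrying the de novo allele.
#' @param father_hq_alt,father_lq_alt,mother_hq_alt,mother_lq_alt parental
#'   de novo-allele read counts split by quality tier.
#' @return character vector of verdicts.
#' @export
platform_verdict_snv <- function(platform, child_usable, child_alt,
                                 father_hq_alt, father_lq_alt,
                                 mother_hq_alt, mother_lq_alt) {
  hq_cap <- ifelse(platform == "ONT", 1L, 0L)
  lq_cap <- ifelse(platform == "ONT", 2L, 1L)
  father_clean <- father_hq_alt <= hq_cap & father_lq_alt <= lq_cap
  mother_clean <- mother_hq_alt <= hq_cap & mother_lq_alt <= lq_cap
  ifelse(child_usable == 0L, "NODATA",
         ifelse(!father_clean | !mother_clean, "INHERITED",
                ifelse(child_alt >= 1L, "DENOVO", "NOSUPPORT")))
}

#' Combine per-platform verdicts into a validation status
#'
#' A variant is INHERITED if it looks inherited on at least one platform,
#' VALIDATED if it is supported (DENOVO) on at least two platforms, and
#' FAILED_SUPPORT otherwise.
#'
#' @param verdicts character vector of per-platform verdicts for one
#'   variant.
#' @return "VALIDATED", "INHERITED" or "FAILED_SUPPORT".
#' @export
combine_verdicts <- function(verdicts) {
  stopifnot(length(verdicts) >= 1L)
  if (any(verdicts == "INHERITED")) return("INHERITED")
  if (sum(verdicts == "DENOVO") >= 2L) return("VALIDATED")
  "FAILED_SUPPORT"
}

#' Cohort recurrence screen
#'
#' Counts unrelated cohort samples (outside the child's family) with at
#' least one usable HiFi read carrying the de novo allele. Outside tandem
#' repeats the variant must be unique to the child (count 0); inside a TR
#' one unrelated carrier is allowed. Sibling carriage never counts.
#'
#' @param candidates candidate table (chrom, pos, alt, child_id,
#'   family_id).
#' @param evidence cohort read-evidence table (keyed chrom, pos).
#' @param pedigree pedigree table.
#' @param tr_track tandem-repeat BED track (or NULL).
#' @return logical vector: TRUE = pass.
#' @export
cohort_recurrence_filter <- function(candidates, evidence, pedigree,
                                     tr_track = NULL) {
  cand <- data.table::as.data.table(candidates)
  if (nrow(cand) == 0L) return(logical())
  ped <- data.table::as.data.table(pedigree)
  fam_of <- stats::setNames(ped$family_id, ped$sample_id)
  ev <- evidence[unique(data.table::data.table(chrom = cand$chrom,
                                               pos = cand$pos)),
                 on = c("chrom", "pos"), nomatch = NULL]
  ev <- ev[platform == "HIFI" & mapq >= 59 & base_qual >= 10]
  carriers <- unique(ev[, list(chrom, pos, allele, sample_id)])
  carriers[, family_id := fam_of[sample_id]]
  tot <- carriers[, list(n_total = .N), by = list(chrom, pos, allele)]
  own <- carriers[, list(n_own = .N),
                  by = list(chrom, pos, allele, family_id)]
  q <- data.table::data.table(chrom = cand$chrom, pos = cand$pos,
                              allele = cand$alt, family_id = cand$family_id)
  n_tot <- tot[q, on = c("chrom", "pos", "allele")]$n_total
  n_own <- own[q, on = c("chrom", "pos", "allele", "family_id")]$n_own
  n_tot[is.na(n_tot)] <- 0L
  n_own[is.na(n_own)] <- 0L
  counts <- n_tot - n_own
  in_tr <- points_in_track(cand$chrom, cand$pos, tr_track)
  ifelse(in_tr, counts <= 1L, counts == 0L)
}

#' Repeat-context allele-balance filters
#'
#' The mean allele balance (AB) is taken over platforms with at least one
#' usable child read. Variants in tandem repeats must have mean AB > 0.05;
#' variants in RepeatMasker regions must exceed 0.10 when also in a TR and
#' 0.08 otherwise.
#'
#' @param mean_ab mean cross-platform allele balance per variant (NA when
#'   no platform has reads).
#' @param in_tr,in_rm logical: variant overlaps a TR / RepeatMasker
#'   interval.
#' @return character vector: "pass" or the failure reason
#'   ("tr_ab", "rm_ab", "nodata").
#' @export
repeat_ab_filters <- function(mean_ab, in_tr, in_rm) {
  ifelse(is.na(mean_ab), "nodata",
         ifelse(in_tr & mean_ab <= 0.05, "tr_ab",
                ifelse(in_rm & mean_ab <= ifelse(in_tr, 0.10, 0.08),
                       "rm_ab", "pass")))
}

#' Homopolymer filter
#'
#' Fails a substitution that lies within, or within 1 bp of, a homopolymer
#' run (length >= 4) when either its reference or alternate allele equals
#' the run base (e.g. an A-to-T substitution on the edge of an A
#' homopolymer). The local reference context must be centered on the
#' variant site; if it is too short to detect a run the variant passes
#' with a warning.
#'
#' @param ref,alt single-base alleles (vectorized).
#' @param context centered reference context strings.
#' @param min_run minimum run length treated as a homopolymer (default 4).
#' @return logical vector: TRUE = pass, FALSE = fail.
#' @export
homopolymer_filter <- function(ref, alt, context, min_run = 4L) {
  n <- length(ref)
  pass <- rep(TRUE, n)
  for (i in seq_len(n)) {
    ctx <- context[i]
    if (is.na(ctx) || nchar(ctx) < min_run) {
      warning("context too short for homopolymer detection; variant passes")
      next
    }
    chars <- strsplit(ctx, "")[[1L]]
    center <- (length(chars) + 1L) %/% 2L
    r <- rle(chars)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$lengths >= min_run)
    for (k in runs) {
      if (center >= starts[k] - 1L && center <= ends[k] + 1L &&
          r$values[k] %in% c(ref[i], alt[i])) {
        pass[i] <- FALSE
        break
      }
    }
  }
  pass
}

#' Cross-platform noise filter
#'
#' A platform is noisy when either parent shows two or more usable reads
#' of a third allele (neither reference nor the de novo allele); the
#' variant fails when two or more platforms are noisy.
#'
#' @param noisy_platforms integer count of noisy platforms per variant.
#' @return logical: TRUE = pass.
#' @export
cross_platform_noise_filter <- function(noisy_platforms) {
  noisy_platforms < 2L
}

#' Multi-allele filter for indels
#'
#' Counts distinct non-reference, non-de novo alleles each supported by at
#' least two usable child reads; the variant fails when two or more such
#' alleles exist (an automated stand-in for visual review of noisy indel
#' pileups).
#'
#' @param child_obs usable child evidence rows at the site.
#' @param ref,alt the variant's alleles.
#' @param max_extra_alleles fail threshold: fail iff the number of
#'   supported third alleles is >= `max_extra_alleles`.
#' @return TRUE = pass.
#' @export
multiallele_filter <- function(child_obs, ref, alt, max_extra_alleles = 2) {
  third <- child_obs$allele[!child_obs$allele %in% c(ref, alt)]
  if (!length(third)) return(TRUE)
  supported <- sum(table(third) >= 2L)
  supported < max_extra_alleles
}

#' Validate a non-TR candidate indel from read evidence
#'
#' Usable reads must have mapping quality 60 on every platform and fully
#' span the site with at least 10 bp of flanking sequence on each side.
#' The variant is INHERITED when any parent or sibling read carries the de
#' novo allele on any platform, VALIDATED when the child carries the
#' allele in both HiFi and Illumina, otherwise FAILED_SUPPORT. A
#' multi-allele screen ([multiallele_filter()]) is applied to validated
#' calls.
#'
#' @param variant one-row data.table/list: chrom, pos, ref, alt, child_id.
#' @param evidence cohort evidence table.
#' @param pedigree pedigree table.
#' @return list(status, child_platforms, n_carrier_reads).
#' @export
validate_indel <- function(variant, evidence, pedigree) {
  ped <- data.table::as.data.table(pedigree)
  children <- pedigree_children(ped)
  kid <- children[children$child_id == variant$child_id, ]
  sibs <- children$child_id[children$family_id == kid$family_id &
                              children$child_id != kid$child_id]
  fam_members <- c(kid$child_id, kid$father_id, kid$mother_id, sibs)
  obs <- evidence[data.table::data.table(chrom = variant$chrom,
                                         pos = variant$pos),
                  on = c("chrom", "pos"), nomatch = NULL]
  obs <- obs[sample_id %in% fam_members & mapq == 60 &
               flank_left >= 10 & flank_right >= 10]
  carrier <- obs[allele == variant$alt]
  other_carriers <- carrier[sample_id != kid$child_id]
  if (nrow(other_carriers) > 0L) {
    return(list(status = "INHERITED",
                child_platforms = character(),
                n_carrier_reads = nrow(other_carriers)))
  }
  child_platforms <- sort(unique(carrier$platform[carrier$sample_id ==
                                                    kid$child_id]))
  status <- if (all(c("HIFI", "ILLUMINA") %in% child_platforms)) {
    child_obs <- obs[sample_id == kid$child_id]
    if (multiallele_filter(child_obs, variant$ref, variant$alt)) "VALIDATED"
    else "FAILED_MULTIALLELE"
  } else "FAILED_SUPPORT"
  list(status = status, child_platforms = child_platforms,
       n_carrier_reads = 0L)
}

#' Validate candidate SNVs against three-platform read evidence
#'
#' Applies, in the documented short-circuit order, the platform-support
#' rule, cohort recurrence, repeat-context AB filters, the homopolymer
#' filter and the cross-platform noise filter, and records per-platform
#' allele counts for every candidate.
#'
#' @param candidates candidate SNV table from [select_candidate_snvs()]
#'   (post [cluster_filter()]).
#' @param evidence cohort read-evidence table (keyed chrom, pos).
#' @param pedigree pedigree table.
#' @param features feature track table (TR and RM classes used), or NULL.
#' @param context context table (chrom, pos, context), or NULL (the
#'   homopolymer filter then passes everything).
#' @return the candidate table with per-platform counts, `mean_ab`,
#'   `validation_status` and `first_fail` columns.
#' @export
validate_snvs <- function(candidates, evidence, pedigree, features = NULL,
                          context = NULL) {
  cand <- data.table::copy(data.table::as.data.table(candidates))
  if (nrow(cand) == 0L) {
    cand[, `:=`(validation_status = character(), first_fail = character(),
                mean_ab = numeric())]
    return(cand)
  }
  cand[, variant_id := .I]
  ped <- data.table::as.data.table(pedigree)
  children <- pedigree_children(ped)
  cand_fam <- merge(cand, children[, list(child_id, father_id, mother_id)],
                    by = "child_id", sort = FALSE)
  data.table::setorder(cand_fam, variant_id)

  # trio evidence at candidate sites
  ev <- evidence[data.table::data.table(chrom = cand_fam$chrom,
                                        pos = cand_fam$pos,
                                        variant_id = cand_fam$variant_id),
                 on = c("chrom", "pos"), nomatch = NULL, allow.cartesian = TRUE]
  vmap <- cand_fam[match(ev$variant_id, cand_fam$variant_id), ]
  who <- ifelse(ev$sample_id == vmap$child_id, "child",
                ifelse(ev$sample_id == vmap$father_id, "father",
                       ifelse(ev$sample_id == vmap$mother_id, "mother", NA)))
  ev <- ev[!is.na(who)]
  vmap <- vmap[!is.na(who), ]
  who <- who[!is.na(who)]
  ev[, `:=`(who = who, ref_a = vmap$ref, alt_a = vmap$alt)]
  ev[, usable := usable_flag(platform, tissue, mapq, base_qual,
                             who == "child")]
  ev <- ev[usable == TRUE]
  ev[, tier := ifelse(base_qual > 20, "HIGH", "LOW")]

  counts <- ev[, list(
    child_usable = sum(who == "child"),
    child_alt = sum(who == "child" & allele == alt_a[1L]),
    child_ref = sum(who == "child" & allele == ref_a[1L]),
    father_hq_alt = sum(who == "father" & allele == alt_a[1L] &
                          tier == "HIGH"),
    father_lq_alt = sum(who == "father" & allele == alt_a[1L] &
                          tier == "LOW"),
    mother_hq_alt = sum(who == "mother" & allele == alt_a[1L] &
                          tier == "HIGH"),
    mother_lq_alt = sum(who == "mother" & allele == alt_a[1L] &
                          tier == "LOW"),
    father_third = sum(who == "father" &
                         !allele %in% c(ref_a[1L], alt_a[1L])),
    mother_third = sum(who == "mother" &
                         !allele %in% c(ref_a[1L], alt_a[1L]))),
    by = list(variant_id, platform)]

  grid <- data.table::CJ(variant_id = cand$variant_id, platform = PLATFORMS)
  counts <- merge(grid, counts, by = c("variant_id", "platform"),
                  all.x = TRUE)
  for (cc in setdiff(names(counts), c("variant_id", "platform"))) {
    data.table::set(counts, which(is.na(counts[[cc]])), cc, 0L)
  }
  counts[, verdict := platform_verdict_snv(platform, child_usable, child_alt,
                                           father_hq_alt, father_lq_alt,
                                           mother_hq_alt, mother_lq_alt)]
  counts[, ab := ifelse(child_usable > 0, child_alt / child_usable, NA_real_)]
  counts[, noisy := father_third >= 2L | mother_third >= 2L]

  agg <- counts[, list(
    support = combine_verdicts(verdict),
    mean_ab = if (all(is.na(ab))) NA_real_ else mean(ab, na.rm = TRUE),
    noisy_platforms = sum(noisy)), by = variant_id]
  wide <- data.table::dcast(counts, variant_id ~ platform,
                            value.var = c("child_ref", "child_alt"))
  data.table::setnames(
    wide,
    c("variant_id",
      paste0("nref_", PLATFORMS[order(PLATFORMS)]),
      paste0("nalt_", PLATFORMS[order(PLATFORMS)])))
  res <- merge(merge(cand, agg, by = "variant_id"), wide, by = "variant_id")

  tr_track <- if (!is.null(features)) features[features$feature_class == "TR", ]
    else NULL
  rm_track <- if (!is.null(features)) features[features$feature_class == "RM", ]
    else NULL
  res[, in_tr := points_in_track(chrom, pos, tr_track)]
  res[, in_rm := points_in_track(chrom, pos, rm_track)]
  recur_pass <- cohort_recurrence_filter(res, evidence, pedigree, tr_track)
  ab_check <- repeat_ab_filters(res$mean_ab, res$in_tr, res$in_rm)
  hp_pass <- if (is.null(context)) rep(TRUE, nrow(res)) else {
    ctx <- context[data.table::data.table(chrom = res$chrom, pos = res$pos),
                   on = c("chrom", "pos"), mult = "first"]$context
    homopolymer_filter(res$ref, res$alt, ctx)
  }
  noise_pass <- cross_platform_noise_filter(res$noisy_platforms)

  # short-circuit order: platform support -> recurrence -> repeat AB ->
  # homopolymer -> noise
  res[, first_fail := data.table::fcase(
    support == "INHERITED", "inherited",
    support == "FAILED_SUPPORT", "platform_support",
    !recur_pass, "recurrence",
    ab_check != "pass", paste0("ab_", ab_check),
    !hp_pass, "homopolymer",
    !noise_pass, "noise",
    default = "")]
  res[, validation_status := data.table::fcase(
    first_fail == "", "VALIDATED",
    first_fail == "inherited", "INHERITED",
    default = paste0("FAILED_",
                     toupper(sub("^ab_", "", first_fail))))]
  data.table::setorder(res, variant_id)
  res[, variant_id := NULL]
  res[]
}
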