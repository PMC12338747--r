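# Naive de novo candidate selection: caller union, trio genotype pattern,
# child genotype-quality filter, clustered-SNV filter, ploidy-aware sex
# chromosome logic and TR/non-TR indel categorization.

#' Union of candidate callsets
#'
#' Deduplicates calls from multiple variant callers by (chrom, pos, alt,
#' sample); caller provenance is retained as a comma-joined `callers`
#' column, and the per-sample genotype/GQ of each contributing caller is
#' kept in the long table so quality filters can be applied per record.
#'
#' @param callsets list of long call tables (as from [read_trio_vcf()]).
#' @return a single long call table with all records; an attribute
#'   `n_unique_sites` counts distinct (chrom, pos, alt) sites.
#' @export
union_callsets <- function(callsets) {
  stopifnot(length(callsets) >= 1L)
  calls <- data.table::rbindlist(callsets, use.names = TRUE, fill = TRUE)
  # identical (site, sample, caller) duplicates collapse to one record
  calls <- unique(calls, by = c("chrom", "pos", "ref", "alt", "caller_id",
                                "sample_id"))
  data.table::setattr(calls, "n_unique_sites",
                      nrow(unique(calls[, list(chrom, pos, alt)])))
  calls[]
}

#' Select candidate de novo SNVs for the children of a pedigree
#'
#' A site is a candidate for a child when both parents are homozygous
#' reference (0/0), the child carries at least one alternate allele, and at
#' least one caller's record gives the child genotype quality >= `gq_min`.
#' Parental genotype quality is not thresholded. Sites with a missing
#' parental genotype are skipped (counted in attribute `n_skipped`).
#'
#' @param calls long call table (possibly multi-caller, post-union).
#' @param pedigree pedigree table.
#' @param gq_min minimum child genotype quality (phred), default 20.
#' @return data.table of candidates: chrom, pos, ref, alt, child_id,
#'   family_id, gq (best over callers), callers, category = "SNV",
#'   sex_chrom_mode = "AUTO".
#' @export
select_candidate_snvs <- function(calls, pedigree, gq_min = 20) {
  calls <- data.table::as.data.table(calls)
  snv <- calls[nchar(ref) == 1L & nchar(alt) == 1L]
  children <- pedigree_children(pedigree)
  out <- vector("list", nrow(children))
  n_skipped <- 0L
  for (i in seq_len(nrow(children))) {
    kid <- children$child_id[i]
    trio <- snv[sample_id %in% c(kid, children$father_id[i],
                                 children$mother_id[i])]
    if (nrow(trio) == 0L) next
    wide <- data.table::dcast(trio, chrom + pos + ref + alt + caller_id ~
                                sample_id, value.var = c("gt", "gq"))
    if (!paste0("gt_", kid) %in% names(wide)) next
    for (cc in paste0(c("gt_", "gq_"),
                      rep(c(children$father_id[i], children$mother_id[i]),
                          each = 2L))) {
      if (!cc %in% names(wide)) wide[, (cc) := NA]
    }
    gt_c <- wide[[paste0("gt_", kid)]]
    gt_f <- wide[[paste0("gt_", children$father_id[i])]]
    gt_m <- wide[[paste0("gt_", children$mother_id[i])]]
    missing_parent <- is.na(gt_f) | is.na(gt_m)
    n_skipped <- n_skipped + sum(missing_parent & !is.na(gt_c) &
                                   gt_has_alt(gt_c))
    keep <- !missing_parent & !is.na(gt_c) &
      gt_is_homref(gt_f) & gt_is_homref(gt_m) & gt_has_alt(gt_c) &
      wide[[paste0("gq_", kid)]] >= gq_min
    keep[is.na(keep)] <- FALSE
    if (!any(keep)) next
    gq_child <- wide[[paste0("gq_", kid)]]
    sel <- wide[keep, list(chrom, pos, ref, alt, caller_id)]
    sel[, gq := gq_child[keep]]
    sel <- sel[, list(gq = max(gq),
                      callers = paste(sort(unique(caller_id)),
                                      collapse = ",")),
               by = list(chrom, pos, ref, alt)]
    sel[, `:=`(child_id = kid, family_id = children$family_id[i])]
    out[[i]] <- sel
  }
  out <- Filter(Negate(is.null), out)
  res <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           gq = numeric(), callers = character(),
                           child_id = character(), family_id = character())
  res[, `:=`(category = "SNV", sex_chrom_mode = "AUTO")]
  data.table::setorder(res, chrom, pos, child_id)
  data.table::setattr(res, "n_skipped", n_skipped)
  res[]
}

#' Clustered-SNV filter
#'
#' Removes candidate SNVs sitting in dense clusters, the signature of a
#' dropped parental haplotype: any SNV that belongs to at least one window
#' of `window_bp` consecutive bases containing `min_count` or more of the
#' same child's candidate SNVs (equivalently, any `min_count` SNVs whose
#' positions span at most `window_bp - 1` bases) is moved to the
#' `clustered` partition. The partition is exhaustive and disjoint and is
#' computed per child per chromosome.
#'
#' @param candidates candidate table (chrom, pos, child_id, ...).
#' @param window_bp sliding window length in bp (default 1000).
#' @param min_count cluster size threshold (default 3).
#' @return list with `kept` and `clustered` data.tables.
#' @export
cluster_filter <- function(candidates, window_bp = 1000, min_count = 3) {
  cand <- data.table::as.data.table(candidates)
  if (nrow(cand) == 0L) return(list(kept = cand, clustered = cand))
  data.table::setorder(cand, child_id, chrom, pos)
  flag <- logical(nrow(cand))
  idx <- cand[, list(rows = list(.I)), by = list(child_id, chrom)]
  for (g in seq_len(nrow(idx))) {
    rows <- idx$rows[[g]]
    p <- cand$pos[rows]
    n <- length(p)
    if (n < min_count) next
    # j = furthest candidate within window of candidate i
    j <- findInterval(p + window_bp - 1L, p)
    for (i in seq_len(n)) {
      if (j[i] - i + 1L >= min_count) flag[rows[i:j[i]]] <- TRUE
    }
  }
  list(kept = cand[!flag], clustered = cand[flag])
}

#' Select candidate de novo variants on the sex chromosomes
#'
#' Ploidy-aware candidate logic: a female child's X is treated like an
#' autosome except the father must be hemizygous reference; a male child's
#' X is compared against the mother only (any child allele absent from the
#' mother's genotype), and his Y against the father only.
#' Pseudoautosomal regions are excluded via the provided BED track.
#'
#' @param calls long call table restricted to sex chromosomes
#'   (chrom names containing "X"/"Y").
#' @param pedigree pedigree table.
#' @param par_track optional BED (0-based half-open) of pseudoautosomal
#'   regions to exclude.
#' @return candidate table with `sex_chrom_mode` one of FEMALE_X, MALE_X,
#'   MALE_Y.
#' @export
select_sex_candidates <- function(calls, pedigree, par_track = NULL) {
  calls <- data.table::as.data.table(calls)
  children <- pedigree_children(pedigree)
  out <- vector("list", 0L)
  for (i in seq_len(nrow(children))) {
    kid <- children$child_id[i]
    fa <- children$father_id[i]
    mo <- children$mother_id[i]
    trio <- calls[sample_id %in% c(kid, fa, mo)]
    if (nrow(trio) == 0L) next
    wide <- data.table::dcast(trio, chrom + pos + ref + alt + caller_id ~
                                sample_id, value.var = c("gt", "gq"))
    if (!paste0("gt_", kid) %in% names(wide)) next
    for (cc in paste0(c("gt_", "gq_"), rep(c(fa, mo), each = 2L))) {
      if (!cc %in% names(wide)) wide[, (cc) := NA]
    }
    gt_c <- wide[[paste0("gt_", kid)]]
    gt_f <- wide[[paste0("gt_", fa)]]
    gt_m <- wide[[paste0("gt_", mo)]]
    is_x <- grepl("X", wide$chrom)
    is_y <- grepl("Y", wide$chrom)
    if (children$sex[i] == "F") {
      if (any(is_y & !is.na(gt_c))) {
        # female Y calls indicate an upstream error; ignore them
      }
      keep <- is_x & !is.na(gt_c) & !is.na(gt_f) & !is.na(gt_m) &
        gt_is_homref(gt_m) & gt_f == "0" & gt_has_alt(gt_c)
      mode <- "FEMALE_X"
    } else {
      if (any(is_y & !is.na(gt_c) & !gt_is_haploid(gt_c))) {
        stop(sprintf("male sample %s has a diploid chrY genotype", kid),
             call. = FALSE)
      }
      keep_x <- is_x & !is.na(gt_c) & !is.na(gt_m) & gt_is_haploid(gt_c) &
        !mapply(function(c1, m1) gt_carries(m1, as.integer(c1)),
                gt_c, gt_m)
      keep_y <- is_y & !is.na(gt_c) & !is.na(gt_f) & gt_is_haploid(gt_c) &
        gt_c != gt_f
      keep <- keep_x | keep_y
      mode <- ifelse(is_x, "MALE_X", "MALE_Y")
    }
    keep[is.na(keep)] <- FALSE
    if (!any(keep)) next
    gq_child <- wide[[paste0("gq_", kid)]]
    sel <- wide[keep, list(chrom, pos, ref, alt, caller_id)]
    sel[, gq := gq_child[keep]]
    sel[, sex_chrom_mode := if (length(mode) == 1L) mode else mode[keep]]
    sel <- sel[, list(gq = max(gq),
                      callers = paste(sort(unique(caller_id)), collapse = ","),
                      sex_chrom_mode = sex_chrom_mode[1L]),
               by = list(chrom, pos, ref, alt)]
    sel[, `:=`(child_id = kid, family_id = children$family_id[i],
               category = ifelse(nchar(ref) == 1L & nchar(alt) == 1L,
                                 "SNV", "INDEL_NONTR"))]
    out[[length(out) + 1L]] <- sel
  }
  if (!length(out)) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  gq = numeric(), callers = character(),
                                  sex_chrom_mode = character(),
                                  child_id = character(),
                                  family_id = character(),
                                  category = character()))
  }
  res <- data.table::rbindlist(out)
  if (!is.null(par_track) && nrow(res)) {
    res <- res[!points_in_track(res$chrom, res$pos, par_track)]
  }
  data.table::setorder(res, chrom, pos, child_id)
  res[]
}

#' Categorize an indel as a tandem-repeat mutation or a plain indel
#'
#' An insertion/deletion is an `INDEL_TR` when it overlaps a tandem-repeat
#' interval and the inserted or deleted sequence is a whole number of
#' copies of the repeat motif (one or more subunits added or subtracted);
#' anything else is `INDEL_NONTR`.
#'
#' @param ref,alt VCF-style ref/alt alleles sharing a leading anchor base.
#' @param chrom,pos variant location (1-based).
#' @param tr_track tandem-repeat BED with a `motif` column, or with the
#'   motif encoded in `feature_class` metadata; if no motif column exists
#'   the function falls back to testing whether the indel sequence is
#'   itself a tandem concatemer of some unit whose repeats cover the
#'   interval.
#' @return "INDEL_TR" or "INDEL_NONTR" (vectorized over variants).
#' @export
classify_indel_category <- function(ref, alt, chrom, pos, tr_track) {
  n <- length(ref)
  out <- rep("INDEL_NONTR", n)
  in_tr <- points_in_track(chrom, pos, tr_track)
  motifs <- if (!is.null(tr_track$motif)) tr_track$motif else NULL
  for (i in which(in_tr)) {
    long <- if (nchar(ref[i]) > nchar(alt[i])) ref[i] else alt[i]
    short <- if (nchar(ref[i]) > nchar(alt[i])) alt[i] else ref[i]
    if (!startsWith(long, short)) next
    inserted <- substr(long, nchar(short) + 1L, nchar(long))
    tr_idx <- which(tr_track$chrom == chrom[i] &
                      tr_track$start < pos[i] & tr_track$end >= pos[i])
    if (!length(tr_idx)) next
    motif <- if (!is.null(motifs)) motifs[tr_idx[1L]] else NA_character_
    if (is.na(motif) || !nzchar(motif)) {
      # infer candidate motif as the shortest period of the indel sequence
      motif <- inserted
      for (k in seq_len(nchar(inserted))) {
        unit <- substr(inserted, 1L, k)
        if (nchar(inserted) %% k == 0L &&
            paste(rep(unit, nchar(inserted) / k), collapse = "") == inserted) {
          motif <- unit
          break
        }
      }
    }
    m <- nchar(motif)
    if (m > 0L && nchar(inserted) %% m == 0L &&
        paste(rep(motif, nchar(inserted) / m), collapse = "") == inserted) {
      out[i] <- "INDEL_TR"
    }
  }
  out
}
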