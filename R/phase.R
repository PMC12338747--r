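# Parent-of-origin phasing. Each validated DNM is assigned to a parental
# haplotype by scoring the child's long reads against informative SNPs in
# a window around the mutation, with an inverse-distance weighted
# inheritance score; HiFi assignments take precedence and ONT rescues
# variants HiFi cannot phase.

#' Find informative SNPs around a de novo mutation
#'
#' An informative SNP is a biallelic site where the child is heterozygous
#' and exactly one assignment of {alternate allele, reference allele} to
#' the two parents is consistent with the parental genotypes (for example
#' one parent 0/0, the other 0/1 or 1/1, child 0/1). The SNP then tags the
#' donor parent's haplotype with `tag_allele` and the other parent's with
#' `other_allele`.
#'
#' @param trio_calls long call table for one trio (father, mother, child
#'   rows; multiple callers are deduplicated by site).
#' @param child_id,father_id,mother_id sample ids.
#' @param dnm_chrom,dnm_pos the mutation site (excluded from the result).
#' @param window_bp total window width centered on the mutation
#'   (default 80000).
#' @return data.table(pos, donor ("P"/"M"), tag_allele, other_allele).
#' @export
find_informative_snps <- function(trio_calls, child_id, father_id, mother_id,
                                  dnm_chrom, dnm_pos, window_bp = 80000) {
  calls <- data.table::as.data.table(trio_calls)
  calls <- calls[chrom == dnm_chrom & abs(pos - dnm_pos) <= window_bp / 2 &
                   pos != dnm_pos & nchar(ref) == 1L & nchar(alt) == 1L]
  if (nrow(calls) == 0L) {
    return(data.table::data.table(pos = integer(), donor = character(),
                                  tag_allele = character(),
                                  other_allele = character()))
  }
  calls <- unique(calls, by = c("pos", "alt", "sample_id"))
  wide <- data.table::dcast(calls, pos + ref + alt ~ sample_id,
                            value.var = "gt",
                            fun.aggregate = function(x) x[1L])
  for (s in c(child_id, father_id, mother_id)) {
    if (!s %in% names(wide)) wide[, (s) := NA_character_]
  }
  inf <- informative_pattern(wide[[child_id]], wide[[father_id]],
                             wide[[mother_id]])
  out <- data.table::data.table(pos = wide$pos, donor = inf$donor,
                                tag_allele = ifelse(inf$donor_gave_alt,
                                                    wide$alt, wide$ref),
                                other_allele = ifelse(inf$donor_gave_alt,
                                                      wide$ref, wide$alt))
  out[!is.na(out$donor)]
}

# Vectorized informativeness: child must be 0/1; consider the two
# assignments (father->alt, mother->ref) and (father->ref, mother->alt);
# informative iff exactly one is consistent with the parental genotypes.
informative_pattern <- function(gt_c, gt_f, gt_m) {
  ok <- !is.na(gt_c) & !is.na(gt_f) & !is.na(gt_m) &
    gt_c %in% c("0/1", "1/0", "0|1", "1|0")
  f_has_alt <- gt_carries(gt_f, 1L)
  f_has_ref <- gt_carries(gt_f, 0L)
  m_has_alt <- gt_carries(gt_m, 1L)
  m_has_ref <- gt_carries(gt_m, 0L)
  a_valid <- f_has_alt & m_has_ref  # father gave alt
  b_valid <- f_has_ref & m_has_alt  # mother gave alt
  informative <- ok & (a_valid != b_valid)
  donor <- rep(NA_character_, length(gt_c))
  donor[informative & a_valid] <- "P"
  donor[informative & b_valid] <- "M"
  list(donor = donor, donor_gave_alt = !is.na(donor))
}

#' Inverse-distance-weighted read inheritance score
#'
#' Each informative SNP spanned by the read contributes +1 when the read
#' carries the maternal-haplotype allele at that SNP and -1 for the
#' paternal allele (a read allele matching neither parental allele is a
#' base-call error and contributes nothing); contributions are averaged
#' with weights 1/max(1, distance to the mutation site). A negative score
#' marks a paternally inherited read, positive maternal; a read spanning
#' no informative SNP, or scoring exactly zero, is undetermined (NA).
#'
#' @param read_tag_pos,read_tag_allele the read's observed alleles at
#'   tagging-SNP positions.
#' @param snps informative-SNP table from [find_informative_snps()].
#' @param dnm_pos mutation position.
#' @return numeric score in \[-1, 1\], or NA when undetermined.
#' @export
read_inheritance_score <- function(read_tag_pos, read_tag_allele, snps,
                                   dnm_pos) {
  if (!length(read_tag_pos) || nrow(snps) == 0L) return(NA_real_)
  m <- match(read_tag_pos, snps$pos)
  keep <- !is.na(m)
  if (!any(keep)) return(NA_real_)
  m <- m[keep]
  obs <- read_tag_allele[keep]
  p <- read_tag_pos[keep]
  donor_sign <- ifelse(snps$donor[m] == "M", 1, -1)
  v <- ifelse(obs == snps$tag_allele[m], donor_sign,
              ifelse(obs == snps$other_allele[m], -donor_sign, NA))
  w <- 1 / pmax(1, abs(p - dnm_pos))
  keep2 <- !is.na(v)
  if (!any(keep2)) return(NA_real_)
  s <- sum(w[keep2] * v[keep2]) / sum(w[keep2])
  if (s == 0) NA_real_ else s
}

#' Phase one DNM on one platform
#'
#' Scores every usable child read (validation read filters plus base
#' quality >= 20 at the mutation site) and applies the all-on-one-parent
#' rule: PATERNAL/MATERNAL when every read carrying the de novo allele
#' scores to that parent, CONFLICT when de novo reads score to both
#' parents, UNPHASED when no de novo read can be scored. Per-haplotype
#' reference/alternate counts over all scored reads are tallied for the
#' origin classifier.
#'
#' @param obs usable child evidence rows at the site (one platform).
#' @param snps informative-SNP table.
#' @param dnm_ref,dnm_alt,dnm_pos the mutation.
#' @return list(assignment, n_pat_alt, n_mat_alt, hap_counts) where
#'   hap_counts is a named list P/M of c(n_ref, n_alt).
#' @export
phase_dnm <- function(obs, snps, dnm_ref, dnm_alt, dnm_pos) {
  obs <- data.table::as.data.table(obs)
  obs <- obs[base_qual >= 20]
  if (nrow(obs) == 0L || nrow(snps) == 0L) {
    return(list(assignment = "UNPHASED", n_pat_alt = 0L, n_mat_alt = 0L,
                hap_counts = list(P = c(0L, 0L), M = c(0L, 0L))))
  }
  tags <- parse_tag_snps(obs$tag_snps)
  scores <- rep(NA_real_, nrow(obs))
  if (nrow(tags)) {
    for (r in unique(tags$read_row)) {
      sel <- tags[tags$read_row == r, ]
      scores[r] <- read_inheritance_score(sel$snp_pos, sel$allele, snps,
                                          dnm_pos)
    }
  }
  assign <- ifelse(is.na(scores), NA,
                   ifelse(scores < 0, "P", "M"))
  is_alt <- obs$allele == dnm_alt
  n_pat_alt <- sum(assign == "P" & is_alt, na.rm = TRUE)
  n_mat_alt <- sum(assign == "M" & is_alt, na.rm = TRUE)
  assignment <- if (n_pat_alt > 0L && n_mat_alt > 0L) "CONFLICT"
    else if (n_pat_alt > 0L) "PATERNAL"
    else if (n_mat_alt > 0L) "MATERNAL"
    else "UNPHASED"
  hap_counts <- lapply(c(P = "P", M = "M"), function(h) {
    c(sum(assign == h & obs$allele == dnm_ref, na.rm = TRUE),
      sum(assign == h & is_alt, na.rm = TRUE))
  })
  list(assignment = assignment, n_pat_alt = n_pat_alt,
       n_mat_alt = n_mat_alt, hap_counts = hap_counts)
}

#' Merge HiFi and ONT phase assignments
#'
#' HiFi is preferred when it produced an assignment; ONT rescues variants
#' HiFi left unphased or in conflict. When informative SNPs were present
#' but neither platform could assign a haplotype, the variant is excluded
#' from the final callset (treated as a sequencing error); with no
#' informative SNPs it is retained unphased.
#'
#' @param hifi,ont assignment strings ("PATERNAL", "MATERNAL", "UNPHASED",
#'   "CONFLICT"), vectorized.
#' @param has_tagging_snps logical: informative SNPs existed in the window.
#' @return "PATERNAL", "MATERNAL", "UNPHASED" or "EXCLUDE".
#' @export
merge_phase <- function(hifi, ont, has_tagging_snps) {
  assigned <- c("PATERNAL", "MATERNAL")
  ifelse(hifi %in% assigned, hifi,
         ifelse(ont %in% assigned, ont,
                ifelse(has_tagging_snps, "EXCLUDE", "UNPHASED")))
}

#' Phase all validated SNVs (vectorized driver)
#'
#' @param validated validated SNV table (from [validate_snvs()], rows with
#'   `validation_status == "VALIDATED"`).
#' @param calls cohort long call table (used to derive informative SNPs).
#' @param evidence cohort read-evidence table.
#' @param pedigree pedigree table.
#' @param window_bp phasing window (default 80000).
#' @return the input with columns phase_HIFI, phase_ONT, phase, and
#'   per-platform per-origin-haplotype counts hap_nref_HIFI, hap_nalt_HIFI,
#'   hap_nref_ONT, hap_nalt_ONT.
#' @export
phase_validated <- function(validated, calls, evidence, pedigree,
                            window_bp = 80000) {
  v <- data.table::copy(data.table::as.data.table(validated))
  if (nrow(v) == 0L) {
    v[, `:=`(phase_HIFI = character(), phase_ONT = character(),
             phase = character(), hap_nref_HIFI = integer(),
             hap_nalt_HIFI = integer(), hap_nref_ONT = integer(),
             hap_nalt_ONT = integer())]
    return(v)
  }
  v[, variant_id := .I]
  ped <- data.table::as.data.table(pedigree)
  children <- pedigree_children(ped)
  calls <- data.table::as.data.table(calls)

  # informative SNPs per (family, child) over all family SNV calls
  inf_list <- vector("list", nrow(children))
  snv_calls <- calls[nchar(ref) == 1L & nchar(alt) == 1L]
  for (i in seq_len(nrow(children))) {
    kid <- children$child_id[i]
    trio <- snv_calls[sample_id %in% c(kid, children$father_id[i],
                                       children$mother_id[i])]
    if (nrow(trio) == 0L) next
    trio <- unique(trio, by = c("chrom", "pos", "alt", "sample_id"))
    wide <- data.table::dcast(trio, chrom + pos + ref + alt ~ sample_id,
                              value.var = "gt",
                              fun.aggregate = function(x) x[1L])
    need <- c(kid, children$father_id[i], children$mother_id[i])
    if (!all(need %in% names(wide))) next
    inf <- informative_pattern(wide[[kid]],
                               wide[[children$father_id[i]]],
                               wide[[children$mother_id[i]]])
    sel <- !is.na(inf$donor)
    if (!any(sel)) next
    inf_list[[i]] <- data.table::data.table(
      child_id = kid, chrom = wide$chrom[sel], snp_pos = wide$pos[sel],
      donor = inf$donor[sel],
      tag_allele = wide$alt[sel], other_allele = wide$ref[sel])
  }
  inf_snps <- data.table::rbindlist(Filter(Negate(is.null), inf_list))

  # usable long child reads at validated sites, base quality >= 20
  ev <- evidence[unique(data.table::data.table(chrom = v$chrom,
                                               pos = v$pos)),
                 on = c("chrom", "pos"), nomatch = NULL,
                 allow.cartesian = TRUE]
  ev <- ev[platform %in% c("HIFI", "ONT") & mapq >= 59 & base_qual >= 20 &
             !(platform == "HIFI" & tissue != "BLOOD")]
  ev <- ev[v[, list(chrom, pos, child_id, ref, alt, variant_id)],
           on = c("chrom", "pos", sample_id = "child_id"), nomatch = NULL,
           allow.cartesian = TRUE]
  has_tags_tbl <- v[, list(variant_id, chrom, child_id,
                           lo = pos - window_bp / 2,
                           hi = pos + window_bp / 2)]
  if (nrow(inf_snps)) {
    win <- inf_snps[has_tags_tbl,
                    on = c("child_id", "chrom", "snp_pos>=lo",
                           "snp_pos<=hi"),
                    nomatch = NULL, allow.cartesian = TRUE]
    has_tags <- v$variant_id %in% win$variant_id
  } else {
    has_tags <- rep(FALSE, nrow(v))
  }

  read_assign <- NULL
  if (nrow(ev)) {
    ev[, read_row := .I]
    tags <- parse_tag_snps(ev$tag_snps)
    if (nrow(tags)) {
      tags[, `:=`(variant_id = ev$variant_id[read_row],
                  child_id = ev$sample_id[read_row],
                  chrom = ev$chrom[read_row],
                  dnm_pos = ev$pos[read_row])]
      tags <- tags[abs(snp_pos - dnm_pos) <= window_bp / 2]
      scored <- merge(tags, inf_snps,
                      by = c("child_id", "chrom", "snp_pos"),
                      sort = FALSE)
      if (nrow(scored)) {
        scored[, v := ifelse(allele == tag_allele,
                             ifelse(donor == "M", 1, -1),
                             ifelse(allele == other_allele,
                                    ifelse(donor == "M", -1, 1), NA_real_))]
        scored <- scored[!is.na(v)]
        scored[, w := 1 / pmax(1, abs(snp_pos - dnm_pos))]
        read_assign <- scored[, list(score = sum(w * v) / sum(w)),
                              by = read_row]
      }
    }
  }
  ev[, score := NA_real_]
  if (!is.null(read_assign) && nrow(read_assign)) {
    ev[read_assign$read_row, score := read_assign$score]
  }
  ev[, assignment := ifelse(is.na(score) | score == 0, NA_character_,
                            ifelse(score < 0, "P", "M"))]
  ev[, is_alt := allele == alt]

  pp <- ev[, list(
    n_pat_alt = sum(assignment == "P" & is_alt, na.rm = TRUE),
    n_mat_alt = sum(assignment == "M" & is_alt, na.rm = TRUE),
    nref_P = sum(assignment == "P" & allele == ref, na.rm = TRUE),
    nalt_P = sum(assignment == "P" & is_alt, na.rm = TRUE),
    nref_M = sum(assignment == "M" & allele == ref, na.rm = TRUE),
    nalt_M = sum(assignment == "M" & is_alt, na.rm = TRUE)),
    by = list(variant_id, platform)]
  pp[, assignment := ifelse(n_pat_alt > 0L & n_mat_alt > 0L, "CONFLICT",
                            ifelse(n_pat_alt > 0L, "PATERNAL",
                                   ifelse(n_mat_alt > 0L, "MATERNAL",
                                          "UNPHASED")))]

  grid <- data.table::CJ(variant_id = v$variant_id,
                         platform = c("HIFI", "ONT"))
  pp <- merge(grid, pp, by = c("variant_id", "platform"), all.x = TRUE)
  pp[is.na(assignment), assignment := "UNPHASED"]
  for (cc in c("n_pat_alt", "n_mat_alt", "nref_P", "nalt_P", "nref_M",
               "nalt_M")) {
    data.table::set(pp, which(is.na(pp[[cc]])), cc, 0L)
  }
  wide <- data.table::dcast(pp, variant_id ~ platform,
                            value.var = c("assignment", "nref_P", "nalt_P",
                                          "nref_M", "nalt_M"))
  res <- merge(v, wide, by = "variant_id")
  data.table::setnames(res, c("assignment_HIFI", "assignment_ONT"),
                       c("phase_HIFI", "phase_ONT"))
  res[, phase := merge_phase(phase_HIFI, phase_ONT, has_tags)]

  # per-platform haplotype counts on the final origin haplotype
  hap <- ifelse(res$phase == "PATERNAL", "P",
                ifelse(res$phase == "MATERNAL", "M", NA))
  pick <- function(prefix, plat) {
    ifelse(is.na(hap), NA_integer_,
           ifelse(hap == "P", res[[paste0(prefix, "_P_", plat)]],
                  res[[paste0(prefix, "_M_", plat)]]))
  }
  res[, `:=`(hap_nref_HIFI = pick("nref", "HIFI"),
             hap_nalt_HIFI = pick("nalt", "HIFI"),
             hap_nref_ONT = pick("nref", "ONT"),
             hap_nalt_ONT = pick("nalt", "ONT"))]
  drop_cols <- grep("^(nref|nalt)_[PM]_(HIFI|ONT)$", names(res), value = TRUE)
  res[, (drop_cols) := NULL]
  res[, variant_id := NULL]
  res[]
}
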