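# Callable-genome accounting and mutation-rate estimation. A site is
# callable for a trio when a DNM arising there could have been discovered:
# both parents genotyped homozygous reference (autosomes and the female X)
# and every relevant member covered by at least one high-quality HiFi read
# with a high-quality base call. Rates divide mutation counts by the
# ploidy-adjusted callable length; confidence intervals bootstrap over
# children.

#' Compute a per-trio callable mask
#'
#' @param trio_genotypes base-resolution genotype table (chrom, pos,
#'   sample_id, gt) covering the assayed positions for the trio.
#' @param evidence read-evidence table (HiFi reads are used; mapq >= 59
#'   and base quality >= 20 required; child reads blood-only, parental
#'   reads blood or cell line).
#' @param pedigree pedigree table.
#' @param child_id the child whose mask is computed.
#' @return a `callable_mask` data.table (child_id, chrom, start, end;
#'   0-based half-open) with attribute `total_bp` per chromosome class
#'   (autosome, chrX, chrY) and `n_missing_genotype` counting sites
#'   skipped for a missing parental genotype.
#' @export
compute_callable_mask <- function(trio_genotypes, evidence, pedigree,
                                  child_id) {
  gts <- data.table::as.data.table(trio_genotypes)
  children <- pedigree_children(pedigree)
  idx <- match(child_id, children$child_id)
  if (is.na(idx)) stop("unknown child_id", call. = FALSE)
  kid <- children[idx]
  fa <- kid$father_id; mo <- kid$mother_id

  wide <- data.table::dcast(gts[sample_id %in% c(child_id, fa, mo)],
                            chrom + pos ~ sample_id, value.var = "gt",
                            fun.aggregate = function(x) x[1L])
  for (s in c(fa, mo)) if (!s %in% names(wide)) wide[, (s) := NA_character_]

  ev <- data.table::as.data.table(evidence)
  ev <- ev[platform == "HIFI" & mapq >= 59 & base_qual >= 20]
  has_read <- function(sid, blood_only = FALSE) {
    sub <- ev[sample_id == sid]
    if (blood_only) sub <- sub[tissue == "BLOOD"]
    key <- unique(sub[, list(chrom, pos)])
    !is.na(key[wide, on = c("chrom", "pos"), which = TRUE])
  }
  child_cov <- has_read(child_id, blood_only = TRUE)
  father_cov <- has_read(fa)
  mother_cov <- has_read(mo)

  is_x <- grepl("X", wide$chrom)
  is_y <- grepl("Y", wide$chrom)
  gt_f <- wide[[fa]]; gt_m <- wide[[mo]]
  missing_par <- is.na(gt_f) | is.na(gt_m)

  callable <- logical(nrow(wide))
  auto_like <- !is_y & !(is_x & kid$sex == "M")
  callable[auto_like] <- (!missing_par & gt_is_homref(gt_f) &
                            gt_is_homref(gt_m) & child_cov & father_cov &
                            mother_cov)[auto_like]
  if (kid$sex == "M") {
    # parental genotype not restricted on male sex chromosomes; only the
    # transmitting parent's coverage is required
    callable[is_x] <- (child_cov & mother_cov)[is_x]
    callable[is_y] <- (child_cov & father_cov)[is_y]
  }

  sel <- wide[callable, list(chrom, pos)]
  mask <- if (nrow(sel)) {
    data.table::rbindlist(lapply(split(sel, sel$chrom), function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(start = d$pos, width = 1L))
      data.table::data.table(chrom = d$chrom[1L],
                             start = IRanges::start(ir) - 1L,
                             end = IRanges::end(ir))
    }))
  } else data.table::data.table(chrom = character(), start = integer(),
                                end = integer())
  mask[, child_id := child_id]
  data.table::setcolorder(mask, c("child_id", "chrom", "start", "end"))
  data.table::setorder(mask, chrom, start)
  cls <- ifelse(grepl("Y", mask$chrom), "chrY",
                ifelse(grepl("X", mask$chrom), "chrX", "autosome"))
  total_bp <- vapply(split(as.numeric(mask$end - mask$start), cls), sum,
                     numeric(1))
  data.table::setattr(mask, "total_bp", total_bp)
  data.table::setattr(mask, "n_missing_genotype",
                      sum(missing_par & auto_like))
  data.table::setattr(mask, "class", c("callable_mask", class(mask)))
  mask[]
}

#' Mutation rate with bootstrap confidence interval
#'
#' rate = n_mutations / (ploidy_factor x callable_bp), with a
#' nonparametric bootstrap over children for the 95% interval (children
#' are the resampling unit so between-child variance, including age
#' effects, propagates into the interval).
#'
#' @param dnms DNM table (must carry `child_id`; one row per mutation).
#' @param mask callable mask table (child_id, chrom, start, end) covering
#'   every child in scope.
#' @param ploidy_factor 2 for autosomes and the female X; 1 for the
#'   haploid male sex chromosomes (whose callable lengths are summed).
#' @param bootstrap_reps bootstrap replicates (default 10000).
#' @param conf_level interval coverage (default 0.95).
#' @return a `rate_estimate` list: n_mutations, callable_bp,
#'   ploidy_factor, rate, ci_low, ci_high.
#' @export
mutation_rate <- function(dnms, mask, ploidy_factor = 2,
                          bootstrap_reps = 10000, conf_level = 0.95) {
  dnms <- data.table::as.data.table(dnms)
  mask <- data.table::as.data.table(mask)
  per_bp <- mask[, list(bp = sum(as.numeric(end - start))), by = child_id]
  if (nrow(per_bp) == 0L || sum(per_bp$bp) == 0) {
    stop("callable length is zero", call. = FALSE)
  }
  per_n <- dnms[, list(n = .N), by = child_id]
  per <- merge(per_bp, per_n, by = "child_id", all.x = TRUE)
  per[is.na(per$n), n := 0L]
  n <- sum(per$n)
  bp <- sum(per$bp)
  rate <- n / (ploidy_factor * bp)
  k <- nrow(per)
  if (k > 1L) {
    idx <- matrix(sample.int(k, k * bootstrap_reps, replace = TRUE),
                  nrow = bootstrap_reps)
    ns <- matrix(per$n[idx], nrow = bootstrap_reps)
    bps <- matrix(per$bp[idx], nrow = bootstrap_reps)
    reps <- rowSums(ns) / (ploidy_factor * rowSums(bps))
    qs <- stats::quantile(reps, c((1 - conf_level) / 2,
                                  1 - (1 - conf_level) / 2), names = FALSE)
  } else {
    qs <- c(rate, rate)
  }
  structure(list(n_mutations = n, callable_bp = bp,
                 ploidy_factor = ploidy_factor, rate = rate,
                 ci_low = min(qs[1L], rate), ci_high = max(qs[2L], rate)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate %.3e per bp per generation (%d mutations / %s bp x %d)\n",
              x$rate, x$n_mutations, format(x$callable_bp, big.mark = ","),
              x$ploidy_factor))
  cat(sprintf("  95%% CI [%.3e, %.3e]\n", x$ci_low, x$ci_high))
  invisible(x)
}

#' Feature-stratified mutation rates
#'
#' Intersects each child's callable mask and DNMs with a feature class
#' (optionally binned by percent identity for segmental duplications) and
#' computes rate = mutations in feature / (ploidy_factor x callable bp in
#' feature). A DNM belongs to a feature iff its 0-based position lies in
#' [start, end).
#'
#' @param dnms DNM table (chrom, pos, child_id).
#' @param mask callable mask (child_id, chrom, start, end).
#' @param features feature track table.
#' @param feature_class class to stratify ("SD", "TR", ...).
#' @param id_bins optional numeric cut points for pct_identity bins, e.g.
#'   `c(90, 98, 99, 100)`.
#' @param per_sample return one row per child per bin instead of pooled.
#' @param ploidy_factor see [mutation_rate()].
#' @return data.table with bin, n, callable_bp, rate (NA when the
#'   intersection is empty).
#' @export
feature_rate <- function(dnms, mask, features, feature_class,
                         id_bins = NULL, per_sample = FALSE,
                         ploidy_factor = 2) {
  dnms <- data.table::as.data.table(dnms)
  mask <- data.table::as.data.table(mask)
  feats <- data.table::as.data.table(features)
  feats <- feats[feats$feature_class == feature_class, ]
  if (!is.null(id_bins)) {
    feats[, bin := as.character(cut(pct_identity, id_bins,
                                    include.lowest = TRUE))]
  } else {
    feats[, bin := feature_class]
  }
  out <- vector("list", 0L)
  for (b in unique(feats$bin)) {
    fb <- feats[feats$bin == b, ]
    for (kid in unique(mask$child_id)) {
      mk <- mask[mask$child_id == kid, list(chrom, start, end)]
      inter <- intersect_intervals(mk, fb[, list(chrom, start, end)])
      bp <- interval_bp(inter)
      dk <- dnms[dnms$child_id == kid, ]
      n <- if (nrow(dk)) sum(points_in_track(dk$chrom, dk$pos, inter))
        else 0L
      out[[length(out) + 1L]] <- data.table::data.table(
        bin = b, child_id = kid, n = n, callable_bp = bp,
        rate = if (bp > 0) n / (ploidy_factor * bp) else NA_real_)
    }
  }
  res <- data.table::rbindlist(out)
  if (per_sample) return(res[])
  res[, list(n = sum(n), callable_bp = sum(callable_bp),
             rate = if (sum(callable_bp) > 0)
               sum(n) / (ploidy_factor * sum(callable_bp)) else NA_real_),
      by = bin]
}

#' Compare per-sample feature rates against genome-wide rates
#'
#' Paired t-test per feature of each child's feature rate against its
#' genome-wide rate, with Benjamini-Hochberg correction across features.
#'
#' @param feature_rates data.table (feature, child_id, rate) — one row per
#'   child per feature.
#' @param genome_rates data.table (child_id, rate).
#' @return data.table (feature, t, p, p_BH).
#' @export
compare_rates <- function(feature_rates, genome_rates) {
  fr <- data.table::as.data.table(feature_rates)
  gr <- data.table::as.data.table(genome_rates)
  if (data.table::uniqueN(gr$child_id) < 2L) {
    stop("need at least 2 samples for rate comparison", call. = FALSE)
  }
  out <- vector("list", 0L)
  for (f in unique(fr$feature)) {
    sub <- merge(fr[fr$feature == f, list(child_id, feat_rate = rate)],
                 gr[, list(child_id, genome_rate = rate)], by = "child_id")
    sub <- sub[stats::complete.cases(sub), ]
    d <- sub$feat_rate - sub$genome_rate
    if (length(d) < 2L || all(d == 0)) {
      out[[length(out) + 1L]] <- data.table::data.table(
        feature = f, t = 0, p = 1)
      next
    }
    tt <- stats::t.test(sub$feat_rate, sub$genome_rate, paired = TRUE)
    out[[length(out) + 1L]] <- data.table::data.table(
      feature = f, t = unname(tt$statistic), p = tt$p.value)
  }
  res <- data.table::rbindlist(out)
  res[, p_BH := stats::p.adjust(p, method = "BH")]
  res[]
}
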