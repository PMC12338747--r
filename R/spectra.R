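# Mutational spectra and cohort statistics: 7-class pyrimidine-collapsed
# substitution spectrum with CpG>TpG split out, Ti/Tv, parental-age
# regression, parent-of-origin ratio tests, germline-vs-postzygotic
# spectrum comparison and multinucleotide-mutation (MnM) pair detection.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a single-base substitution into the 7-class spectrum
#'
#' Substitutions are collapsed to an A- or C-reference representation via
#' reverse complement (G>A is C>T on the other strand, etc.). A C>T
#' substitution is CpG>TpG when the mutated C is followed by G on its
#' strand — after collapsing, a G>A preceded by C also qualifies.
#'
#' @param ref,alt single bases (vectorized).
#' @param prev_base,next_base reference bases immediately 5' and 3' of the
#'   site.
#' @return factor-like character vector over
#'   A>C, A>G, A>T, C>A, C>G, C>T, CpG>TpG.
#' @export
classify_substitution <- function(ref, alt, prev_base, next_base) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L)) {
    stop("classify_substitution needs single-base substitutions",
         call. = FALSE)
  }
  flip <- ref %in% c("G", "T")
  r <- ifelse(flip, COMPLEMENT[ref], ref)
  a <- ifelse(flip, COMPLEMENT[alt], alt)
  # on the collapsed strand the "next" base of a flipped site is the
  # complement of the original previous base
  nxt <- ifelse(flip, COMPLEMENT[prev_base], next_base)
  cls <- paste0(r, ">", a)
  ifelse(cls == "C>T" & nxt == "G", "CpG>TpG", cls)
}

#' Transition/transversion ratio
#'
#' @param ref,alt vectors of single-base alleles.
#' @return transitions (A<->G, C<->T) divided by transversions; `Inf` with
#'   zero transversions.
#' @export
titv_ratio <- function(ref, alt) {
  stopifnot(length(ref) >= 1L)
  ti <- (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
  n_ti <- sum(ti)
  n_tv <- sum(!ti)
  if (n_tv == 0L) return(Inf)
  n_ti / n_tv
}

#' Spectrum summary for a set of SNVs
#'
#' @param dnms table with ref, alt columns.
#' @param context optional context table (chrom, pos, context) to resolve
#'   CpG status; without it C>T at CpG collapses into C>T.
#' @return list(class_counts, titv).
#' @export
spectrum_summary <- function(dnms, context = NULL) {
  dnms <- data.table::as.data.table(dnms)
  if (!is.null(context)) {
    ctx <- context[dnms[, list(chrom, pos)], on = c("chrom", "pos"),
                   mult = "first"]$context
    half <- (nchar(ctx) + 1L) %/% 2L
    prev_b <- substr(ctx, half - 1L, half - 1L)
    next_b <- substr(ctx, half + 1L, half + 1L)
  } else {
    prev_b <- next_b <- rep("N", nrow(dnms))
  }
  cls <- classify_substitution(dnms$ref, dnms$alt, prev_b, next_b)
  counts <- table(factor(cls, levels = SPECTRUM_CLASSES))
  list(class_counts = counts, titv = titv_ratio(dnms$ref, dnms$alt))
}

#' Parental-age regression of phased DNM counts
#'
#' Ordinary least squares of per-child haplotype-assigned DNM counts on
#' the corresponding parent's age at the child's birth.
#'
#' @param counts per-child mutation counts.
#' @param ages parental ages at birth (same order).
#' @return list(slope, intercept, p) with the two-sided slope p-value.
#' @export
age_regression <- function(counts, ages) {
  stopifnot(length(counts) == length(ages), length(counts) >= 3L)
  if (stats::var(ages) == 0) stop("ages are constant", call. = FALSE)
  fit <- stats::lm(counts ~ ages)
  # a perfect fit triggers a harmless precision warning in summary.lm
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       p = sm$coefficients[2L, 4L])
}

#' Parent-of-origin ratio and tests
#'
#' Pooled paternal:maternal ratio with a Wilcoxon signed-rank test on the
#' per-child paternal minus maternal counts (exact null for small n
#' without ties; normal approximation with continuity correction
#' otherwise).
#'
#' @param paternal,maternal per-child phased counts.
#' @return list(ratio, wilcoxon_p, pooled_fraction).
#' @export
parental_ratio <- function(paternal, maternal) {
  stopifnot(length(paternal) == length(maternal), length(paternal) >= 2L)
  sp <- sum(paternal); sm_ <- sum(maternal)
  ratio <- if (sm_ == 0) Inf else sp / sm_
  p <- if (all(paternal == maternal)) 1 else
    suppressWarnings(stats::wilcox.test(paternal, maternal,
                                        paired = TRUE))$p.value
  list(ratio = ratio, wilcoxon_p = p,
       pooled_fraction = sp / (sp + sm_))
}

#' Two-proportion Z-test for pooled paternal fractions
#'
#' Compares the pooled paternal fraction of two groups (e.g. germline vs
#' postzygotic mutations).
#'
#' @param k1,n1 paternal count and total phased count in group 1.
#' @param k2,n2 same for group 2.
#' @return list(z, p) (two-sided).
#' @export
proportion_z_test <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Find multinucleotide-mutation candidate pairs
#'
#' All within-child pairs of DNMs on one chromosome separated by 1 to
#' `max_dist_bp` bases, flagged as adjacent when the distance is exactly 1.
#'
#' @param dnms DNM table (chrom, pos, child_id).
#' @param max_dist_bp maximum pair distance (default 500).
#' @return data.table (child_id, chrom, pos1, pos2, dist, adjacent).
#' @export
find_mnm_pairs <- function(dnms, max_dist_bp = 500) {
  dnms <- data.table::as.data.table(dnms)
  if (nrow(dnms) < 2L) {
    return(data.table::data.table(child_id = character(),
                                  chrom = character(), pos1 = integer(),
                                  pos2 = integer(), dist = integer(),
                                  adjacent = logical()))
  }
  out <- vector("list", 0L)
  grp <- split(dnms, paste(dnms$child_id, dnms$chrom, sep = "\r"))
  for (g in grp) {
    p <- sort(unique(g$pos))
    n <- length(p)
    if (n < 2L) next
    # sorted sweep: for each position, partners within max_dist to the right
    j <- findInterval(p + max_dist_bp, p)
    for (i in seq_len(n)) {
      if (j[i] > i) {
        partners <- p[(i + 1L):j[i]]
        out[[length(out) + 1L]] <- data.table::data.table(
          child_id = g$child_id[1L], chrom = g$chrom[1L], pos1 = p[i],
          pos2 = partners, dist = partners - p[i])
      }
    }
  }
  if (!length(out)) {
    return(data.table::data.table(child_id = character(),
                                  chrom = character(), pos1 = integer(),
                                  pos2 = integer(), dist = integer(),
                                  adjacent = logical()))
  }
  res <- data.table::rbindlist(out)
  res[, adjacent := dist == 1L]
  data.table::setorder(res, child_id, chrom, pos1, pos2)
  res[]
}

#' Per-class spectrum comparison between two groups
#'
#' For every substitution class, a 2x2 chi-squared test (class vs rest,
#' group A vs group B) with Benjamini-Hochberg correction across classes;
#' degenerate tables fall back to Fisher's exact test. Also reports a
#' two-proportion Z-test on the transition fractions of the groups.
#'
#' @param counts_a,counts_b named class-count vectors over the same
#'   classes (as from [spectrum_summary()]).
#' @return list(per_class = data.table(class, p, p_BH), ti_z, ti_p).
#' @export
spectrum_compare <- function(counts_a, counts_b) {
  counts_a <- as.numeric(counts_a)[match(SPECTRUM_CLASSES,
                                         names(c(counts_a)))] |>
    stats::setNames(SPECTRUM_CLASSES)
  counts_b <- as.numeric(counts_b)[match(SPECTRUM_CLASSES,
                                         names(c(counts_b)))] |>
    stats::setNames(SPECTRUM_CLASSES)
  counts_a[is.na(counts_a)] <- 0
  counts_b[is.na(counts_b)] <- 0
  na <- sum(counts_a); nb <- sum(counts_b)
  if (na == 0 || nb == 0) stop("empty spectrum group", call. = FALSE)
  ps <- vapply(SPECTRUM_CLASSES, function(cl) {
    tab <- rbind(c(counts_a[cl], na - counts_a[cl]),
                 c(counts_b[cl], nb - counts_b[cl]))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0)) return(stats::fisher.test(tab)$p.value)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }, numeric(1))
  ti_classes <- c("A>G", "C>T", "CpG>TpG")
  zt <- proportion_z_test(sum(counts_a[ti_classes]), na,
                          sum(counts_b[ti_classes]), nb)
  list(per_class = data.table::data.table(class = SPECTRUM_CLASSES,
                                          p = unname(ps),
                                          p_BH = stats::p.adjust(ps, "BH")),
       ti_z = zt$z, ti_p = zt$p)
}
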