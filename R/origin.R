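# Germline vs postzygotic classification. A postzygotic mutation (PZM)
# lives on only a fraction of the cells carrying one parental haplotype,
# so reads from that haplotype split between reference and alternate
# ("three haplotypes"); a germline DNM is carried by every read from its
# haplotype of origin. Haplotype read counts give the primary call per
# long-read platform; a cross-platform allele-balance test arbitrates
# conflicts and ambiguity.

#' Haplotype-based origin call for one platform
#'
#' Postzygotic when at least two reference reads and one alternate read
#' are assigned to the origin haplotype; germline when at most one
#' reference read accompanies the alternate reads; ambiguous when no
#' alternate read was assigned.
#'
#' @param n_ref,n_alt reference/alternate read counts on the origin
#'   haplotype (vectorized).
#' @return "PZM", "GERMLINE" or "AMBIGUOUS".
#' @export
haplotype_origin_call <- function(n_ref, n_alt) {
  ifelse(is.na(n_alt) | n_alt == 0L, "AMBIGUOUS",
         ifelse(n_ref >= 2L, "PZM", "GERMLINE"))
}

#' Cross-platform allele-balance concordance test
#'
#' Chi-squared test of homogeneity on the platforms-by-{ref, alt}
#' contingency table (platforms with zero reads are dropped). Concordant
#' when p > alpha. Degenerate tables (an expected cell of zero) fall back
#' to an exact homogeneity test; with fewer than two platforms carrying
#' reads the counts are concordant by convention (flagged).
#'
#' @param n_ref,n_alt per-platform read counts (equal-length vectors).
#' @param alpha significance level (default 0.05).
#' @return list(concordant, p, testable).
#' @export
ab_concordance_test <- function(n_ref, n_alt, alpha = 0.05) {
  keep <- (n_ref + n_alt) > 0 & !is.na(n_ref + n_alt)
  n_ref <- n_ref[keep]; n_alt <- n_alt[keep]
  if (length(n_ref) < 2L) {
    return(list(concordant = TRUE, p = NA_real_, testable = FALSE))
  }
  tab <- cbind(n_ref, n_alt)
  if (any(colSums(tab) == 0)) {
    # all-ref or all-alt on every platform: trivially homogeneous
    return(list(concordant = TRUE, p = 1, testable = TRUE))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    p <- stats::fisher.test(tab)$p.value
  } else {
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  list(concordant = p > alpha, p = p, testable = TRUE)
}

#' Pooled allele-balance binomial test
#'
#' Pools reference and alternate counts across platforms and tests whether
#' the total allele balance is significantly below 0.5 with a one-sided
#' exact binomial test. Predicts PZM when p < alpha.
#'
#' @param n_ref,n_alt per-platform counts to pool.
#' @param alpha significance level (default 0.05).
#' @return list(prediction = "GERMLINE"/"PZM", p).
#' @export
pooled_ab_test <- function(n_ref, n_alt, alpha = 0.05) {
  total <- sum(n_ref, na.rm = TRUE) + sum(n_alt, na.rm = TRUE)
  if (total == 0) stop("pooled AB test needs at least one read",
                       call. = FALSE)
  p <- stats::binom.test(sum(n_alt, na.rm = TRUE), total, p = 0.5,
                         alternative = "less")$p.value
  list(prediction = if (p < alpha) "PZM" else "GERMLINE", p = p)
}

#' Combine haplotype calls and the allele-balance prediction
#'
#' When the HiFi and ONT haplotype calls agree (and are not ambiguous)
#' that call stands; when they disagree the allele-balance prediction
#' breaks the tie; when both are ambiguous the allele-balance prediction
#' is used (the prediction defaults to germline when the platform ABs were
#' discordant).
#'
#' @param hifi_call,ont_call "GERMLINE"/"PZM"/"AMBIGUOUS" (vectorized).
#' @param ab_prediction "GERMLINE"/"PZM".
#' @return "GERMLINE" or "POSTZYGOTIC".
#' @export
classify_origin <- function(hifi_call, ont_call, ab_prediction) {
  pick <- ifelse(hifi_call == ont_call & hifi_call != "AMBIGUOUS", hifi_call,
                 ifelse(hifi_call == "AMBIGUOUS" & ont_call != "AMBIGUOUS",
                        ont_call,
                        ifelse(ont_call == "AMBIGUOUS" &
                                 hifi_call != "AMBIGUOUS", hifi_call,
                               ab_prediction)))
  # a true disagreement (one GERMLINE, one PZM) always defers to AB
  disagree <- hifi_call != ont_call & hifi_call != "AMBIGUOUS" &
    ont_call != "AMBIGUOUS"
  pick[disagree] <- ab_prediction[disagree]
  ifelse(pick == "PZM", "POSTZYGOTIC", "GERMLINE")
}

#' Indel origin rule
#'
#' An indel is postzygotic when more than three reads on the origin
#' haplotype carry an allele that differs from the called de novo event
#' (reference reads and third alleles alike) and at least one read carries
#' the de novo allele; otherwise germline. Indel pileups are noisier than
#' SNVs, hence the higher tolerance.
#'
#' @param n_non_denovo,n_denovo read counts on the origin haplotype.
#' @return "GERMLINE" or "POSTZYGOTIC" (vectorized).
#' @export
classify_indel_origin <- function(n_non_denovo, n_denovo) {
  ifelse(n_non_denovo > 3L & n_denovo >= 1L, "POSTZYGOTIC", "GERMLINE")
}

#' Classify origin for all phased SNVs (vectorized driver)
#'
#' @param phased table from [phase_validated()] with per-platform counts
#'   (`nref_*`/`nalt_*` from validation, `hap_*` from phasing).
#' @param alpha significance level for both AB tests.
#' @return the input with columns hifi_call, ont_call, ab_concordant,
#'   ab_p, pooled_p, ab_prediction, origin. Variants with phase
#'   "EXCLUDE" get origin NA (they leave the callset).
#' @export
classify_origins <- function(phased, alpha = 0.05) {
  ph <- data.table::copy(data.table::as.data.table(phased))
  if (nrow(ph) == 0L) {
    ph[, `:=`(hifi_call = character(), ont_call = character(),
              ab_concordant = logical(), ab_p = numeric(),
              pooled_p = numeric(), ab_prediction = character(),
              origin = character())]
    return(ph)
  }
  ph[, hifi_call := haplotype_origin_call(hap_nref_HIFI, hap_nalt_HIFI)]
  ph[, ont_call := haplotype_origin_call(hap_nref_ONT, hap_nalt_ONT)]

  n <- nrow(ph)
  conc <- logical(n); ab_p <- rep(NA_real_, n)
  pooled_p <- rep(NA_real_, n); pred <- character(n)
  nref_m <- as.matrix(ph[, list(nref_HIFI, nref_ONT, nref_ILLUMINA)])
  nalt_m <- as.matrix(ph[, list(nalt_HIFI, nalt_ONT, nalt_ILLUMINA)])
  for (i in seq_len(n)) {
    ct <- ab_concordance_test(nref_m[i, ], nalt_m[i, ], alpha)
    conc[i] <- ct$concordant; ab_p[i] <- ct$p
    if (!ct$concordant) {
      pred[i] <- "GERMLINE"  # cannot predict confidently
    } else if (sum(nref_m[i, ], nalt_m[i, ]) == 0) {
      pred[i] <- "GERMLINE"
    } else {
      pt <- pooled_ab_test(nref_m[i, ], nalt_m[i, ], alpha)
      pooled_p[i] <- pt$p
      pred[i] <- pt$prediction
    }
  }
  ph[, `:=`(ab_concordant = conc, ab_p = ab_p, pooled_p = pooled_p,
            ab_prediction = pred)]
  ph[, origin := ifelse(phase == "EXCLUDE", NA_character_,
                        classify_origin(hifi_call, ont_call, ab_prediction))]
  ph[]
}
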