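# End-to-end orchestration: candidate selection -> cluster filter ->
# three-platform validation -> phasing -> origin classification ->
# statistics, with per-stage counts, truth-based evaluation and
# deterministic outputs.

#' Run the full DNM pipeline on a cohort
#'
#' @param cohort a `trio_cohort` (from [simulate_cohort()] /
#'   [read_cohort()]) or a cohort directory path.
#' @param out_dir optional output directory; when given, the DNM table
#'   (`dnms.tsv`) and a JSON summary (`summary.json`) are written.
#' @param seed RNG seed for the bootstrap intervals (the pipeline is
#'   otherwise deterministic).
#' @param bootstrap_reps bootstrap replicates for rate intervals.
#' @return a `pipeline_result` list: `records` (all candidates with filter
#'   provenance), `callset` (final validated, non-excluded records),
#'   `summary` (stage counts and cohort statistics) and, when truth is
#'   available, `evaluation`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, seed = 1L,
                         bootstrap_reps = 1000) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(is(cohort, "trio_cohort") || is.list(cohort))
  set.seed(derive_seed(seed, 11L))
  ped <- cohort$pedigree
  children <- pedigree_children(ped)

  calls <- union_callsets(list(cohort$calls))
  candidates <- select_candidate_snvs(calls, ped)
  cf <- cluster_filter(candidates)
  validated_tbl <- validate_snvs(cf$kept, cohort$evidence, ped,
                                 cohort$features, cohort$context)
  val <- validated_tbl[validation_status == "VALIDATED"]
  phased <- phase_validated(val, cohort$calls, cohort$evidence, ped)
  classified <- classify_origins(phased)
  callset <- classified[phase != "EXCLUDE"]
  callset[, variant_type := "SNV"]

  # bookkeeping: every candidate leaves through exactly one door
  n_candidates <- nrow(candidates)
  n_clustered <- nrow(cf$clustered)
  fail_counts <- table(validated_tbl$first_fail[
    validated_tbl$validation_status != "VALIDATED"])
  n_phase_excluded <- sum(classified$phase == "EXCLUDE")
  n_final <- nrow(callset)

  germ <- callset[origin == "GERMLINE"]
  pzm <- callset[origin == "POSTZYGOTIC"]
  phased_set <- callset[phase %in% c("PATERNAL", "MATERNAL")]

  per_child <- merge(
    children,
    callset[origin == "GERMLINE" & phase %in% c("PATERNAL", "MATERNAL"),
            list(n_pat = sum(phase == "PATERNAL"),
                 n_mat = sum(phase == "MATERNAL")), by = child_id],
    by = "child_id", all.x = TRUE)
  for (cc in c("n_pat", "n_mat")) {
    data.table::set(per_child, which(is.na(per_child[[cc]])), cc, 0L)
  }

  stats_out <- list()
  if (nrow(germ) >= 2L && nrow(pzm) >= 2L) {
    g_ratio <- parental_ratio(per_child$n_pat, per_child$n_mat)
    pz_counts <- pzm[phase %in% c("PATERNAL", "MATERNAL"),
                     list(n_pat = sum(phase == "PATERNAL"),
                          n_mat = sum(phase == "MATERNAL")), by = child_id]
    pz_full <- merge(children[, list(child_id)], pz_counts,
                     by = "child_id", all.x = TRUE)
    for (cc in c("n_pat", "n_mat")) {
      data.table::set(pz_full, which(is.na(pz_full[[cc]])), cc, 0L)
    }
    pz_ratio <- parental_ratio(pz_full$n_pat, pz_full$n_mat)
    reg_pat <- age_regression(per_child$n_pat,
                              per_child$father_age_at_birth)
    reg_mat <- age_regression(per_child$n_mat,
                              per_child$mother_age_at_birth)
    g_spec <- spectrum_summary(germ, cohort$context)
    z_spec <- spectrum_summary(pzm, cohort$context)
    stats_out <- list(
      germline_paternal_ratio = g_ratio$ratio,
      germline_ratio_wilcoxon_p = g_ratio$wilcoxon_p,
      pzm_paternal_ratio = pz_ratio$ratio,
      pzm_ratio_wilcoxon_p = pz_ratio$wilcoxon_p,
      germline_titv = g_spec$titv,
      pzm_titv = z_spec$titv,
      germline_mean_ab = mean(germ$mean_ab, na.rm = TRUE),
      pzm_mean_ab = mean(pzm$mean_ab, na.rm = TRUE),
      paternal_age_slope = reg_pat$slope,
      paternal_age_p = reg_pat$p,
      maternal_age_slope = reg_mat$slope,
      maternal_age_p = reg_mat$p,
      germline_spectrum = as.list(g_spec$class_counts),
      pzm_spectrum = as.list(z_spec$class_counts))
  }
  mnm <- find_mnm_pairs(callset)

  # rates against the simulated genome (fully callable by construction)
  rate_block <- NULL
  if (!is.null(cohort$genome) && nrow(callset)) {
    mask <- data.table::data.table(child_id = children$child_id,
                                   chrom = cohort$genome$chrom[1L],
                                   start = 0L,
                                   end = cohort$genome$length[1L])
    rg <- mutation_rate(germ, mask, 2, bootstrap_reps)
    rz <- mutation_rate(pzm, mask, 2, bootstrap_reps)
    rate_block <- list(germline_rate = rg$rate,
                       germline_rate_ci = c(rg$ci_low, rg$ci_high),
                       pzm_rate = rz$rate,
                       pzm_rate_ci = c(rz$ci_low, rz$ci_high))
  }

  summary <- c(list(
    n_children = nrow(children),
    n_candidates = n_candidates,
    n_clustered = n_clustered,
    filter_removed = as.list(fail_counts),
    n_validated = nrow(val),
    n_phase_excluded = n_phase_excluded,
    n_final = n_final,
    n_germline = nrow(germ),
    n_pzm = nrow(pzm),
    pzm_fraction = if (n_final > 0) nrow(pzm) / n_final else NA_real_,
    phased_fraction = if (n_final > 0) nrow(phased_set) / n_final
      else NA_real_,
    mean_snvs_per_child = n_final / nrow(children),
    n_mnm_pairs = nrow(mnm)),
    stats_out, rate_block)

  result <- list(records = validated_tbl, callset = callset,
                 clustered = cf$clustered, mnm_pairs = mnm,
                 summary = summary)
  if (!is.null(cohort$truth)) {
    result$evaluation <- evaluate_against_truth(callset, cohort$truth)
  }
  class(result) <- "pipeline_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dnm_table(callset, file.path(out_dir, "dnms.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  result
}

#' Evaluate a callset against the simulator truth table
#'
#' Records are matched by (chrom, pos, child_id). Sensitivity and
#' precision are computed over true mutations (germline + postzygotic);
#' origin accuracy over callset records matching a true mutation; phase
#' accuracy over phased records with a known true parent. Confounder
#' survivorship is reported per class.
#'
#' @param callset final DNM table (with `phase` and `origin` columns).
#' @param truth simulator truth table.
#' @return list of metrics.
#' @export
evaluate_against_truth <- function(callset, truth) {
  cs <- data.table::as.data.table(callset)
  tr <- data.table::as.data.table(truth)
  key <- c("chrom", "pos", "child_id")
  tr_mut <- tr[true_class %in% c("GERMLINE", "PZM")]
  hit <- merge(tr_mut, cs, by = key, suffixes = c("", ".cs"))

  sensitivity <- if (nrow(tr_mut)) nrow(hit) / nrow(tr_mut) else NA_real_
  germ_truth <- tr_mut[true_class == "GERMLINE"]
  germ_hit <- hit[true_class == "GERMLINE"]
  germline_sensitivity <- if (nrow(germ_truth))
    nrow(germ_hit) / nrow(germ_truth) else NA_real_
  precision <- if (nrow(cs)) nrow(hit) / nrow(cs) else NA_real_

  origin_match <- hit$origin == ifelse(hit$true_class == "PZM",
                                       "POSTZYGOTIC", "GERMLINE")
  origin_accuracy <- if (nrow(hit)) mean(origin_match, na.rm = TRUE)
    else NA_real_

  ph <- hit[phase %in% c("PATERNAL", "MATERNAL") & !is.na(true_parent)]
  phase_accuracy <- if (nrow(ph)) {
    mean(ph$phase == ifelse(ph$true_parent == "P", "PATERNAL", "MATERNAL"))
  } else NA_real_
  phased_fraction <- if (nrow(hit))
    mean(hit$phase %in% c("PATERNAL", "MATERNAL")) else NA_real_

  survivors <- function(cls) {
    sub <- tr[true_class == cls]
    if (!nrow(sub)) return(c(n = 0L, in_callset = 0L))
    m <- merge(sub, cs, by = key)
    c(n = nrow(sub), in_callset = nrow(m))
  }
  list(sensitivity = sensitivity,
       germline_sensitivity = germline_sensitivity,
       precision = precision,
       origin_accuracy = origin_accuracy,
       phase_accuracy = phase_accuracy,
       phased_fraction = phased_fraction,
       pzm_sensitivity = if (nrow(tr_mut[true_class == "PZM"]))
         nrow(hit[true_class == "PZM"]) / nrow(tr_mut[true_class == "PZM"])
       else NA_real_,
       confounders = list(
         inherited_artifact = survivors("INHERITED_ARTIFACT"),
         recurrent_error = survivors("RECURRENT_ERROR"),
         homopolymer_error = survivors("HP_ERROR")))
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("DNM pipeline: %d candidates -> %d validated -> %d final (%d germline, %d PZM)\n",
              s$n_candidates, s$n_validated, s$n_final, s$n_germline,
              s$n_pzm))
  if (!is.null(s$germline_paternal_ratio)) {
    cat(sprintf("  paternal:maternal %.2f (germline) / %.2f (PZM); Ti/Tv %.2f / %.2f; mean AB %.3f / %.3f\n",
                s$germline_paternal_ratio, s$pzm_paternal_ratio,
                s$germline_titv, s$pzm_titv, s$germline_mean_ab,
                s$pzm_mean_ab))
  }
  if (!is.null(x$evaluation)) {
    e <- x$evaluation
    cat(sprintf("  vs truth: sensitivity %.3f, precision %.3f, origin accuracy %.3f, phase accuracy %.3f\n",
                e$sensitivity, e$precision, e$origin_accuracy,
                e$phase_accuracy))
  }
  invisible(x)
}
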