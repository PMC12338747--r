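# Synthetic trio-cohort generator.
#
# Emits a full study cohort -- pedigree, per-family two-caller VCFs, a
# per-read evidence table across three platforms (HiFi, ONT, Illumina),
# feature tracks, local reference contexts and a truth table -- so that the
# discovery/validation/phasing/classification pipeline can be evaluated
# against known ground truth. Reads are emitted only at candidate sites;
# the inherited-SNP scaffold used for phasing is emitted at the configured
# density within a window around each candidate site (the only region reads
# anchored at the site can span).

BASES <- c("A", "C", "G", "T")
SPECTRUM_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T", "CpG>TpG")
CONTEXT_FLANK <- 10L

#' Calibrated default generator configuration
#'
#' Returns the default cohort model: 42 families (31 quads, 11 trios, 73
#' transmissions); germline single-nucleotide DNM counts split into
#' independent paternal and maternal Poisson components with slopes of 1.32
#' and 0.46 mutations per year of parental age (intercepts solved so that a
#' child born to 33/31-year-old parents expects 70 germline SNVs at a
#' 3.98:1 paternal:maternal ratio); postzygotic mutations (PZMs) at 18% of
#' the germline expectation (about 12.6 per child) with a 1.15:1 paternal
#' bias and cell fractions drawn from Beta(2.2, 7.8) (mean allele balance
#' 0.22); a germline mutation spectrum with transition fraction 2.10/3.10
#' and a transversion-enriched PZM spectrum with transition fraction
#' 1.35/2.35; per-platform reference bias chosen so the observed mean
#' germline allele balance is about 0.48; and confounder channels for
#' dropped parental haplotypes, cohort-recurrent artifacts and
#' homopolymer-edge noise.
#'
#' @param genome_bp total simulated genome length per trio (single
#'   chromosome). The default keeps per-child mutation counts at cohort
#'   scale on a desk-scale genome, so per-bp rates are inflated relative to
#'   a 2.9 Gbp genome by design.
#' @param seed RNG seed stored in the configuration.
#' @return a `generator_config` list; see the methods vignette for the
#'   meaning and rationale of every field.
#' @export
calibrated_preset <- function(genome_bp = 5e7, seed = 1L) {
  germ_ti <- 2.10 / 3.10
  pzm_ti <- 1.35 / 2.35
  config <- list(
    n_families = 42L,
    n_quads = 31L,
    genome = data.table::data.table(chrom = "chr1",
                                    length = as.integer(genome_bp)),
    snp_density = 1 / 1200,
    snp_window_bp = 25000L,
    informative_fraction = 0.55,
    platform_models = list(
      HIFI = list(depth = 30, ref_bias = 0.013, error = 0.002,
                  read_len_mean = 18000, read_len_sd = 3000,
                  read_len_min = 3000,
                  tier_probs = c(HIGH = 0.97, LOW = 0.02, DISCARD = 0.01),
                  error_tier_probs = c(HIGH = 0.05, LOW = 0.45, DISCARD = 0.50),
                  p_mapq60 = 0.97),
      ONT = list(depth = 40, ref_bias = 0.010, error = 0.020,
                 read_len_mean = 30000, read_len_sd = 8000,
                 read_len_min = 5000,
                 tier_probs = c(HIGH = 0.55, LOW = 0.35, DISCARD = 0.10),
                 error_tier_probs = c(HIGH = 0.05, LOW = 0.45, DISCARD = 0.50),
                 p_mapq60 = 0.95),
      ILLUMINA = list(depth = 40, ref_bias = 0.065, error = 0.001,
                      read_len_mean = 150, read_len_sd = 0,
                      read_len_min = 150,
                      tier_probs = c(HIGH = 0.95, LOW = 0.04, DISCARD = 0.01),
                      error_tier_probs = c(HIGH = 0.05, LOW = 0.45,
                                           DISCARD = 0.50),
                      p_mapq60 = 0.90)),
    germline = list(
      paternal_slope = 1.32, maternal_slope = 0.46,
      paternal_intercept = 12.38, maternal_intercept = -0.20,
      paternal_fraction = 3.98 / 4.98,
      mean_snvs_per_child = 70,
      spectrum = c("A>C" = 0.06, "A>G" = 0.27, "A>T" = 0.07,
                   "C>A" = 0.10, "C>G" = (1 - germ_ti) - 0.23,
                   "C>T" = germ_ti - 0.42, "CpG>TpG" = 0.15)),
    pzm = list(
      rate_fraction = 0.18, paternal_fraction = 1.15 / 2.15,
      mean_ab = 0.22, ab_shape1 = 2.2, ab_shape2 = 7.8,
      spectrum = c("A>C" = 0.10, "A>G" = 0.16, "A>T" = 0.14,
                   "C>A" = 0.10, "C>G" = (1 - pzm_ti) - 0.34,
                   "C>T" = pzm_ti - 0.2755, "CpG>TpG" = 0.1155)),
    ages = list(father_mean = 33, father_sd = 5,
                mother_mean = 31, mother_sd = 4.5, min = 18, max = 55),
    caller = list(p_both = 0.90, p_gatk_only = 0.05, p_gq_low = 0.01),
    confounders = list(dropped_run_rate = 1.5,
                       recurrent_artifact_rate = 3,
                       homopolymer_noise_rate = 2),
    seed = as.integer(seed))
  class(config) <- "generator_config"
  validate_generator_config(config)
  config
}

#' Validate a generator configuration
#' @param config a `generator_config` list.
#' @return the config, invisibly, or an error before any generation.
#' @export
validate_generator_config <- function(config) {
  stopifnot(config$n_families >= 1L, config$n_quads <= config$n_families,
            all(config$genome$length >= 10000L))
  for (grp in list(config$germline$spectrum, config$pzm$spectrum)) {
    if (any(grp < 0) || abs(sum(grp) - 1) > 1e-6) {
      stop("spectrum probabilities must be non-negative and sum to 1",
           call. = FALSE)
    }
    if (!identical(sort(names(grp)), sort(SPECTRUM_CLASSES))) {
      stop("spectrum must cover the 7 substitution classes", call. = FALSE)
    }
  }
  for (pm in config$platform_models) {
    stopifnot(pm$depth > 0, pm$ref_bias >= 0, pm$ref_bias <= 1,
              pm$error >= 0, pm$error <= 1,
              abs(sum(pm$tier_probs) - 1) < 1e-6,
              abs(sum(pm$error_tier_probs) - 1) < 1e-6)
  }
  probs <- c(config$germline$paternal_fraction, config$pzm$paternal_fraction,
             config$informative_fraction, config$caller$p_both,
             config$caller$p_gatk_only, config$caller$p_gq_low)
  stopifnot(all(probs >= 0 & probs <= 1))
  stopifnot(all(unlist(config$confounders) >= 0))
  invisible(config)
}

#' Read/write a generator configuration as JSON
#' @param path JSON file path.
#' @export
read_generator_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$genome <- data.table::as.data.table(cfg$genome)
  cfg$genome[, length := as.integer(length)]
  for (p in names(cfg$platform_models)) {
    pm <- as.list(cfg$platform_models[[p]])
    pm$tier_probs <- unlist(pm$tier_probs)
    pm$error_tier_probs <- unlist(pm$error_tier_probs)
    cfg$platform_models[[p]] <- pm
  }
  cfg$germline <- as.list(cfg$germline)
  cfg$germline$spectrum <- unlist(cfg$germline$spectrum)
  cfg$pzm <- as.list(cfg$pzm)
  cfg$pzm$spectrum <- unlist(cfg$pzm$spectrum)
  cfg$confounders <- as.list(cfg$confounders)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' @rdname read_generator_config
#' @param config configuration to serialize.
#' @export
write_generator_config <- function(config, path) {
  # named atomic vectors (spectra, tier probabilities) must serialize as
  # JSON objects, not bare arrays, to survive the round trip
  named_to_list <- function(x) {
    if (is.data.frame(x)) return(as.list(x))
    if (is.list(x)) return(lapply(x, named_to_list))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  jsonlite::write_json(named_to_list(unclass(config)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- pedigree ---------------------------------------------------------------

sim_pedigree <- function(config) {
  fams <- sprintf("fam%02d", seq_len(config$n_families))
  rows <- vector("list", config$n_families)
  ages <- config$ages
  draw_age <- function(n, mean, sd) {
    round(pmin(ages$max, pmax(ages$min, stats::rnorm(n, mean, sd))), 1)
  }
  for (i in seq_len(config$n_families)) {
    fam <- fams[i]
    n_children <- if (i <= config$n_quads) 2L else 1L
    fa <- paste0(fam, "-fa"); mo <- paste0(fam, "-mo")
    kids <- paste0(fam, "-c", seq_len(n_children))
    rows[[i]] <- data.table::data.table(
      family_id = fam,
      sample_id = c(fa, mo, kids),
      father_id = c(NA, NA, rep(fa, n_children)),
      mother_id = c(NA, NA, rep(mo, n_children)),
      sex = c("M", "F", sample(c("M", "F"), n_children, replace = TRUE)),
      role = c("father", "mother", "proband",
               rep("sibling", n_children - 1L)),
      father_age_at_birth = c(NA, NA, draw_age(n_children, ages$father_mean,
                                               ages$father_sd)),
      mother_age_at_birth = c(NA, NA, draw_age(n_children, ages$mother_mean,
                                               ages$mother_sd)))
  }
  validate_pedigree(data.table::rbindlist(rows))
}

# --- positions and substitution contexts ------------------------------------

# Sample candidate positions with a minimum gap (to existing positions and
# among themselves) so that true mutations never trip the clustered-SNV
# filter by chance and never collide across children (clusters and
# recurrences are dedicated confounder channels, not background noise).
sim_positions <- function(n, glen, min_gap = 1200L, margin = 30000L,
                          avoid = integer()) {
  if (n == 0L) return(integer())
  margin <- min(margin, as.integer(glen %/% 20))
  kept <- integer(0)
  guard <- 0L
  while (length(kept) < n && guard < 200L) {
    guard <- guard + 1L
    cand <- as.integer(floor(stats::runif(2L * (n - length(kept)),
                                          margin, glen - margin)))
    ref <- sort(c(avoid, kept))
    if (length(ref)) {
      i <- findInterval(cand, ref)
      d_lo <- ifelse(i == 0L, min_gap, cand - ref[pmax(i, 1L)])
      d_hi <- ifelse(i == length(ref), min_gap,
                     ref[pmin(i + 1L, length(ref))] - cand)
      cand <- cand[pmin(d_lo, d_hi) >= min_gap]
    }
    cand <- sort(unique(cand))
    sel <- integer(0)
    last <- -Inf
    for (p in cand) {
      if (as.numeric(p) - last >= min_gap) {
        sel <- c(sel, p)
        last <- as.numeric(p)
      }
    }
    kept <- c(kept, utils::head(sel, n - length(kept)))
  }
  if (length(kept) < n) stop("genome too small for requested variant count",
                             call. = FALSE)
  sort(kept)
}

# Realize a spectrum class as concrete ref/alt bases with a strand flip.
# Classes are pyrimidine-centred except the A-reference classes; a flip
# emits the reverse-complement representation.
realize_class <- function(cls) {
  n <- length(cls)
  base_cls <- sub("CpG>TpG", "C>T", cls)
  ref <- substr(base_cls, 1L, 1L)
  alt <- substr(base_cls, 3L, 3L)
  flip <- stats::runif(n) < 0.5
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  data.table::data.table(ref = ref, alt = alt, cpg = cls == "CpG>TpG",
                         flipped = flip)
}

# Vectorized context generation with rejection: no 4-base run anywhere in
# the window (keeps true mutations clear of the homopolymer filter), and
# the CpG status of the realized context must match the intended class.
gen_contexts <- function(ref, alt, cpg, flipped, flank = CONTEXT_FLANK) {
  n <- length(ref)
  L <- 2L * flank + 1L
  out <- character(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    mat <- matrix(sample(BASES, m * L, replace = TRUE), nrow = m)
    mat[, flank + 1L] <- ref[todo]
    fwd_cpg <- cpg[todo] & !flipped[todo]
    flp_cpg <- cpg[todo] & flipped[todo]
    if (any(fwd_cpg)) mat[fwd_cpg, flank + 2L] <- "G"
    if (any(flp_cpg)) mat[flp_cpg, flank] <- "C"
    s <- do.call(paste0, lapply(seq_len(L), function(j) mat[, j]))
    ok <- !grepl("(.)\\1{3}", s)
    # a non-CpG C>T must not look CpG in context (and its reverse complement
    # form, G>A, must not be preceded by C)
    noncpg_ct <- !cpg[todo] & ((ref[todo] == "C" & alt[todo] == "T") |
                                 (ref[todo] == "G" & alt[todo] == "A"))
    nxt <- mat[, flank + 2L]
    prv <- mat[, flank]
    bad_cpg <- noncpg_ct & ((ref[todo] == "C" & nxt == "G") |
                              (ref[todo] == "G" & prv == "C"))
    ok <- ok & !bad_cpg
    out[todo[ok]] <- s[ok]
    todo <- todo[!ok]
  }
  out
}

# Homopolymer-edge contexts: the variant site extends a run of its own
# reference base, so the homopolymer filter must remove it.
gen_hp_contexts <- function(n, flank = CONTEXT_FLANK) {
  if (n == 0L) {
    return(data.table::data.table(ref = character(), alt = character(),
                                  context = character()))
  }
  run_base <- sample(BASES, n, replace = TRUE)
  run_len <- sample(3:6, n, replace = TRUE)  # run beyond the site itself
  alt <- vapply(run_base, function(b) sample(setdiff(BASES, b), 1L),
                character(1))
  ctx <- vapply(seq_len(n), function(i) {
    left <- sample(setdiff(BASES, run_base[i]), flank, replace = TRUE)
    right <- c(rep(run_base[i], run_len[i]),
               sample(setdiff(BASES, run_base[i]), flank - run_len[i],
                      replace = TRUE))
    paste(c(left, run_base[i], right), collapse = "")
  }, character(1))
  data.table::data.table(ref = run_base, alt = alt, context = ctx)
}

# --- SNP scaffold -----------------------------------------------------------

# Inherited-SNP scaffold around candidate sites: genotype patterns,
# per-child haplotype alleles (for read threading) and VCF call rows.
sim_snp_scaffold <- function(variants, ped, config) {
  children <- pedigree_children(ped)
  W <- config$snp_window_bp
  glen <- config$genome$length[1L]
  dens <- config$snp_density
  inf_frac <- config$informative_fraction

  fam_calls <- vector("list", 0L)
  hap_rows <- vector("list", 0L)
  vsub <- variants[variants$hap_linked == TRUE, ]
  for (fam in unique(vsub$family_id)) {
    vf <- vsub[vsub$family_id == fam, ]
    members <- ped[ped$family_id == fam, ]
    fa <- members$sample_id[members$role == "father"]
    mo <- members$sample_id[members$role == "mother"]
    kids <- members$sample_id[members$role %in% c("proband", "sibling")]
    snp_list <- vector("list", nrow(vf))
    for (i in seq_len(nrow(vf))) {
      lo <- max(1L, vf$pos[i] - W)
      hi <- min(glen, vf$pos[i] + W)
      k <- stats::rpois(1L, (hi - lo) * dens)
      if (k == 0L) next
      p <- as.integer(floor(stats::runif(k, lo, hi)))
      snp_list[[i]] <- data.table::data.table(pos = p,
                                              child_id = vf$child_id[i])
    }
    snps <- data.table::rbindlist(snp_list)
    if (nrow(snps) == 0L) next
    snps <- snps[!duplicated(snps$pos) & !snps$pos %in% vf$pos, ]
    n <- nrow(snps)
    ref <- sample(BASES, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1))
    u <- stats::runif(n)
    type <- ifelse(u < inf_frac / 2, "INF_P",
                   ifelse(u < inf_frac, "INF_M", "UNINF"))
    donor_het <- stats::runif(n) < 0.5  # donor 0/1 vs 1/1
    fa_gt <- ifelse(type == "INF_P", ifelse(donor_het, "0/1", "1/1"),
                    ifelse(type == "INF_M", "0/0", "0/1"))
    mo_gt <- ifelse(type == "INF_M", ifelse(donor_het, "0/1", "1/1"),
                    ifelse(type == "INF_P", "0/0", "0/1"))
    # haplotype alleles of the window child (always 0/1 at scaffold SNPs)
    pat_is_alt <- ifelse(type == "INF_P", TRUE,
                         ifelse(type == "INF_M", FALSE, stats::runif(n) < 0.5))
    pat_allele <- ifelse(pat_is_alt, alt, ref)
    mat_allele <- ifelse(pat_is_alt, ref, alt)

    transmit <- function(gt_vec) {
      # allele a random gamete carries, as 0/1 code
      code <- integer(length(gt_vec))
      code[gt_vec == "1/1"] <- 1L
      het <- gt_vec == "0/1"
      code[het] <- as.integer(stats::runif(sum(het)) < 0.5)
      code
    }
    gt_rows <- list(
      data.table::data.table(sample_id = fa, gt = fa_gt),
      data.table::data.table(sample_id = mo, gt = mo_gt))
    for (kid in kids) {
      is_window_kid <- snps$child_id == kid
      cf <- transmit(fa_gt)
      cm <- transmit(mo_gt)
      gt_kid <- paste(pmin(cf, cm), pmax(cf, cm), sep = "/")
      gt_kid[is_window_kid] <- "0/1"
      gt_rows[[length(gt_rows) + 1L]] <-
        data.table::data.table(sample_id = kid, gt = gt_kid)
    }
    base <- data.table::data.table(chrom = vf$chrom[1L], pos = snps$pos,
                                   ref = ref, alt = alt)
    fam_calls[[length(fam_calls) + 1L]] <- data.table::rbindlist(
      lapply(gt_rows, function(g) {
        data.table::data.table(base, caller_id = "gatk",
                               sample_id = g$sample_id, gt = g$gt, gq = 99,
                               family_id = fam)
      }))
    hap_rows[[length(hap_rows) + 1L]] <- data.table::data.table(
      child_id = snps$child_id, chrom = vf$chrom[1L], pos = snps$pos,
      pat_allele = pat_allele, mat_allele = mat_allele)
  }
  list(calls = data.table::rbindlist(fam_calls),
       hap = data.table::rbindlist(hap_rows))
}

# --- read simulation --------------------------------------------------------

# One evidence row per read per (variant, sample, platform). `variants`
# rows carry: chrom, pos, ref, alt, child_id, family_id, true_class,
# origin ("P"/"M"/NA), true_ab (overall allele balance), hap_linked.
sim_reads <- function(variants, ped, config, id_offset = 0L) {
  if (nrow(variants) == 0L) {
    return(data.table::data.table())
  }
  children <- pedigree_children(ped)
  v <- merge(variants, children[, list(child_id, father_id, mother_id)],
             by = "child_id", sort = FALSE)
  member <- data.table::rbindlist(list(
    v[, list(variant_row = .I, sample_id = child_id, who = "child")],
    v[, list(variant_row = .I, sample_id = father_id, who = "father")],
    v[, list(variant_row = .I, sample_id = mother_id, who = "mother")]))

  out <- vector("list", length(PLATFORMS))
  for (pi in seq_along(PLATFORMS)) {
    p <- PLATFORMS[pi]
    pm <- config$platform_models[[p]]
    n_reads <- stats::rpois(nrow(member), pm$depth)
    idx <- rep(seq_len(nrow(member)), times = n_reads)
    if (!length(idx)) next
    vr <- member$variant_row[idx]
    who <- member$who[idx]
    n <- length(idx)
    ref <- v$ref[vr]; alt <- v$alt[vr]
    others <- t(vapply(seq_len(nrow(v)), function(i)
      setdiff(BASES, c(v$ref[i], v$alt[i])), character(2)))
    o1 <- others[vr, 1L]; o2 <- others[vr, 2L]

    is_child <- who == "child"
    hap <- sample(c("P", "M"), n, replace = TRUE)
    f_onhap <- pmin(1, 2 * v$true_ab[vr])
    carrier <- rep(FALSE, n)
    linked <- v$hap_linked[vr]
    carrier[is_child & linked] <- (hap == v$origin[vr] &
      stats::runif(n) < f_onhap)[is_child & linked]
    carrier[is_child & !linked] <-
      (stats::runif(n) < v$true_ab[vr])[is_child & !linked]

    u <- stats::runif(n)
    err <- u >= 1 - pm$error
    pick <- sample.int(3L, n, replace = TRUE)
    allele <- character(n)
    # carrier reads: alt unless reference bias drops them to ref, or a
    # sequencing error replaces the base
    ci <- which(carrier)
    allele[ci] <- ifelse(u[ci] < 1 - pm$ref_bias - pm$error, alt[ci],
                         ifelse(!err[ci], ref[ci],
                                cbind(ref, o1, o2)[cbind(seq_len(n), pick)][ci]))
    # non-carrier reads: ref unless error; parental errors never hit the de
    # novo allele (cross-sample recurrence is a dedicated confounder channel)
    ni <- which(!carrier)
    err_base_child <- cbind(alt, o1, o2)[cbind(seq_len(n), pick)]
    err_base_parent <- cbind(o1, o2)[cbind(seq_len(n),
                                           1L + (pick %% 2L))]
    allele[ni] <- ifelse(!err[ni], ref[ni],
                         ifelse(is_child[ni], err_base_child[ni],
                                err_base_parent[ni]))

    tu <- stats::runif(n)
    tp <- pm$tier_probs; ep <- pm$error_tier_probs
    tier <- ifelse(!err,
                   ifelse(tu < tp[["HIGH"]], "HIGH",
                          ifelse(tu < tp[["HIGH"]] + tp[["LOW"]], "LOW",
                                 "DISCARD")),
                   ifelse(tu < ep[["HIGH"]], "HIGH",
                          ifelse(tu < ep[["HIGH"]] + ep[["LOW"]], "LOW",
                                 "DISCARD")))
    base_qual <- integer(n)
    base_qual[tier == "HIGH"] <- sample(25:50, sum(tier == "HIGH"),
                                        replace = TRUE)
    base_qual[tier == "LOW"] <- sample(10:20, sum(tier == "LOW"),
                                       replace = TRUE)
    base_qual[tier == "DISCARD"] <- sample(2:9, sum(tier == "DISCARD"),
                                           replace = TRUE)
    mapq <- ifelse(stats::runif(n) < pm$p_mapq60, 60L,
                   sample(20:58, n, replace = TRUE))
    len <- if (pm$read_len_sd > 0) {
      pmax(pm$read_len_min,
           as.integer(round(stats::rnorm(n, pm$read_len_mean,
                                         pm$read_len_sd))))
    } else rep(as.integer(pm$read_len_mean), n)
    offset <- as.integer(floor(stats::runif(n) * len))
    flank_left <- offset
    flank_right <- len - 1L - offset
    tissue <- if (p == "HIFI") {
      ifelse(is_child, "BLOOD",
             ifelse(stats::runif(n) < 0.5, "BLOOD", "CELL_LINE"))
    } else if (p == "ONT") rep("CELL_LINE", n) else rep("BLOOD", n)

    out[[pi]] <- data.table::data.table(
      sample_id = member$sample_id[idx], platform = p, tissue = tissue,
      chrom = v$chrom[vr], pos = v$pos[vr],
      read_id = sprintf("r%d_%d_%d", pi + id_offset, vr, seq_len(n)),
      mapq = mapq, base_qual = base_qual, allele = allele,
      flank_left = flank_left, flank_right = flank_right,
      tag_snps = ".", hap = hap, is_child = is_child,
      rstart = v$pos[vr] - flank_left, rend = v$pos[vr] + flank_right)
  }
  data.table::rbindlist(out)
}

# Thread tagging-SNP alleles onto child long reads, consistent with the
# parental haplotype each read was drawn from.
thread_tags <- function(ev, hap_table, config) {
  if (nrow(hap_table) == 0L || nrow(ev) == 0L) return(ev)
  long <- which(ev$is_child & ev$platform %in% c("HIFI", "ONT"))
  if (!length(long)) return(ev)
  reads <- data.table::data.table(
    row = long, child_id = ev$sample_id[long], chrom = ev$chrom[long],
    start = ev$rstart[long], end = ev$rend[long],
    hap = ev$hap[long], platform = ev$platform[long])
  snps <- data.table::copy(hap_table)
  snps[, `:=`(start = pos, end = pos)]
  data.table::setkey(snps, child_id, chrom, start, end)
  hits <- data.table::foverlaps(reads, snps, type = "any", nomatch = NULL)
  if (nrow(hits) == 0L) return(ev)
  hits[, allele := ifelse(hap == "P", pat_allele, mat_allele)]
  # per-platform base-call error at the tag site
  err_rate <- vapply(hits$platform,
                     function(p) config$platform_models[[p]]$error,
                     numeric(1))
  flip <- stats::runif(nrow(hits)) < err_rate
  if (any(flip)) {
    hits$allele[flip] <- vapply(hits$allele[flip], function(b)
      sample(setdiff(BASES, b), 1L), character(1))
  }
  data.table::setorder(hits, row, pos)
  tags <- hits[, list(tag_snps = paste(paste0(pos, ":", allele),
                                       collapse = ";")), by = "row"]
  ev$tag_snps[tags$row] <- tags$tag_snps
  ev
}

# VCF candidate rows (child het, parents/sibling homozygous reference) for a
# set of simulated variants, with two-caller provenance and GQ draws.
sim_candidate_calls <- function(variants, ped, config) {
  if (nrow(variants) == 0L) return(data.table::data.table())
  rows <- vector("list", 0L)
  members <- data.table::as.data.table(ped)
  cal <- config$caller
  u_caller <- stats::runif(nrow(variants))
  callers <- ifelse(u_caller < cal$p_both, "both",
                    ifelse(u_caller < cal$p_both + cal$p_gatk_only,
                           "gatk", "dv"))
  for (i in seq_len(nrow(variants))) {
    fam <- members[members$family_id == variants$family_id[i], ]
    for (caller in c("gatk", "dv")) {
      if (callers[i] != "both" && callers[i] != caller) next
      gq_child <- if (stats::runif(1) < cal$p_gq_low) sample(5:19, 1L)
        else sample(30:99, 1L)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = variants$chrom[i], pos = variants$pos[i],
        ref = variants$ref[i], alt = variants$alt[i], caller_id = caller,
        sample_id = fam$sample_id,
        gt = ifelse(fam$sample_id == variants$child_id[i], "0/1", "0/0"),
        gq = ifelse(fam$sample_id == variants$child_id[i], gq_child, 99),
        family_id = variants$family_id[i])
    }
  }
  data.table::rbindlist(rows)
}

# Random feature track covering roughly `frac` of the genome
rand_track <- function(genome, frac, len_lo, len_hi, class, ident = NULL) {
  glen <- genome$length[1L]
  n <- as.integer(ceiling(frac * glen / mean(c(len_lo, len_hi))))
  len <- as.integer(floor(stats::runif(n, len_lo, len_hi)))
  start <- as.integer(floor(stats::runif(n, 0, glen - len)))
  dt <- data.table::data.table(chrom = genome$chrom[1L], start = start,
                               end = start + len, feature_class = class,
                               pct_identity = NA_real_)
  if (!is.null(ident)) dt[, pct_identity := sample(ident, n, replace = TRUE)]
  data.table::setorder(dt, chrom, start)
  dt[]
}

# --- top-level generator ----------------------------------------------------

#' Simulate a trio/quad cohort with known truth
#'
#' Generates pedigree, two-caller family VCF call tables, read evidence
#' across HiFi/ONT/Illumina, feature tracks, reference contexts and a truth
#' table. Deterministic given `config$seed`. Confounders (dropped parental
#' haplotypes, cohort-recurrent artifacts, homopolymer-edge noise) are
#' injected by [inject_confounders()] at the configured rates.
#'
#' @param config a `generator_config`, e.g. [calibrated_preset()].
#' @param out_dir optional directory; when given, all cohort artifacts are
#'   also written there (see [write_cohort()]).
#' @return a `trio_cohort` list with elements `pedigree`, `calls`,
#'   `evidence`, `truth`, `features`, `context`, `genome`, `config`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  validate_generator_config(config)
  set.seed(config$seed)
  ped <- sim_pedigree(config)
  children <- pedigree_children(ped)
  glen <- config$genome$length[1L]
  chrom <- config$genome$chrom[1L]
  g <- config$germline; z <- config$pzm

  # per-child germline (paternal/maternal Poisson with age slopes) and PZM
  # counts
  lam_p <- pmax(0, g$paternal_intercept +
                  g$paternal_slope * children$father_age_at_birth)
  lam_m <- pmax(0, g$maternal_intercept +
                  g$maternal_slope * children$mother_age_at_birth)
  lam_z <- z$rate_fraction * (lam_p + lam_m)
  n_gp <- stats::rpois(nrow(children), lam_p)
  n_gm <- stats::rpois(nrow(children), lam_m)
  n_zp <- stats::rpois(nrow(children), lam_z * z$paternal_fraction)
  n_zm <- stats::rpois(nrow(children), lam_z * (1 - z$paternal_fraction))

  var_rows <- vector("list", nrow(children))
  global_avoid <- integer()
  for (i in seq_len(nrow(children))) {
    counts <- c(n_gp[i], n_gm[i], n_zp[i], n_zm[i])
    n_tot <- sum(counts)
    if (n_tot == 0L) next
    pos <- sim_positions(n_tot, glen, avoid = global_avoid)
    global_avoid <- c(global_avoid, pos)
    # shuffle (class, parent) labels jointly across the child's positions
    lab <- rep(seq_len(4L), counts)
    lab <- lab[sample.int(length(lab))]
    cls_lab <- c("GERMLINE", "GERMLINE", "PZM", "PZM")[lab]
    par_lab <- c("P", "M", "P", "M")[lab]
    ab <- ifelse(cls_lab == "GERMLINE", 0.5,
                 pmin(0.495, pmax(0.01, stats::rbeta(n_tot, z$ab_shape1,
                                                     z$ab_shape2))))
    spec_cls <- character(n_tot)
    is_g <- cls_lab == "GERMLINE"
    spec_cls[is_g] <- sample(names(g$spectrum), sum(is_g), replace = TRUE,
                             prob = g$spectrum)
    spec_cls[!is_g] <- sample(names(z$spectrum), sum(!is_g), replace = TRUE,
                              prob = z$spectrum)
    var_rows[[i]] <- data.table::data.table(
      family_id = children$family_id[i], child_id = children$child_id[i],
      chrom = chrom, pos = pos, true_class = cls_lab, origin = par_lab,
      true_ab = ab, spectrum_class = spec_cls, hap_linked = TRUE)
  }
  variants <- data.table::rbindlist(var_rows)
  rz <- realize_class(variants$spectrum_class)
  variants[, `:=`(ref = rz$ref, alt = rz$alt)]
  variants[, context := gen_contexts(rz$ref, rz$alt, rz$cpg, rz$flipped)]

  scaffold <- sim_snp_scaffold(variants, ped, config)
  ev <- sim_reads(variants, ped, config)
  ev <- thread_tags(ev, scaffold$hap, config)
  call_parts <- Filter(function(x) !is.null(x) && nrow(x) > 0,
                       list(scaffold$calls,
                            sim_candidate_calls(variants, ped, config)))
  calls <- data.table::rbindlist(call_parts, use.names = TRUE)

  features <- data.table::rbindlist(list(
    rand_track(config$genome, 0.02, 100, 1000, "TR"),
    rand_track(config$genome, 0.06, 300, 3000, "RM"),
    rand_track(config$genome, 0.04, 5000, 50000, "SD",
               ident = c(97, 98.5, 99.5)),
    data.table::data.table(chrom = chrom,
                           start = as.integer(glen * 0.48),
                           end = as.integer(glen * 0.52),
                           feature_class = "CENTROMERE",
                           pct_identity = NA_real_)))

  truth <- variants[, list(chrom, pos, ref, alt, child_id, true_class,
                           true_parent = origin, true_ab)]
  context <- variants[, list(chrom, pos, context)]

  cohort <- list(pedigree = ped, calls = calls, evidence = ev, truth = truth,
                 features = features, context = context,
                 genome = data.table::copy(config$genome), config = config)
  class(cohort) <- "trio_cohort"
  cohort <- inject_confounders(cohort, config)

  # finalize: strip generator-internal read columns, deterministic order
  data.table::setorder(cohort$evidence, chrom, pos, sample_id, platform,
                       read_id)
  cohort$evidence <- cohort$evidence[, EVIDENCE_COLS, with = FALSE]
  data.table::setkey(cohort$evidence, chrom, pos)
  data.table::setorder(cohort$calls, chrom, pos, alt, caller_id, sample_id)
  data.table::setorder(cohort$truth, chrom, pos, child_id)
  data.table::setorder(cohort$context, chrom, pos)
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Inject confounders into a simulated cohort
#'
#' Adds, at the configured per-child rates: (a) dropped-haplotype runs —
#' three or more apparent child-only variants within 1 kbp that are truly
#' inherited from one parent whose own reads show no alternate allele;
#' (b) cohort-recurrent artifacts — an identical false alternate allele in
#' the HiFi reads of two or more unrelated children; (c) homopolymer-edge
#' substitutions involving the run base. All are labeled in the truth
#' table (INHERITED_ARTIFACT, RECURRENT_ERROR, HP_ERROR).
#'
#' @param cohort a `trio_cohort`.
#' @param config the generator configuration (uses `config$confounders`).
#' @return the cohort with confounder variants, calls, evidence, contexts
#'   and truth rows appended. With all rates zero the cohort is returned
#'   unchanged.
#' @export
inject_confounders <- function(cohort, config) {
  rates <- config$confounders
  if (all(unlist(rates) == 0)) return(cohort)
  ped <- cohort$pedigree
  children <- pedigree_children(ped)
  glen <- cohort$genome$length[1L]
  chrom <- cohort$genome$chrom[1L]

  new_rows <- vector("list", 0L)
  avoid <- cohort$truth$pos
  for (i in seq_len(nrow(children))) {
    kid <- children$child_id[i]
    fam <- children$family_id[i]

    n_runs <- stats::rpois(1L, rates$dropped_run_rate)
    for (r in seq_len(n_runs)) {
      k <- 3L + stats::rpois(1L, 0.8)
      anchor <- sim_positions(1L, glen, min_gap = 2500L, avoid = avoid)
      offs <- sort(sample(0:900, k))
      pos <- anchor + offs
      avoid <- c(avoid, pos)
      new_rows[[length(new_rows) + 1L]] <- data.table::data.table(
        family_id = fam, child_id = kid, chrom = chrom, pos = pos,
        true_class = "INHERITED_ARTIFACT",
        origin = sample(c("P", "M"), 1L), true_ab = 0.5, hap_linked = TRUE)
    }
    n_rec <- stats::rpois(1L, rates$recurrent_artifact_rate)
    if (n_rec > 0L) {
      pos <- sim_positions(n_rec, glen, avoid = avoid)
      avoid <- c(avoid, pos)
      new_rows[[length(new_rows) + 1L]] <- data.table::data.table(
        family_id = fam, child_id = kid, chrom = chrom, pos = pos,
        true_class = "RECURRENT_ERROR", origin = NA_character_,
        true_ab = 0.35, hap_linked = FALSE)
    }
    n_hp <- stats::rpois(1L, rates$homopolymer_noise_rate)
    if (n_hp > 0L) {
      pos <- sim_positions(n_hp, glen, avoid = avoid)
      new_rows[[length(new_rows) + 1L]] <- data.table::data.table(
        family_id = fam, child_id = kid, chrom = chrom, pos = pos,
        true_class = "HP_ERROR", origin = NA_character_,
        true_ab = 0.45, hap_linked = FALSE)
    }
  }
  if (!length(new_rows)) return(cohort)
  conf <- data.table::rbindlist(new_rows)

  # realize alleles and contexts
  is_hp <- conf$true_class == "HP_ERROR"
  rz <- realize_class(sample(SPECTRUM_CLASSES[1:6], nrow(conf),
                             replace = TRUE))
  ref_v <- rz$ref; alt_v <- rz$alt
  ctx_v <- rep(NA_character_, nrow(conf))
  if (any(!is_hp)) {
    ctx_v[!is_hp] <- gen_contexts(ref_v[!is_hp], alt_v[!is_hp],
                                  rep(FALSE, sum(!is_hp)),
                                  rep(FALSE, sum(!is_hp)))
  }
  if (any(is_hp)) {
    hp <- gen_hp_contexts(sum(is_hp))
    ref_v[is_hp] <- hp$ref
    alt_v[is_hp] <- hp$alt
    ctx_v[is_hp] <- hp$context
  }
  conf[, `:=`(ref = ref_v, alt = alt_v, context = ctx_v)]

  ev_new <- sim_reads(conf, ped, config, id_offset = 100L)
  calls_new <- sim_candidate_calls(conf, ped, config)

  # cohort-recurrence carriers: unrelated children whose HiFi reads carry
  # the same false allele
  rec <- conf[conf$true_class == "RECURRENT_ERROR", ]
  carrier_rows <- vector("list", 0L)
  truth_extra <- vector("list", 0L)
  if (nrow(rec)) {
    for (j in seq_len(nrow(rec))) {
      pool <- children$child_id[children$family_id != rec$family_id[j]]
      carriers <- sample(pool, min(2L, length(pool)))
      for (cc in carriers) {
        n_alt <- sample(2:4, 1L)
        n_ref <- sample(3:6, 1L)
        carrier_rows[[length(carrier_rows) + 1L]] <- data.table::data.table(
          sample_id = cc, platform = "HIFI", tissue = "BLOOD",
          chrom = rec$chrom[j], pos = rec$pos[j],
          read_id = sprintf("rc_%d_%s_%d", j, cc, seq_len(n_alt + n_ref)),
          mapq = 60L,
          base_qual = sample(25:45, n_alt + n_ref, replace = TRUE),
          allele = c(rep(rec$alt[j], n_alt), rep(rec$ref[j], n_ref)),
          flank_left = sample(2000:9000, n_alt + n_ref, replace = TRUE),
          flank_right = sample(2000:9000, n_alt + n_ref, replace = TRUE),
          tag_snps = ".", hap = "P", is_child = TRUE,
          rstart = 0L, rend = 0L)
        truth_extra[[length(truth_extra) + 1L]] <- data.table::data.table(
          chrom = rec$chrom[j], pos = rec$pos[j], ref = rec$ref[j],
          alt = rec$alt[j], child_id = cc,
          true_class = "RECURRENT_ERROR", true_parent = NA_character_,
          true_ab = 0.1)
      }
    }
  }
  if (length(carrier_rows)) {
    ev_new <- data.table::rbindlist(list(ev_new,
                                         data.table::rbindlist(carrier_rows)),
                                    use.names = TRUE)
  }

  truth_new <- conf[, list(chrom, pos, ref, alt, child_id, true_class,
                           true_parent = origin, true_ab)]
  if (length(truth_extra)) {
    truth_new <- data.table::rbindlist(
      c(list(truth_new), truth_extra), use.names = TRUE)
  }

  cohort$evidence <- data.table::rbindlist(list(cohort$evidence, ev_new),
                                           use.names = TRUE, fill = TRUE)
  cohort$calls <- data.table::rbindlist(list(cohort$calls, calls_new),
                                        use.names = TRUE)
  cohort$truth <- data.table::rbindlist(list(cohort$truth, truth_new),
                                        use.names = TRUE)
  cohort$context <- data.table::rbindlist(
    list(cohort$context, conf[, list(chrom, pos, context)]),
    use.names = TRUE)
  cohort
}

#' Write a simulated cohort to a directory
#'
#' Emits `pedigree.tsv`, `evidence.tsv`, `truth.tsv`, `context.tsv`,
#' `features.bed`, `config.json` and one VCF per family per caller under
#' `vcf/`.
#'
#' @param cohort a `trio_cohort`.
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  write_pedigree(cohort$pedigree, file.path(dir, "pedigree.tsv"))
  write_read_evidence(cohort$evidence, file.path(dir, "evidence.tsv"))
  write_truth_table(cohort$truth, file.path(dir, "truth.tsv"))
  write_context_table(cohort$context, file.path(dir, "context.tsv"))
  write_feature_bed(cohort$features, file.path(dir, "features.bed"))
  write_generator_config(cohort$config, file.path(dir, "config.json"))
  fams <- unique(cohort$pedigree$family_id)
  for (fam in fams) {
    members <- cohort$pedigree$sample_id[cohort$pedigree$family_id == fam]
    for (caller in c("gatk", "dv")) {
      sub <- cohort$calls[cohort$calls$family_id == fam &
                            cohort$calls$caller_id == caller, ]
      write_trio_vcf(sub, file.path(dir, "vcf",
                                    sprintf("%s_%s.vcf", fam, caller)),
                     sample_order = members, source_id = caller,
                     contigs = cohort$genome)
    }
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir cohort directory.
#' @return a `trio_cohort` list.
#' @export
read_cohort <- function(dir) {
  ped <- read_pedigree(file.path(dir, "pedigree.tsv"))
  config <- read_generator_config(file.path(dir, "config.json"))
  vcfs <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                     full.names = TRUE)
  calls <- data.table::rbindlist(lapply(vcfs, function(f) {
    fam <- sub("_(gatk|dv)\\.vcf$", "", basename(f))
    cc <- read_trio_vcf(f, ped)
    cc[, family_id := fam]
    cc
  }))
  cohort <- list(
    pedigree = ped, calls = calls,
    evidence = read_read_evidence(file.path(dir, "evidence.tsv")),
    truth = read_truth_table(file.path(dir, "truth.tsv")),
    features = read_feature_bed(file.path(dir, "features.bed")),
    context = read_context_table(file.path(dir, "context.tsv")),
    genome = data.table::as.data.table(config$genome), config = config)
  class(cohort) <- "trio_cohort"
  cohort
}
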