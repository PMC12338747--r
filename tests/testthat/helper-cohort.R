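# Shared fixtures and independent oracles. Cohorts are generated once per
# test session and cached; all fixtures are built in code.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 4 families (2 quads), 8 Mbp genome: small enough for unit tests, large
# enough that every stage sees real work
small_preset <- function(seed = 7L) {
  cfg <- calibrated_preset(genome_bp = 8e6, seed = seed)
  cfg$n_families <- 4L
  cfg$n_quads <- 2L
  cfg
}

small_cohort <- function() {
  cache_get("small_cohort", function() simulate_cohort(small_preset()))
}

small_result <- function() {
  cache_get("small_result", function() run_pipeline(small_cohort()))
}

# full calibrated cohort (73 transmissions); used by the acceptance
# tests only
full_result <- function() {
  cache_get("full_result", function() {
    co <- simulate_cohort(calibrated_preset(seed = 1L))
    list(cohort = co, result = run_pipeline(co))
  })
}

# --- independent oracles ----------------------------------------------------

# brute-force sliding-window cluster scan: a position is clustered iff some
# window of `window` consecutive bases contains >= k candidate positions
# including it
oracle_cluster_flags <- function(pos, window = 1000L, k = 3L) {
  flag <- logical(length(pos))
  starts <- seq(min(pos) - window + 1L, max(pos))
  for (s in starts) {
    inside <- pos >= s & pos <= s + window - 1L
    if (sum(inside) >= k) flag[inside] <- TRUE
  }
  flag
}

# all-pairs scan for MnM pairs
oracle_mnm_pairs <- function(pos, max_dist = 500L) {
  pairs <- list()
  pos <- sort(pos)
  n <- length(pos)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && pos[j] - pos[i] >= 1L && pos[j] - pos[i] <= max_dist) {
        pairs[[length(pairs) + 1L]] <- c(pos[i], pos[j])
      }
    }
  }
  pairs
}

# exact lower binomial tail by enumeration
oracle_binom_tail <- function(k, n, p = 0.5) {
  sum(vapply(0:k, function(x) choose(n, x) * p^x * (1 - p)^(n - x),
             numeric(1)))
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# minimal pedigree: one quad family
quad_pedigree <- function() {
  validate_pedigree(data.table::data.table(
    family_id = "f1",
    sample_id = c("fa", "mo", "p1", "s1"),
    father_id = c(NA, NA, "fa", "fa"),
    mother_id = c(NA, NA, "mo", "mo"),
    sex = c("M", "F", "M", "F"),
    role = c("father", "mother", "proband", "sibling"),
    father_age_at_birth = c(NA, NA, 32, 35),
    mother_age_at_birth = c(NA, NA, 30, 33)))
}

# evidence row builder with sensible defaults
ev_row <- function(sample_id, allele, platform = "HIFI", tissue = "BLOOD",
                   chrom = "chr1", pos = 5000L, mapq = 60L, base_qual = 40L,
                   flank_left = 500L, flank_right = 500L, tag_snps = ".",
                   read_id = NULL) {
  data.table::data.table(
    sample_id = sample_id, platform = platform, tissue = tissue,
    chrom = chrom, pos = as.integer(pos),
    read_id = read_id %||% paste0("r", sample(1e9, 1)),
    mapq = as.integer(mapq), base_qual = as.integer(base_qual),
    allele = allele, flank_left = as.integer(flank_left),
    flank_right = as.integer(flank_right), tag_snps = tag_snps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
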