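# Shared small helpers: coordinate conventions, genotype parsing, interval
# algebra. All BED-style intervals in this package are 0-based half-open;
# all VCF/read positions are 1-based. Conversions are centralized here.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a 1-based position to its 0-based half-open interval
#'
#' @param pos integer vector of 1-based positions.
#' @return data.table with `start` (0-based) and `end` (half-open) columns,
#'   each interval of length 1.
#' @keywords internal
pos_to_bed <- function(pos) {
  data.table::data.table(start = as.integer(pos) - 1L, end = as.integer(pos))
}

#' Test which 1-based positions fall inside 0-based half-open intervals
#'
#' @param chrom,pos vectors describing query points (1-based).
#' @param track a feature track data.table with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return logical vector, TRUE where the point overlaps any interval.
#' @keywords internal
points_in_track <- function(chrom, pos, track) {
  if (is.null(track) || nrow(track) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    tr <- track[track$chrom == ch, ]
    if (nrow(tr) == 0L) next
    q <- IRanges::IRanges(start = pos[idx], width = 1L)
    s <- IRanges::IRanges(start = tr$start + 1L, end = tr$end)
    hit[idx] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Merge possibly-overlapping 0-based half-open intervals per chromosome
#' @param dt data.table with chrom, start, end (0-based half-open).
#' @return normalized, sorted, non-overlapping intervals.
#' @keywords internal
reduce_intervals <- function(dt) {
  if (nrow(dt) == 0L) return(dt)
  out <- lapply(split(dt, dt$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.table::data.table(chrom = d$chrom[1L],
                           start = IRanges::start(ir) - 1L,
                           end = IRanges::end(ir))
  })
  out <- data.table::rbindlist(out)
  data.table::setorder(out, chrom, start)
  out[]
}

#' Intersect two interval sets (0-based half-open)
#' @keywords internal
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  out <- lapply(chroms, function(ch) {
    ia <- IRanges::IRanges(start = a$start[a$chrom == ch] + 1L,
                           end = a$end[a$chrom == ch])
    ib <- IRanges::IRanges(start = b$start[b$chrom == ch] + 1L,
                           end = b$end[b$chrom == ch])
    ix <- IRanges::intersect(ia, ib)
    if (length(ix) == 0L) return(NULL)
    data.table::data.table(chrom = ch, start = IRanges::start(ix) - 1L,
                           end = IRanges::end(ix))
  })
  out <- data.table::rbindlist(out)
  if (nrow(out)) data.table::setorder(out, chrom, start)
  out[]
}

#' Total base pairs covered by an interval set
#' @keywords internal
interval_bp <- function(dt) {
  if (nrow(dt) == 0L) return(0)
  sum(as.numeric(dt$end - dt$start))
}

# --- genotype helpers -------------------------------------------------------

#' Split a GT string into allele codes
#'
#' Handles diploid ("0/1", "1|0") and haploid ("0", "1") genotypes.
#' Missing alleles (".") yield NA.
#' @param gt character vector of GT strings.
#' @return list of integer vectors.
#' @keywords internal
gt_alleles <- function(gt) {
  lapply(strsplit(as.character(gt), "[/|]"), function(a) {
    a[a == "."] <- NA_character_
    as.integer(a)
  })
}

gt_is_homref <- function(gt) {
  vapply(gt_alleles(gt), function(a) length(a) > 0 && all(!is.na(a)) && all(a == 0L),
         logical(1))
}

gt_has_alt <- function(gt) {
  vapply(gt_alleles(gt), function(a) any(!is.na(a) & a > 0L), logical(1))
}

gt_is_haploid <- function(gt) {
  !grepl("[/|]", gt)
}

#' Which parent(s) could have donated an allele code
#' @keywords internal
gt_carries <- function(gt, code) {
  vapply(gt_alleles(gt), function(a) any(!is.na(a) & a == code), logical(1))
}

# --- misc -------------------------------------------------------------------

#' Derive a stream-specific RNG seed from a master seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 7919) %% 2147483647)
}

stop_row <- function(msg, row) {
  stop(sprintf("%s (row %d)", msg, row), call. = FALSE)
}
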