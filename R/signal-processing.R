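# From raw damage-count tracks to per-region repair time courses.
#
# The pipeline is: sum normalized damage counts per region at each sample
# time, transform to repair fractions against the 0-minute sample,
# rectify to a monotone non-decreasing course, and (optionally) derive an
# empirical per-interval rate surrogate.

#' Count dipyrimidine sites in a sequence
#'
#' Counts adjacent pyrimidine-pyrimidine dinucleotides (TT, TC, CT, CC)
#' on the requested strand; on the minus strand this equals the number of
#' purine-purine dinucleotides (AA, AG, GA, GG) of the given (plus
#' strand) sequence. Dinucleotides containing N (or any non-ACGT code)
#' are excluded. UV-induced cyclobutane pyrimidine dimers can only form
#' at such sites, so this is the normalization denominator for damage
#' counts.
#'
#' @param sequence A character string or [Biostrings::DNAString] over
#'   `A, C, G, T, N`.
#' @param strand `"+"` or `"-"`.
#' @return Integer count; `0` for an empty sequence.
#' @examples
#' count_dipyrimidines("TTAA", "+")  # 1 (TT)
#' count_dipyrimidines("AA", "-")    # 1 (reverse complement TT)
#' @export
count_dipyrimidines <- function(sequence, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (inherits(sequence, "XString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 2L) return(0L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("sequence must be over the alphabet {A, C, G, T, N}")
  set <- if (strand == "+") c("C", "T") else c("A", "G")
  hit <- chars %in% set
  sum(hit[-n] & hit[-1L])
}

#' Normalize summed damage counts by available dipyrimidine sites
#'
#' Divides the summed raw damage counts of a region by the number of
#' dipyrimidine sites on the relevant strand. Within one region the
#' repair transformation [region_repair_fraction] is a ratio and the
#' normalization cancels; it is retained so that intermediate per-region
#' outputs remain comparable across regions.
#'
#' @param count_sum Summed raw counts in the region, `>= 0`.
#' @param dipyr_count Number of dipyrimidine sites, `> 0` unless the
#'   counts are all zero.
#' @return Normalized damage value.
#' @export
normalize_damage <- function(count_sum, dipyr_count) {
  stopifnot(is.numeric(count_sum), is.numeric(dipyr_count),
            count_sum >= 0, dipyr_count >= 0)
  if (dipyr_count == 0) {
    if (count_sum > 0)
      stop("non-zero damage counts in a region without dipyrimidine sites")
    return(0)
  }
  count_sum / dipyr_count
}

#' Repair fraction of a region at a sampled time
#'
#' Transforms summed damage at time `t` into the fraction repaired since
#' irradiation: `(S(0) - S(t)) / S(0)` where `S` is the per-region sum of
#' (normalized) damage counts. The result may be negative before
#' rectification (sampling noise) and is at most 1.
#'
#' @param sum0 Per-region damage sum at time 0, `> 0`.
#' @param sum_t Per-region damage sum at time `t` (vectorized).
#' @return Repair fraction(s), `<= 1`.
#' @export
region_repair_fraction <- function(sum0, sum_t) {
  stopifnot(is.numeric(sum0), length(sum0) == 1L, is.numeric(sum_t))
  if (sum0 <= 0)
    stop(unfittable_condition("undamaged region: zero damage at time 0"))
  (sum0 - sum_t) / sum0
}

#' Rectify a repair time course
#'
#' No new lesions arise after the irradiation source is removed, so the
#' true repair fraction is non-negative and non-decreasing. The observed
#' values are rectified sequentially: the first value is clipped at 0 and
#' each later value at its predecessor. The operation is idempotent and
#' leaves already-monotone non-negative courses unchanged.
#'
#' @param values Repair fractions ordered by time.
#' @return Rectified numeric vector, non-negative and non-decreasing.
#' @examples
#' rectify(c(-0.1, 0.2, 0.1))  # 0.0 0.2 0.2
#' @export
rectify <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) == 0L) return(values)
  out <- values
  out[1L] <- max(out[1L], 0)
  for (i in seq_along(out)[-1L]) out[i] <- max(out[i], out[i - 1L])
  out
}

#' Empirical per-interval repair rate surrogate
#'
#' A data-derived stand-in for the ongoing-repair rate: forward finite
#' differences of the rectified repair fractions, with `R(0) = 0`
#' prepended so the first interval is `(0, t_1]`. On rectified input all
#' rates are non-negative.
#'
#' @param times Sampling times, strictly increasing, all `> 0`.
#' @param values Rectified repair fractions at `times`.
#' @return `data.frame` with `t_start`, `t_end`, `rate` (per minute).
#' @examples
#' empirical_repair_rate(c(20, 60, 120), c(0.2, 0.5, 0.6))
#' @export
empirical_repair_rate <- function(times, values) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 1L,
            all(times > 0), !is.unsorted(times, strictly = TRUE))
  t_all <- c(0, times)
  v_all <- c(0, values)
  data.frame(t_start = t_all[-length(t_all)],
             t_end = t_all[-1L],
             rate = diff(v_all) / diff(t_all))
}

#' Aggregate a damage signal track over regions
#'
#' Sums track values whose positions fall inside each region. Strand
#' handling: a region on `+` or `-` takes only the matching strand's
#' track values; a `both`-strand region takes all.
#'
#' @param track A [GenomicRanges::GRanges] with a numeric `score` column
#'   (as returned by [read_signal_track]).
#' @param regions A [GenomicRanges::GRanges] of target regions (names or
#'   a `region_id` column identify them).
#' @return Numeric vector of per-region sums, in `regions` order.
#' @export
aggregate_track <- function(track, regions) {
  stopifnot(is(track, "GRanges"), is(regions, "GRanges"))
  score <- S4Vectors::mcols(track)$score
  if (is.null(score)) stop("track must carry a 'score' metadata column")
  hits <- GenomicRanges::findOverlaps(track, regions, ignore.strand = TRUE)
  if (length(hits) == 0L) return(numeric(length(regions)))
  tr_strand <- as.character(GenomicRanges::strand(track))[S4Vectors::queryHits(hits)]
  rg_strand <- as.character(GenomicRanges::strand(regions))[S4Vectors::subjectHits(hits)]
  keep <- rg_strand == "*" | tr_strand == "*" | tr_strand == rg_strand
  hits_q <- S4Vectors::queryHits(hits)[keep]
  hits_s <- S4Vectors::subjectHits(hits)[keep]
  sums <- numeric(length(regions))
  agg <- tapply(score[hits_q], hits_s, sum)
  sums[as.integer(names(agg))] <- as.numeric(agg)
  sums
}

#' Build per-region repair time courses from damage tracks
#'
#' Full damage-to-repair transformation: for each region, sum the damage
#' track at every sample time, optionally normalize by dipyrimidine
#' counts, convert to repair fractions against the time-0 sum, and
#' rectify. Supports multiple experimental courses (each with its own
#' time-0 sample, e.g. `{0, 60}` and `{0, 20, 120}` minutes): fractions
#' are computed against each course's own time-0 denominator, which
#' removes course-specific sequencing depth, and then merged.
#'
#' @param tracks Named list of [GenomicRanges::GRanges] damage tracks;
#'   names are times in minutes (e.g. `"0"`, `"20"`), or a list of such
#'   lists for multiple courses (each must contain `"0"`).
#' @param regions [GenomicRanges::GRanges] with a `region_id` metadata
#'   column (and optionally `role`).
#' @param dipyr Optional numeric vector of per-region dipyrimidine
#'   counts (same order as `regions`); cancels in the ratio but scales
#'   the reported raw sums.
#' @return `data.frame` with columns `region_id`, `time`, `raw` (pre
#'   rectification) and `value` (rectified), one row per region and
#'   positive sample time. Regions with zero damage at time 0 are
#'   dropped with a warning.
#' @export
repair_time_courses <- function(tracks, regions, dipyr = NULL) {
  stopifnot(is(regions, "GRanges"))
  ids <- S4Vectors::mcols(regions)$region_id
  if (is.null(ids)) stop("regions must carry a 'region_id' metadata column")
  if (is(tracks[[1L]], "GRanges")) tracks <- list(tracks)
  per_course <- lapply(tracks, function(course) {
    stopifnot(!is.null(names(course)), "0" %in% names(course))
    tms <- as.numeric(names(course))
    sums <- vapply(course, aggregate_track, numeric(length(regions)),
                   regions = regions)
    if (length(regions) == 1L) sums <- matrix(sums, nrow = 1L)
    if (!is.null(dipyr)) {
      stopifnot(length(dipyr) == length(regions))
      sums <- vapply(seq_along(regions), function(i)
        vapply(sums[i, ], normalize_damage, numeric(1L),
               dipyr_count = dipyr[i]),
        numeric(ncol(sums)))
      sums <- t(sums)
    }
    list(times = tms, sums = sums)
  })
  rows <- lapply(seq_along(regions), function(i) {
    frac <- list()
    for (course in per_course) {
      i0 <- which(course$times == 0)
      s0 <- course$sums[i, i0]
      pos <- which(course$times > 0)
      if (s0 <= 0) return(NULL)
      for (j in pos) {
        frac[[length(frac) + 1L]] <- c(time = course$times[j],
                                       raw = region_repair_fraction(s0, course$sums[i, j]))
      }
    }
    if (length(frac) == 0L) return(NULL)
    tab <- as.data.frame(do.call(rbind, frac))
    tab <- tab[order(tab$time), , drop = FALSE]
    data.frame(region_id = ids[i], time = tab$time, raw = tab$raw,
               value = rectify(tab$raw))
  })
  dropped <- sum(vapply(rows, is.null, logical(1L)))
  if (dropped > 0L)
    warning(sprintf("%d region(s) dropped: zero damage at time 0", dropped))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-region time courses as TSV
#'
#' One row per region with post-rectification columns `t<time>` plus the
#' raw pre-rectification values as `raw_t<time>`.
#'
#' @param courses Long-format output of [repair_time_courses].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_time_courses <- function(courses, path) {
  stopifnot(all(c("region_id", "time", "value") %in% names(courses)))
  ids <- unique(courses$region_id)
  times <- sort(unique(courses$time))
  wide <- data.frame(region_id = ids)
  for (t in times) {
    sel <- courses[courses$time == t, ]
    wide[[paste0("t", t)]] <- sel$value[match(ids, sel$region_id)]
    if ("raw" %in% names(courses))
      wide[[paste0("raw_t", t)]] <- sel$raw[match(ids, sel$region_id)]
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
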