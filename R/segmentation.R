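# Genome segmentation into repair strata.
#
# Two setups are supported. The "TCR" setup distinguishes transcription
# units (TUs) with evident transcription-coupled repair: their
# transcribed strand (TS) and non-transcribed strand (NTS) are each split
# into start / centre / end thirds (in transcription order), and all
# remaining genomic space -- including TUs without a TCR signature --
# becomes strand-merged non-TCR blocks. The "gene" setup is the
# traditional TS / NTS / intergenic partition of all TUs.

#' Classify transcription units as TCR or non-TCR
#'
#' A TU is labelled TCR when the rectified repair fraction of its
#' transcribed strand at 20 minutes exceeds the threshold: regions under
#' transcription-coupled repair show strong early repair, whereas
#' global-genome repair acts later.
#'
#' @param tu_ids Character vector of TU identifiers.
#' @param repair_ts_20 Rectified TS repair fraction at 20 minutes per TU
#'   (`NA` allowed: such TUs are labelled non-TCR with a note).
#' @param threshold Early-repair cutoff, default `0.2`.
#' @return Character vector (`"TCR"` / `"non-TCR"`) named by `tu_ids`.
#' @export
classify_tcr <- function(tu_ids, repair_ts_20, threshold = 0.2) {
  stopifnot(length(tu_ids) == length(repair_ts_20), is.numeric(threshold))
  missing <- is.na(repair_ts_20)
  if (any(missing))
    message(sprintf("%d TU(s) lack a 20-minute repair value; labelled non-TCR",
                    sum(missing)))
  lab <- ifelse(!missing & repair_ts_20 > threshold, "TCR", "non-TCR")
  stats::setNames(lab, tu_ids)
}

#' Split a region into start, centre and end thirds
#'
#' Divides `[start, end)` into three contiguous, non-overlapping thirds
#' that tile the region exactly; remainder nucleotides go to the centre.
#' On the minus strand the "start" third is the transcriptionally first
#' one, i.e. the right end in genome coordinates. Regions shorter than 3
#' nt cannot be split and fall back to a single centre piece flagged
#' `unsplit`.
#'
#' @param region A length-1 [GenomicRanges::GRanges] with strand `+` or
#'   `-`.
#' @return A [GenomicRanges::GRanges] of up to three ranges with
#'   metadata columns `part` (`start`/`centre`/`end`) and `unsplit`.
#' @export
subdivide_region <- function(region) {
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  s <- GenomicRanges::start(region) - 1L  # to 0-based
  e <- GenomicRanges::end(region)        # half-open end
  w <- e - s
  str <- as.character(GenomicRanges::strand(region))
  stopifnot(str %in% c("+", "-"))
  chrom <- as.character(GenomicRanges::seqnames(region))
  if (w < 3L) {
    out <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(s + 1L, e), strand = str)
    S4Vectors::mcols(out)$part <- "centre"
    S4Vectors::mcols(out)$unsplit <- TRUE
    return(out)
  }
  k <- w %/% 3L
  bounds0 <- c(s, s + k, e - k, e)  # 0-based cut points; centre absorbs remainder
  gr <- GenomicRanges::GRanges(
    rep(chrom, 3L),
    IRanges::IRanges(start = bounds0[1:3] + 1L, end = bounds0[2:4]),
    strand = str)
  parts <- if (str == "+") c("start", "centre", "end") else c("end", "centre", "start")
  S4Vectors::mcols(gr)$part <- parts
  S4Vectors::mcols(gr)$unsplit <- FALSE
  gr[order(match(S4Vectors::mcols(gr)$part, c("start", "centre", "end")))]
}

resolve_tu_overlaps <- function(tus) {
  keep <- rep(TRUE, length(tus))
  for (str in unique(as.character(GenomicRanges::strand(tus)))) {
    idx <- which(as.character(GenomicRanges::strand(tus)) == str & keep)
    sub <- tus[idx]
    hits <- GenomicRanges::findOverlaps(sub, sub, ignore.strand = FALSE)
    hits <- hits[S4Vectors::queryHits(hits) < S4Vectors::subjectHits(hits)]
    for (h in seq_along(hits)) {
      a <- idx[S4Vectors::queryHits(hits)[h]]
      b <- idx[S4Vectors::subjectHits(hits)[h]]
      if (!keep[a] || !keep[b]) next
      drop <- if (GenomicRanges::width(tus[a]) >= GenomicRanges::width(tus[b])) b else a
      keep[drop] <- FALSE
      message(sprintf("overlapping TUs on strand %s: dropping the shorter of %s / %s",
                      str, S4Vectors::mcols(tus)$tu_id[a],
                      S4Vectors::mcols(tus)$tu_id[b]))
    }
  }
  tus[keep]
}

#' Build the analysis region set
#'
#' Constructs the per-strand partition used for fitting. In `"TCR"` mode
#' every TCR-labelled TU contributes six stranded subregions (TS and NTS
#' thirds, roles `TS_start`, ..., `NTS_end`) and the remaining genomic
#' space -- including non-TCR TUs -- becomes strand-merged (`*`) non-TCR
#' blocks bounded by TCR TU ends. In `"gene"` mode every TU contributes
#' whole-TU `TS` and `NTS` regions and the complement becomes
#' `intergenic` blocks.
#'
#' @param tus [GenomicRanges::GRanges] of transcription units with a
#'   `tu_id` metadata column; same-strand overlaps are resolved by
#'   keeping the longer TU.
#' @param tcr_labels Output of [classify_tcr] (named by `tu_id`); only
#'   used in `"TCR"` mode.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param mode `"TCR"` or `"gene"`.
#' @param min_subregion Minimum subregion width (nt) for a third to be
#'   flagged fit-eligible, default 9 for the whole TU (3 per third).
#' @return A [GenomicRanges::GRanges] with metadata columns `region_id`,
#'   `role`, `parent_id`, `fit_eligible`.
#' @export
build_region_set <- function(tus, tcr_labels = NULL, chrom_sizes,
                             mode = c("TCR", "gene"), min_subregion = 9L) {
  mode <- match.arg(mode)
  stopifnot(is(tus, "GRanges"), !is.null(S4Vectors::mcols(tus)$tu_id),
            !is.null(names(chrom_sizes)))
  bad <- GenomicRanges::end(tus) >
    chrom_sizes[as.character(GenomicRanges::seqnames(tus))] |
    GenomicRanges::start(tus) < 1L
  if (any(is.na(bad)) || any(bad))
    stop("malformed annotation: TU outside chromosome bounds")
  tus <- resolve_tu_overlaps(tus)
  genome_gr <- GenomicRanges::GRanges(
    names(chrom_sizes), IRanges::IRanges(1L, unname(chrom_sizes)))

  strata <- list()
  flip <- c("+" = "-", "-" = "+")
  if (mode == "TCR") {
    ids <- as.character(S4Vectors::mcols(tus)$tu_id)
    is_tcr <- if (is.null(tcr_labels)) rep(TRUE, length(tus)) else
      unname(tcr_labels[ids]) == "TCR"
    tcr_tus <- tus[which(is_tcr)]
    for (i in seq_along(tcr_tus)) {
      tu <- tcr_tus[i]
      id <- S4Vectors::mcols(tu)$tu_id
      eligible <- GenomicRanges::width(tu) >= min_subregion
      thirds <- subdivide_region(tu)
      for (role_strand in c("TS", "NTS")) {
        g <- thirds
        if (role_strand == "NTS")
          GenomicRanges::strand(g) <- flip[as.character(GenomicRanges::strand(thirds))]
        S4Vectors::mcols(g)$role <-
          paste(role_strand, S4Vectors::mcols(thirds)$part, sep = "_")
        S4Vectors::mcols(g)$parent_id <- id
        S4Vectors::mcols(g)$region_id <-
          paste(id, S4Vectors::mcols(g)$role, sep = ".")
        S4Vectors::mcols(g)$fit_eligible <-
          eligible & !S4Vectors::mcols(thirds)$unsplit
        S4Vectors::mcols(g)$part <- NULL
        S4Vectors::mcols(g)$unsplit <- NULL
        strata[[length(strata) + 1L]] <- g
      }
    }
    covered <- if (length(tcr_tus)) GenomicRanges::reduce(
      GenomicRanges::granges(tcr_tus), ignore.strand = TRUE) else
        GenomicRanges::GRanges()
    GenomicRanges::strand(covered) <- "*"
    blocks <- GenomicRanges::setdiff(genome_gr, covered, ignore.strand = TRUE)
    if (length(blocks)) {
      S4Vectors::mcols(blocks)$role <- "nonTCR"
      S4Vectors::mcols(blocks)$parent_id <- NA_character_
      S4Vectors::mcols(blocks)$region_id <- paste0(
        "nonTCR.", as.character(GenomicRanges::seqnames(blocks)), ".",
        seq_along(blocks))
      S4Vectors::mcols(blocks)$fit_eligible <-
        GenomicRanges::width(blocks) >= min_subregion
      strata[[length(strata) + 1L]] <- blocks
    }
  } else {
    for (i in seq_along(tus)) {
      tu <- tus[i]
      id <- S4Vectors::mcols(tu)$tu_id
      for (role_strand in c("TS", "NTS")) {
        g <- GenomicRanges::granges(tu)
        if (role_strand == "NTS")
          GenomicRanges::strand(g) <- flip[as.character(GenomicRanges::strand(tu))]
        S4Vectors::mcols(g)$role <- role_strand
        S4Vectors::mcols(g)$parent_id <- id
        S4Vectors::mcols(g)$region_id <- paste(id, role_strand, sep = ".")
        S4Vectors::mcols(g)$fit_eligible <- TRUE
        strata[[length(strata) + 1L]] <- g
      }
    }
    covered <- GenomicRanges::reduce(GenomicRanges::granges(tus),
                                     ignore.strand = TRUE)
    GenomicRanges::strand(covered) <- "*"
    blocks <- GenomicRanges::setdiff(genome_gr, covered, ignore.strand = TRUE)
    if (length(blocks)) {
      S4Vectors::mcols(blocks)$role <- "intergenic"
      S4Vectors::mcols(blocks)$parent_id <- NA_character_
      S4Vectors::mcols(blocks)$region_id <- paste0(
        "intergenic.", as.character(GenomicRanges::seqnames(blocks)), ".",
        seq_along(blocks))
      S4Vectors::mcols(blocks)$fit_eligible <- TRUE
      strata[[length(strata) + 1L]] <- blocks
    }
  }
  out <- do.call(c, strata)
  GenomeInfoDb::seqlevels(out) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(out) <- unname(chrom_sizes)
  out
}

#' Relative distance to the nearer of centromere and telomere
#'
#' `d_mere = 2 * min(|x - c|, |x - t|) / |c - t|`: 0 at either landmark
#' and 1 at their midpoint (the farthest a position can be from both),
#' hence the division by half the centromere-telomere span.
#'
#' @param x Position(s), conventionally the region midpoint.
#' @param centromere,telomere Landmark positions (scalars), distinct.
#' @return Values in `[0, 1]` for `x` between the landmarks.
#' @examples
#' d_mere(200, centromere = 100, telomere = 500)  # 0.5
#' @export
d_mere <- function(x, centromere, telomere) {
  stopifnot(is.numeric(x), length(centromere) == 1L, length(telomere) == 1L)
  span <- abs(centromere - telomere)
  if (span == 0) stop("invalid chromosome geometry: centromere equals telomere")
  2 * pmin(abs(x - centromere), abs(x - telomere)) / span
}

#' Per-region centromere/telomere distance feature
#'
#' Applies [d_mere] to region midpoints given a per-chromosome landmark
#' table.
#'
#' @param regions [GenomicRanges::GRanges].
#' @param meres `data.frame` with columns `chrom`, `centromere_pos`,
#'   `telomere_pos`.
#' @return Numeric vector, one value per region (`NA` if the chromosome
#'   has no landmark entry).
#' @export
region_d_mere <- function(regions, meres) {
  stopifnot(is(regions, "GRanges"),
            all(c("chrom", "centromere_pos", "telomere_pos") %in% names(meres)))
  mid <- (GenomicRanges::start(regions) + GenomicRanges::end(regions)) / 2
  chrom <- as.character(GenomicRanges::seqnames(regions))
  idx <- match(chrom, meres$chrom)
  out <- rep(NA_real_, length(regions))
  ok <- !is.na(idx)
  out[ok] <- mapply(d_mere, mid[ok], meres$centromere_pos[idx[ok]],
                    meres$telomere_pos[idx[ok]])
  out
}
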