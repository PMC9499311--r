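# Readers and writers for the standard formats the pipeline touches:
# bedGraph signal tracks, BED6 annotations, FASTA genomes and TSV tables.
# Parsing is delegated to rtracklayer / Biostrings.

#' Read a bedGraph signal track
#'
#' Four-column bedGraph (chrom, start, end, value). bedGraph carries no
#' strand, so per-strand assays ship one file per strand: pass the
#' strand the file represents.
#'
#' @param path bedGraph file.
#' @param strand `"+"`, `"-"` or `"*"` (both/unstranded).
#' @return [GenomicRanges::GRanges] with a `score` column.
#' @export
read_signal_track <- function(path, strand = "*") {
  stopifnot(strand %in% c("+", "-", "*"))
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomicRanges::strand(gr) <- strand
  gr
}

#' Read transcription units from BED6
#'
#' @param path BED file with at least 6 columns (name carries the TU
#'   id, strand is required).
#' @return [GenomicRanges::GRanges] with `tu_id`.
#' @export
read_tus_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) stop("BED file must carry a name column with TU ids")
  S4Vectors::mcols(gr)$tu_id <- nm
  gr
}

#' Write regions as BED6 with the role in the name field
#'
#' @param regions [GenomicRanges::GRanges].
#' @param names Character vector for the BED name column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(regions, names, path) {
  stopifnot(is(regions, "GRanges"), length(names) == length(regions))
  str <- as.character(GenomicRanges::strand(regions))
  str[str == "*"] <- "."
  tab <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start0 = GenomicRanges::start(regions) - 1L,
    end0 = GenomicRanges::end(regions),
    name = names, score = 0L, strand = str)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Read a per-region feature table
#'
#' @param path TSV with a `region_id` column and one column per feature.
#' @return `data.frame`.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"region_id" %in% names(tab))
    stop("feature table must have a region_id column")
  tab
}

#' Read centromere/telomere landmark positions
#'
#' @param path Three-column TSV: `chrom`, `centromere_pos`,
#'   `telomere_pos`.
#' @return `data.frame`.
#' @export
read_meres <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "centromere_pos", "telomere_pos") %in% names(tab)))
  tab
}

#' Propagate TU-level feature values to their subregions
#'
#' Start, centre and end of the TS and NTS of one TU are linked to that
#' TU's single feature value, smoothing out subregion-level noise; both
#' strands share the same value.
#'
#' @param regions [GenomicRanges::GRanges] from [build_region_set]
#'   (needs `region_id` and `parent_id`).
#' @param tu_features `data.frame` with `region_id` (TU ids) and
#'   feature columns.
#' @return `data.frame` keyed by subregion `region_id` with the parent
#'   TU's feature values (`NA` for regions without a parent).
#' @export
share_features <- function(regions, tu_features) {
  stopifnot(is(regions, "GRanges"),
            "region_id" %in% names(tu_features))
  parent <- S4Vectors::mcols(regions)$parent_id
  idx <- match(parent, tu_features$region_id)
  out <- tu_features[idx, , drop = FALSE]
  out$region_id <- S4Vectors::mcols(regions)$region_id
  rownames(out) <- NULL
  out
}
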