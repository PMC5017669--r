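#' Format a percentage in the summary-table convention
#'
#' `100 * numerator / denominator` rounded to one decimal; a nonzero
#' numerator whose rounded percentage is 0.0 renders as `"<0.1"`, and a
#' true zero renders as `"0"`. This is the single formatting authority for
#' every percentage the package prints.
#'
#' @param numerator,denominator Non-negative numerators and positive
#'   denominators (vectorised, recycled).
#' @return Character vector.
#' @examples
#' render_percent(17429392, 19395459)  # "89.9"
#' render_percent(17, 17429392)        # "<0.1"
#' @export
render_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive",
                                  call. = FALSE)
  if (any(numerator < 0)) stop("numerator must be non-negative",
                               call. = FALSE)
  pct <- sprintf("%.1f", 100 * numerator / denominator)
  out <- ifelse(numerator == 0, "0", ifelse(pct == "0.0", "<0.1", pct))
  as.character(out)
}

fmt_count <- function(x) formatC(x, big.mark = ",", format = "d")

#' Render an assignment summary with the study's percentage conventions
#'
#' Formats each count as `"count (percent)"` with two denominator
#' conventions: the ">= 16 nt" column is a percentage of total reads, and
#' every other percentage column (human, human miRNA, per-virus, unknown)
#' uses the reads >= 16 nt as denominator.
#'
#' @param summary Tibble from [assignment_summary()] (or rows of the same
#'   shape: `sample`, `total_reads`, `n_ge16`, `human`, `human_mirna`, one
#'   column per virus, `unknown`; a `cross_species` column is ignored).
#' @return Tibble of character columns, one row per sample.
#' @export
render_summary <- function(summary) {
  fixed <- c("sample", "total_reads", "n_ge16", "human", "human_mirna",
             "unknown", "cross_species")
  viral <- setdiff(names(summary), fixed)
  out <- tibble::tibble(
    sample = summary$sample,
    total_reads = fmt_count(summary$total_reads),
    reads_ge16 = paste0(fmt_count(summary$n_ge16), " (",
                        render_percent(summary$n_ge16,
                                       summary$total_reads), ")"),
    human = paste0(fmt_count(summary$human), " (",
                   render_percent(summary$human, summary$n_ge16), ")"),
    human_mirna = paste0(fmt_count(summary$human_mirna), " (",
                         render_percent(summary$human_mirna,
                                        summary$n_ge16), ")"))
  for (sp in viral) {
    out[[sp]] <- paste0(fmt_count(summary[[sp]]), " (",
                        render_percent(summary[[sp]], summary$n_ge16), ")")
  }
  out$unknown <- paste0(fmt_count(summary$unknown), " (",
                        render_percent(summary$unknown, summary$n_ge16),
                        ")")
  out
}

#' Published read-assignment counts of the modelled eight-sample study
#'
#' The per-sample read accounting (total reads, reads >= 16 nt, human,
#' human-miRNA, per-virus and unknown read counts) of the eight-library
#' AAV2/helper-virus co-infection small RNA-Seq experiment whose design the
#' simulator emulates. Bundled as a plain TSV; used to validate the
#' percentage renderer and the helper-dependence arithmetic (viral reads
#' rise >200-fold with helper co-infection) without access to the original
#' sequencing data.
#'
#' @return Tibble with columns `sample`, `total_reads`, `n_ge16`, `human`,
#'   `human_mirna`, `aav2`, `ad2`, `hsv1`, `unknown`.
#' @export
study_read_counts <- function() {
  path <- system.file("extdata", "study_read_counts.tsv",
                      package = "srnaspot", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Export hotspots as BED6
#'
#' Coordinates convert from the package's 1-based inclusive convention to
#' BED's 0-based half-open at this boundary only; the score field carries
#' the read count and the name field the `sR-<start>` label. Hotspot
#' extent is taken as the single 5'-end nucleotide.
#'
#' @param hotspots An `srna_hotspots` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspots_bed <- function(hotspots, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = hotspots$ref_id,
    ranges = IRanges::IRanges(start = hotspots$five_prime, width = 1L),
    strand = hotspots$strand,
    name = hotspots$name,
    score = as.numeric(hotspots$count))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export a pileup or binned track as bedGraph
#'
#' One file per strand, as bedGraph carries no strand field.
#'
#' @param track An `srna_track` or `srna_binned`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  width <- attr(track, "width")
  pos <- if (is.null(width)) track$pos else track$bin_start
  w <- if (is.null(width)) 1L else width
  gr <- GenomicRanges::GRanges(
    seqnames = attr(track, "ref_id"),
    ranges = IRanges::IRanges(start = pos, width = w),
    score = as.numeric(track$count))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
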