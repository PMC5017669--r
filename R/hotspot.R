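#' Strand-specific 5'-end pileup at single-nucleotide resolution
#'
#' Counts read 5' ends per position of one reference strand. Under
#' `all_placements` weighting each placement of a read's equivalence group
#' contributes the read's full count (the display convention for repeat
#' regions, where an ambiguous read is shown at either copy); under
#' `canonical_only` each read contributes once, at its canonical placement,
#' so species totals are not double-counted.
#'
#' @param assignment An `srna_assignment`.
#' @param ref_id Reference to pile on.
#' @param strand `"+"` or `"-"`.
#' @param weighting `"all_placements"` or `"canonical_only"`.
#' @return An `srna_track`: tibble of `pos` (1-based) and `count` for
#'   positions with nonzero counts, with the reference id/length, strand
#'   and weighting stored as attributes.
#' @export
pileup_five_prime <- function(assignment, ref_id,
                              strand = c("+", "-"),
                              weighting = c("all_placements",
                                            "canonical_only")) {
  strand <- match.arg(strand)
  weighting <- match.arg(weighting)
  refs <- assignment$references
  if (!ref_id %in% refs$id) stop("unknown reference: ", ref_id,
                                 call. = FALSE)
  if (weighting == "all_placements") {
    pl <- dplyr::filter(assignment$placements, .data$ref_id == !!ref_id,
                        .data$strand == !!strand)
    counts <- pl |>
      dplyr::group_by(pos = .data$five_prime) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  } else {
    r <- dplyr::filter(assignment$records,
                       .data$canonical_ref == !!ref_id,
                       .data$canonical_strand == !!strand)
    counts <- r |>
      dplyr::group_by(pos = .data$canonical_five_prime) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }
  counts <- dplyr::arrange(counts, .data$pos)
  structure(counts,
            class = c("srna_track", class(tibble::tibble())),
            ref_id = ref_id, strand = strand, weighting = weighting,
            ref_length = refs$length[refs$id == ref_id][[1]])
}

#' Bin a pileup track into fixed-width intervals
#'
#' Closed intervals `[1..w]`, `[w+1..2w]`, ... as used for genome-wide
#' display tracks (widths of 10 or 100 nt are typical); binning is
#' sum-preserving, and width 1 is the identity.
#'
#' @param track An `srna_track`.
#' @param width Bin width in nt (>= 1).
#' @return An `srna_binned` tibble of `bin_start` and `count` (nonzero
#'   bins), inheriting the track attributes plus `width`.
#' @export
bin_track <- function(track, width) {
  stopifnot(width >= 1)
  binned <- track |>
    tibble::as_tibble() |>
    dplyr::group_by(bin_start = ((.data$pos - 1L) %/% as.integer(width)) *
                      as.integer(width) + 1L) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$bin_start)
  structure(binned,
            class = c("srna_binned", class(tibble::tibble())),
            ref_id = attr(track, "ref_id"), strand = attr(track, "strand"),
            weighting = attr(track, "weighting"),
            ref_length = attr(track, "ref_length"),
            width = as.integer(width))
}

#' Call 5'-end hotspots above a read-count threshold
#'
#' Every position whose 5'-end count strictly exceeds the effective
#' threshold becomes a hotspot, named `sR-<5' start>` after its plus-strand
#' 5' coordinate. In `absolute` mode the threshold is taken as given (the
#' study convention: 3,000 reads, roughly 100-fold above background); in
#' `relative` mode it is `relative_factor` times the background estimate,
#' the median count over nonzero positions. A position at exactly the
#' threshold is not a hotspot.
#'
#' @param track An `srna_track`.
#' @param threshold Absolute read-count threshold.
#' @param mode `"absolute"` or `"relative"`.
#' @param relative_factor Fold over background used in relative mode.
#' @return An `srna_hotspots` tibble (`name`, `ref_id`, `strand`,
#'   `five_prime`, `count`), sorted by count descending (position ascending
#'   on ties), with the effective threshold and background estimate as
#'   attributes.
#' @export
call_hotspots <- function(track, threshold = 3000,
                          mode = c("absolute", "relative"),
                          relative_factor = 100) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, relative_factor > 0)
  background <- if (nrow(track) > 0)
    stats::median(track$count[track$count > 0]) else NA_real_
  eff <- if (mode == "absolute") threshold else relative_factor * background
  hot <- track |>
    tibble::as_tibble() |>
    dplyr::filter(.data$count > eff) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$pos) |>
    dplyr::transmute(name = paste0("sR-", .data$pos),
                     ref_id = attr(track, "ref_id"),
                     strand = attr(track, "strand"),
                     five_prime = .data$pos, count = .data$count)
  structure(hot,
            class = c("srna_hotspots", class(tibble::tibble())),
            threshold = eff, mode = mode, background = background,
            weighting = attr(track, "weighting"))
}

#' @export
glance.srna_hotspots <- function(x, ...) {
  tibble::tibble(n_hotspots = nrow(x),
                 threshold = attr(x, "threshold"),
                 mode = attr(x, "mode"),
                 background = attr(x, "background"),
                 total_count = sum(x$count))
}

#' @export
tidy.srna_hotspots <- function(x, ...) tibble::as_tibble(x)

supporting_records <- function(assignment, ref_id, strand, five_prime) {
  pl <- assignment$placements
  hit <- pl$ref_id == ref_id & pl$strand == strand &
    pl$five_prime == five_prime
  unique(pl$sequence[hit])
}

#' Read-length statistics of called hotspots
#'
#' For each hotspot, the supporting reads are those with a placement at the
#' hotspot's 5' position; their length distribution (weighted by read
#' multiplicity) is summarised as a histogram plus mean (one decimal),
#' median and mode.
#'
#' @param assignment The `srna_assignment` the hotspots were piled from.
#' @param hotspots An `srna_hotspots` tibble (or any tibble with `ref_id`,
#'   `strand`, `five_prime`).
#' @return The hotspots with `length_histogram` (list column of
#'   length/count tibbles), `mean_length`, `median_length` and
#'   `mode_length` added.
#' @export
hotspot_length_stats <- function(assignment, hotspots) {
  stats_one <- function(ref_id, strand, five_prime) {
    seqs <- supporting_records(assignment, ref_id, strand, five_prime)
    rec <- assignment$records[assignment$records$sequence %in% seqs, ]
    len <- nchar(rec$sequence)
    cnt <- rec$count
    h <- dplyr::arrange(dplyr::summarise(
      dplyr::group_by(tibble::tibble(length = len, count = cnt),
                      .data$length),
      count = sum(.data$count), .groups = "drop"), .data$length)
    expanded_median <- weighted_median(h$length, h$count)
    tibble::tibble(
      length_histogram = list(h),
      mean_length = round(sum(h$length * h$count) / sum(h$count), 1),
      median_length = expanded_median,
      mode_length = h$length[which.max(h$count)])
  }
  out <- purrr::pmap(
    list(hotspots$ref_id, hotspots$strand, hotspots$five_prime),
    stats_one)
  dplyr::bind_cols(tibble::as_tibble(hotspots), dplyr::bind_rows(out))
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  lo <- x[which(cw >= 0.5)[1]]
  hi <- x[which(cw > 0.5)[1]]
  if (is.na(hi)) hi <- x[length(x)]
  (lo + hi) / 2
}

#' Link hotspots that share ambiguous reads
#'
#' Hotspots whose supporting read sets share equivalence groups (the same
#' read sequences placed at both positions, as happens across the two
#' copies and the internal palindrome of an inverted terminal repeat) are
#' linked into one group. Linked hotspots carry the same reads, so their
#' shared count is reported once in species totals (which always use
#' canonical weighting).
#'
#' @param hotspots An `srna_hotspots` tibble; hotspots may come from both
#'   strands of the same species (bind rows of the two strand calls).
#' @param assignment The `srna_assignment` behind the calls.
#' @return The hotspots with `equiv_group` (integer) and
#'   `equivalence_partners` (list column of the other hotspot names in the
#'   group) added.
#' @export
link_equivalent_hotspots <- function(hotspots, assignment) {
  n <- nrow(hotspots)
  supp <- purrr::pmap(
    list(hotspots$ref_id, hotspots$strand, hotspots$five_prime),
    function(r, s, f) supporting_records(assignment, r, s, f))
  # union-find over hotspots sharing any supporting sequence
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (length(intersect(supp[[i]], supp[[j]])) > 0) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  group <- match(root, unique(root))
  partners <- lapply(seq_len(n), function(i) {
    setdiff(hotspots$name[group == group[i]], hotspots$name[i])
  })
  out <- dplyr::mutate(tibble::as_tibble(hotspots), equiv_group = group,
                       equivalence_partners = partners)
  structure(out, class = class(hotspots),
            threshold = attr(hotspots, "threshold"),
            mode = attr(hotspots, "mode"),
            background = attr(hotspots, "background"),
            weighting = attr(hotspots, "weighting"))
}

#' Rank the top candidate 5' positions of a species
#'
#' The top-N table of hotspot candidates over both strands of a reference:
#' position, strand, supporting count, median read length and the most
#' abundant supporting sequence, ranked by count descending with ties
#' broken by position ascending (`+` before `-`).
#'
#' @param assignment An `srna_assignment`.
#' @param ref_id Reference id.
#' @param n Number of rows to keep.
#' @param weighting Pileup weighting (see [pileup_five_prime()]).
#' @return Tibble with `rank`, `name`, `strand`, `five_prime`, `count`,
#'   `median_length`, `sequence`.
#' @export
top_hotspot_table <- function(assignment, ref_id, n = 100,
                              weighting = "all_placements") {
  both <- dplyr::bind_rows(lapply(c("+", "-"), function(s) {
    tr <- pileup_five_prime(assignment, ref_id, s, weighting)
    dplyr::mutate(tibble::as_tibble(tr), strand = s)
  }))
  both <- both |>
    dplyr::arrange(dplyr::desc(.data$count), .data$pos, .data$strand) |>
    head(n)
  if (nrow(both) == 0) {
    return(tibble::tibble(rank = integer(), name = character(),
                          strand = character(), five_prime = integer(),
                          count = integer(), median_length = double(),
                          sequence = character()))
  }
  extras <- purrr::pmap(list(both$strand, both$pos), function(s, p) {
    seqs <- supporting_records(assignment, ref_id, s, p)
    rec <- assignment$records[assignment$records$sequence %in% seqs, ]
    rec <- rec[order(-rec$count, rec$sequence), ]
    tibble::tibble(
      median_length = weighted_median(nchar(rec$sequence), rec$count),
      sequence = rec$sequence[1])
  })
  dplyr::bind_cols(
    tibble::tibble(rank = seq_len(nrow(both)),
                   name = paste0("sR-", both$pos), strand = both$strand,
                   five_prime = both$pos, count = both$count),
    dplyr::bind_rows(extras))
}
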