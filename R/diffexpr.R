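#' Build a per-miRNA read count table from assignments
#'
#' Counts the human-miRNA reads of each sample by the pre-miRNA reference
#' of their canonical pre-miRNA placement. Library sizes (the per-sample
#' length-filtered read totals, the denominator used for depth
#' normalisation) are stored in the `lib_sizes` attribute.
#'
#' @param assignments Named list of `srna_assignment` objects, one per
#'   sample.
#' @param mirna_ids Character vector fixing the catalog (rows); miRNAs with
#'   no reads get zero counts.
#' @return Tibble with `mirna` plus one integer column per sample.
#' @export
mirna_count_table <- function(assignments, mirna_ids) {
  stopifnot(length(names(assignments)) == length(assignments))
  out <- tibble::tibble(mirna = mirna_ids)
  libs <- numeric(0)
  for (nm in names(assignments)) {
    a <- assignments[[nm]]
    pre_ids <- a$references$id[a$references$role == "pre_mirna"]
    r <- a$records[a$records$human_mirna, ]
    pl <- a$placements[a$placements$sequence %in% r$sequence &
                         a$placements$ref_id %in% pre_ids, ]
    can <- pl |>
      dplyr::group_by(.data$sequence) |>
      dplyr::arrange(match(.data$ref_id, pre_ids), .data$five_prime,
                     .data$strand, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup()
    counts <- can |>
      dplyr::group_by(.data$ref_id) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    out[[nm]] <- counts$count[match(mirna_ids, counts$ref_id)]
    out[[nm]][is.na(out[[nm]])] <- 0L
    libs[nm] <- sum(a$records$count)
  }
  attr(out, "lib_sizes") <- libs
  out
}

#' Depth-normalise a miRNA count table
#'
#' `cpm` scales each sample column to counts per million length-filtered
#' reads; `raw` is the identity (mirroring analyses that plot raw read
#' counts). Scaling every count and library size by a common factor leaves
#' cpm values unchanged.
#'
#' @param table Count tibble (`mirna` + one column per sample).
#' @param method `"cpm"` or `"raw"`.
#' @param lib_sizes Named numeric of per-sample library sizes; defaults to
#'   the table's `lib_sizes` attribute.
#' @return Tibble of the same shape with normalised values.
#' @export
normalize_counts <- function(table, method = c("cpm", "raw"),
                             lib_sizes = NULL) {
  method <- match.arg(method)
  if (method == "raw") return(table)
  if (is.null(lib_sizes)) lib_sizes <- attr(table, "lib_sizes")
  samples <- setdiff(names(table), "mirna")
  if (is.null(lib_sizes) || !all(samples %in% names(lib_sizes))) {
    stop("lib_sizes required for cpm normalisation", call. = FALSE)
  }
  if (any(lib_sizes[samples] <= 0)) stop("zero library size",
                                         call. = FALSE)
  for (s in samples) table[[s]] <- table[[s]] * 1e6 / lib_sizes[[s]]
  table
}

#' Fold changes between two samples with a representativeness floor
#'
#' For each miRNA the fold change is
#' `(norm_b + pseudocount) / (norm_a + pseudocount)`. A miRNA whose raw
#' counts fall below the floor in both samples (optionally: in either) is
#' classed `not_representative` regardless of its fold change; the
#' remainder are banded by `max(fc, 1/fc)` against the two band limits
#' (defaults 2 and 5): `within_2fold`, `band_2_to_5` (limit-inclusive),
#' or `beyond_5fold`, with direction `up`/`down` by the sign of `fc - 1`.
#' Swapping the samples inverts fold changes and directions but leaves the
#' band classes unchanged.
#'
#' @param table Count tibble ([mirna_count_table()] or compatible).
#' @param sample_a,sample_b Column names; fold change is b over a.
#' @param floor Raw read-count representativeness floor (default 100).
#' @param bands Increasing pair of fold-change band limits.
#' @param pseudocount Added to both normalised values (handles zeros).
#' @param normalization `"cpm"` or `"raw"`.
#' @param lib_sizes Passed to [normalize_counts()] for cpm.
#' @param floor_rule `"both"` (default: not representative only when both
#'   samples are below the floor) or `"either"`.
#' @return An `srna_fold_change` tibble: `mirna`, `count_a`, `count_b`,
#'   `norm_a`, `norm_b`, `fold_change`, `max_fold`, `class`, `direction`.
#' @export
compute_fold_changes <- function(table, sample_a, sample_b, floor = 100,
                                 bands = c(2, 5), pseudocount = 0.5,
                                 normalization = c("cpm", "raw"),
                                 lib_sizes = NULL,
                                 floor_rule = c("both", "either")) {
  normalization <- match.arg(normalization)
  floor_rule <- match.arg(floor_rule)
  stopifnot(floor >= 0, length(bands) == 2, bands[1] < bands[2])
  norm <- normalize_counts(table, normalization, lib_sizes)
  a <- table[[sample_a]]; b <- table[[sample_b]]
  na <- norm[[sample_a]]; nb <- norm[[sample_b]]
  fc <- (nb + pseudocount) / (na + pseudocount)
  mf <- pmax(fc, 1 / fc)
  low <- if (floor_rule == "both") a < floor & b < floor else
    a < floor | b < floor
  cls <- dplyr::case_when(
    low ~ "not_representative",
    mf < bands[1] ~ "within_2fold",
    mf <= bands[2] ~ "band_2_to_5",
    TRUE ~ "beyond_5fold")
  dir <- dplyr::case_when(fc > 1 ~ "up", fc < 1 ~ "down", TRUE ~ "none")
  out <- tibble::tibble(
    mirna = table$mirna, count_a = a, count_b = b, norm_a = na,
    norm_b = nb, fold_change = fc, max_fold = mf, class = cls,
    direction = dir)
  structure(out, class = c("srna_fold_change", class(tibble::tibble())),
            floor = floor, bands = bands, pseudocount = pseudocount,
            normalization = normalization,
            samples = c(a = sample_a, b = sample_b))
}

#' @export
tidy.srna_fold_change <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.srna_fold_change <- function(x, ...) {
  tibble::tibble(
    n_mirna = nrow(x),
    not_representative = sum(x$class == "not_representative"),
    within_2fold = sum(x$class == "within_2fold"),
    band_2_to_5 = sum(x$class == "band_2_to_5"),
    beyond_5fold = sum(x$class == "beyond_5fold"),
    floor = attr(x, "floor"))
}

#' Plot-ready scatter table of a fold-change analysis
#'
#' Per miRNA: log10 of the pseudocounted normalised values for both
#' samples, the band class, and a highlight flag for the beyond-5-fold
#' regulated miRNAs.
#'
#' @param records An `srna_fold_change` tibble.
#' @return Tibble with `mirna`, `log10_a`, `log10_b`, `class`,
#'   `highlight`; one row per catalog miRNA.
#' @export
scatter_table <- function(records) {
  pc <- attr(records, "pseudocount")
  tibble::tibble(
    mirna = records$mirna,
    log10_a = log10(records$norm_a + pc),
    log10_b = log10(records$norm_b + pc),
    class = records$class,
    highlight = records$class == "beyond_5fold")
}
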