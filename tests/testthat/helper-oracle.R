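# Independent brute-force oracles used to cross-check the package's
# alignment and trimming code paths. Deliberately naive: per-position
# Hamming comparison over sliding windows, no index, no early exit.

N_INT <- utf8ToInt("N")

# all full-length ungapped placements of each sequence on both strands of
# every reference, Hamming distance <= max_mm, N never matches
oracle_placements <- function(sequences, references, max_mm) {
  one_strand <- function(q, ref_int, L) {
    M <- length(ref_int)
    if (L > M) return(integer(0))
    win <- embed(ref_int, L)[, L:1, drop = FALSE]
    qmat <- matrix(q, nrow(win), L, byrow = TRUE)
    mm <- rowSums(win != qmat | win == N_INT | qmat == N_INT)
    mm
  }
  rows <- list()
  for (s in sequences) {
    L <- nchar(s)
    qf <- utf8ToInt(s)
    qr <- utf8ToInt(srnaspot::reverse_complement(s))
    for (ri in seq_len(nrow(references))) {
      ref_int <- utf8ToInt(references$sequence[ri])
      mmf <- one_strand(qf, ref_int, L)
      mmr <- one_strand(qr, ref_int, L)
      for (st in seq_along(mmf)) {
        if (mmf[st] <= max_mm) {
          rows[[length(rows) + 1]] <- data.frame(
            sequence = s, ref_id = references$id[ri], strand = "+",
            start = st, end = st + L - 1L, mismatches = mmf[st],
            five_prime = st)
        }
        if (mmr[st] <= max_mm) {
          rows[[length(rows) + 1]] <- data.frame(
            sequence = s, ref_id = references$id[ri], strand = "-",
            start = st, end = st + L - 1L, mismatches = mmr[st],
            five_prime = st + L - 1L)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(sequence = character(), ref_id = character(),
                          strand = character(), start = integer(),
                          end = integer(), mismatches = integer(),
                          five_prime = integer()))
  }
  out <- dplyr::bind_rows(rows)
  # same deterministic order as the package: read input order, then
  # reference order, start, '+' before '-'
  out <- out[order(match(out$sequence, unique(sequences)),
                   match(out$ref_id, references$id), out$start,
                   out$strand), ]
  tibble::as_tibble(out, .name_repair = "minimal")
}

# sliding-window adapter trim oracle
oracle_trim <- function(read, adapter, min_overlap, max_mm) {
  L <- nchar(read)
  for (p in seq_len(L)) {
    overlap <- min(nchar(adapter), L - p + 1L)
    if (overlap < min_overlap) break
    a <- utf8ToInt(substr(read, p, p + overlap - 1L))
    b <- utf8ToInt(substr(adapter, 1L, overlap))
    mm <- sum(a != b | a == N_INT | b == N_INT)
    if (mm <= max_mm) return(substr(read, 1L, p - 1L))
  }
  read
}

mutate_bases <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(s), n_sub)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste0(s, collapse = "")
}

random_seq <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# bare pileup track constructor for unit tests that bypass assignment
make_track <- function(pos, count, ref_id = "ref", strand = "+",
                       ref_length = max(pos, 0) + 100L,
                       weighting = "all_placements") {
  structure(tibble::tibble(pos = as.integer(pos),
                           count = as.integer(count)),
            class = c("srna_track", class(tibble::tibble())),
            ref_id = ref_id, strand = strand, weighting = weighting,
            ref_length = as.integer(ref_length))
}
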