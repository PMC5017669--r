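#' @noRd
random_dna <- function(n, len) {
  # len may be scalar or vector; returns n sequences
  len <- rep_len(len, n)
  if (n == 0) return(character())
  chars <- sample(c("A", "C", "G", "T"), sum(len), replace = TRUE)
  idx <- rep.int(seq_len(n), len)
  vapply(split(chars, idx), paste0, character(1), collapse = "",
         USE.NAMES = FALSE)
}

#' Illumina TruSeq small RNA 3' adapter
#'
#' The 3' sequencing adapter ligated to small RNAs before reverse
#' transcription; the simulator appends it to every insert and the
#' preprocessing stage removes it again.
#' @export
TRUSEQ_3P_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

#' Generate a synthetic host reference with hairpin pre-miRNAs
#'
#' Builds a host reference emulating the mapping targets of a small RNA-Seq
#' cascade: random decoy "genome" sequences plus hairpin pre-miRNAs, each
#' constructed as mature arm + loop + reverse complement of the arm so that
#' the mature arm occurs as an exact substring at position 1 and its reverse
#' complement sits in the 3' half of the hairpin. A catalog of mature arms
#' with a fixed long-tailed (log-normal) expression weight per miRNA is
#' returned alongside; the weights are a property of the host object so that
#' independently simulated samples share one miRNA expression profile.
#'
#' @param n_decoys Number of random decoy genome sequences.
#' @param decoy_len Length of each decoy (nt).
#' @param n_premirnas Number of hairpin pre-miRNAs (the study catalog holds
#'   979 annotated miRNAs, the default).
#' @param arm_len Mature arm length (nt), typical mature miRNA size.
#' @param loop_len Hairpin loop length (nt).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list with `references` (reference tibble: decoys with role
#'   `genome`, hairpins with role `pre_mirna`, all species `host`) and
#'   `mature` (tibble: `mirna`, `arm_seq`, `arm_start`, `weight`).
#' @export
make_host_reference <- function(n_decoys = 3, decoy_len = 10000,
                                n_premirnas = 979, arm_len = 22,
                                loop_len = 15, seed = 1) {
  stopifnot(n_decoys > 0, decoy_len > 0, n_premirnas > 0, arm_len >= 16)
  withr::with_seed(seed, {
    decoys <- reference_set(
      sprintf("decoy_%d", seq_len(n_decoys)),
      random_dna(n_decoys, decoy_len),
      species = "host", role = "genome")
    arms <- random_dna(n_premirnas, arm_len)
    loops <- random_dna(n_premirnas, loop_len)
    hairpins <- paste0(arms, loops, reverse_complement(arms))
    pre <- reference_set(
      sprintf("mir-%04d", seq_len(n_premirnas)), hairpins,
      species = "host", role = "pre_mirna")
    weight <- rlnorm(n_premirnas, meanlog = 0, sdlog = 2)
    mature <- tibble::tibble(
      mirna = pre$id, arm_seq = arms, arm_start = 1L,
      weight = weight / sum(weight))
  })
  list(references = dplyr::bind_rows(decoys, pre), mature = mature)
}

#' Generate a synthetic viral genome flanked by inverted terminal repeats
#'
#' Emulates the architecture of a parvovirus (AAV-like) genome: a left ITR
#' built as `P + reverse_complement(P) + D` (an internal palindrome of
#' `2 * arm_len` nt followed by a unique segment `D`), a random core, and a
#' right ITR that is the reverse complement of the left ITR. By
#' construction, a read whose 5' end is plus-strand position 1 inside the
#' palindromic arm also has an equivalent minus-strand placement with 5' end
#' at position `2 * arm_len` inside the same ITR (the sR-1 / sR-125
#' phenomenon at the terminal resolution site of real AAV ITRs), and every
#' read inside either ITR has a mirrored placement in the other ITR.
#'
#' @param core_len Length of the unique core (nt). The default gives a
#'   genome of 4,681 nt, the ~4.7-kb scale of an AAV genome.
#' @param itr_len Total ITR length (nt); AAV2's ITRs are 145 nt.
#' @param arm_len Palindromic arm length (nt); must satisfy
#'   `itr_len >= 2 * arm_len`.
#' @param seed Integer seed.
#' @param id,species Labels for the genome.
#' @return A list with `reference` (one-row reference tibble), `repeats`
#'   (the [annotate_terminal_repeats()] annotation of the construct) and
#'   `arm_len`/`itr_len` echoed for downstream tests.
#' @export
make_itr_genome <- function(core_len = 4391, itr_len = 145, arm_len = 62,
                            seed = 1, id = "AAV", species = "AAV2") {
  stopifnot(itr_len >= 2 * arm_len, core_len > 0, arm_len >= 10)
  withr::with_seed(seed, {
    p <- random_dna(1, arm_len)
    d <- if (itr_len > 2 * arm_len) random_dna(1, itr_len - 2 * arm_len)
         else ""
    left <- paste0(p, reverse_complement(p), d)
    right <- reverse_complement(left)
    core <- random_dna(1, core_len)
    # keep the terminal relation from extending past the ITR by chance
    while (substr(core, 1, 1) ==
           reverse_complement(substr(core, core_len, core_len))) {
      core <- paste0(random_dna(1, 1), substr(core, 2, core_len))
    }
    genome <- paste0(left, core, right)
  })
  ref <- reference_set(id, genome, species = species, role = "genome")
  list(reference = ref,
       repeats = annotate_terminal_repeats(ref, min_len = min(50, itr_len)),
       arm_len = arm_len, itr_len = itr_len)
}

#' Specify planted viral 5'-end hotspots
#'
#' A hotspot spec fixes where simulated viral reads start (a 1-based
#' plus-strand 5'-end coordinate), how long they are (a probability weight
#' per read length), and how abundant they are (expected read count used as
#' the relative weight among a sample's viral reads).
#'
#' @param ref_id Viral reference id the hotspot lies on.
#' @param strand `"+"` or `"-"`; on the minus strand the 5' end is the
#'   largest plus-strand coordinate of the read.
#' @param five_prime_start 1-based plus-strand 5'-end coordinate.
#' @param length_weights Named numeric vector, names = read lengths (nt, all
#'   >= 16), values summing to 1.
#' @param abundance Expected read count.
#' @return One-row tibble (`length_weights` is a list column); rows from
#'   several calls can be bound with `dplyr::bind_rows()`.
#' @export
hotspot_spec <- function(ref_id, strand, five_prime_start, length_weights,
                         abundance) {
  stopifnot(strand %in% c("+", "-"), five_prime_start >= 1, abundance > 0)
  lens <- as.integer(names(length_weights))
  if (any(is.na(lens)) || any(lens < 16)) {
    stop("length_weights must be named by read lengths >= 16", call. = FALSE)
  }
  if (abs(sum(length_weights) - 1) > 1e-9) {
    stop("length_weights must sum to 1", call. = FALSE)
  }
  tibble::tibble(ref_id = ref_id, strand = strand,
                 five_prime_start = as.integer(five_prime_start),
                 length_weights = list(length_weights),
                 abundance = abundance)
}

#' Default AAV-like hotspot specs
#'
#' Three planted hotspots mirroring the flagship viral small RNAs of the
#' modelled study: an ITR hotspot at position 108 on the plus strand (mode
#' length 21 nt, ~12,000 reads), an anti-p5-like hotspot at position 271 on
#' the minus strand (lengths 16-23 nt, ~12,700 reads), and a p40-proximal
#' hotspot at position 1862 on the plus strand (18-19 nt, ~3,800 reads).
#'
#' @param ref_id Viral reference id.
#' @param abundances Expected read counts for the three hotspots.
#' @return Hotspot spec tibble with three rows.
#' @export
aav_hotspot_specs <- function(ref_id = "AAV",
                              abundances = c(12002, 12737, 3780)) {
  dplyr::bind_rows(
    hotspot_spec(ref_id, "+", 108,
                 c("19" = .10, "20" = .15, "21" = .50, "22" = .15,
                   "23" = .10), abundances[1]),
    hotspot_spec(ref_id, "-", 271,
                 setNames(rep(1 / 8, 8), 16:23), abundances[2]),
    hotspot_spec(ref_id, "+", 1862, c("18" = .5, "19" = .5), abundances[3])
  )
}

#' Describe one sequencing sample to simulate
#'
#' @param name Sample name.
#' @param total_reads Number of machine reads to emit.
#' @param fractions Named numeric vector summing to 1 over source
#'   categories: `host_mirna`, `host_other`, `junk`, and `virus:<species>`
#'   entries (one per infecting virus).
#' @param error_rate Per-base substitution probability applied to the
#'   pre-adapter insert+adapter sequence.
#' @param adapter 3' adapter appended to every insert.
#' @param read_length Fixed machine read length (nt); inserts shorter than
#'   this read through into the adapter, longer pre-reads are truncated.
#' @param seed Integer seed for this sample.
#' @param mirna_scale Optional named numeric vector of per-miRNA abundance
#'   multipliers (e.g. a planted 5-fold depletion for differential
#'   expression tests).
#' @return One-row design tibble (list columns for `fractions` and
#'   `mirna_scale`).
#' @export
sample_design <- function(name, total_reads, fractions, error_rate = 0.002,
                          adapter = TRUSEQ_3P_ADAPTER, read_length = 51,
                          seed = 1, mirna_scale = NULL) {
  stopifnot(total_reads > 0, error_rate >= 0, error_rate < 1)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  known <- names(fractions) %in% c("host_mirna", "host_other", "junk") |
    startsWith(names(fractions), "virus:")
  if (!all(known)) {
    stop("unknown fraction source(s): ",
         paste(names(fractions)[!known], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(name = name, total_reads = as.integer(total_reads),
                 fractions = list(fractions), error_rate = error_rate,
                 adapter = adapter, read_length = as.integer(read_length),
                 seed = as.integer(seed), mirna_scale = list(mirna_scale))
}

#' The eight-sample infection study design
#'
#' Mock / virus / virus+helper / helper at an early (8 hpi) and a late
#' (27 hpi) timepoint, with composition fractions chosen at the magnitudes
#' of the modelled study's read accounting: most reads are host (with a
#' 17-47% miRNA share), viral reads are rare without helper (~1e-5 of
#' total), rise ~200-fold with helper co-infection (0.7-1.4% of reads), and
#' a junk fraction supplies both the <16-nt discard and the unmappable
#' "unknown" classes.
#'
#' @param total_reads Reads per sample. The default (200,000) is a
#'   desk-scale stand-in for the study's 18-25 million reads per library.
#' @param seed Base seed; sample i uses `seed * 100 + i`.
#' @param virus,helper Species names used in `virus:<species>` fraction keys.
#' @return Design tibble with eight rows (see [sample_design()]).
#' @export
aav_study_design <- function(total_reads = 200000, seed = 20, virus = "AAV2",
                             helper = "HV") {
  v <- function(x) setNames(x, paste0("virus:", c(virus, helper)))
  mk <- function(name, mirna, other, junk, aav = 0, hv = 0, i) {
    sample_design(name, total_reads,
                  c(host_mirna = mirna, host_other = other, junk = junk,
                    v(c(aav, hv)))[c(TRUE, TRUE, TRUE, aav > 0, hv > 0)],
                  seed = seed * 100 + i)
  }
  dplyr::bind_rows(
    mk("cells_8hpi",       .33, .505, .165, i = 1),
    mk("aav2_8hpi",        .37, .44999, .18, aav = .00001, i = 2),
    mk("aav2_helper_8hpi", .34, .478, .17, aav = .007, hv = .005, i = 3),
    mk("helper_8hpi",      .46, .36, .174, hv = .006, i = 4),
    mk("cells_27hpi",      .27, .55, .18, i = 5),
    mk("aav2_27hpi",       .36, .46, .17993, aav = .00007, i = 6),
    mk("aav2_helper_27hpi", .17, .45, .237, aav = .013, hv = .13, i = 7),
    mk("helper_27hpi",     .21, .32, .25, hv = .22, i = 8)
  )
}

extract_read <- function(genome, five_prime, strand, len) {
  # strand-aware insert extraction; 5' end expressed on the plus strand
  ifelse(strand == "+",
         substring(genome, five_prime, five_prime + len - 1L),
         reverse_complement(substring(genome, five_prime - len + 1L,
                                      five_prime)))
}

apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, error_rate)
  for (i in which(n_err > 0)) {
    s <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    }
    seqs[i] <- paste0(s, collapse = "")
  }
  seqs
}

#' Simulate one small RNA-Seq sample with ground truth
#'
#' Emits `total_reads` machine reads. Each read is drawn from its source
#' category (host miRNA mature arms with the host catalog's expression
#' weights, host fragment species from the decoy genomes, planted viral
#' hotspots plus a diffuse low-level viral background, or random junk),
#' per-base substitution errors are applied, the 3' adapter is appended, and
#' the result is padded/truncated to the fixed machine read length. Host
#' "other" reads are drawn from a finite catalog of fragment species with
#' log-normal abundances, emulating the recurrent degradation fragments that
#' dominate real small RNA libraries. The diffuse viral background places
#' ~`background_frac` of the hotspot read mass on a small set of preferred
#' background sites, so planted hotspots stand roughly two orders of
#' magnitude above a measurable per-site background level.
#'
#' @param design One-row design tibble from [sample_design()].
#' @param host Host object from [make_host_reference()].
#' @param viral_genomes Reference tibble of viral genomes (one or more
#'   species).
#' @param hotspot_specs Hotspot spec tibble ([hotspot_spec()]); specs are
#'   matched to viral genomes by `ref_id`.
#' @param n_fragment_species Size of the host fragment-species catalog.
#' @param background_frac Diffuse viral background mass relative to the
#'   summed hotspot abundance of the species.
#' @param background_sites Number of preferred viral background sites.
#' @return A list with `reads` (tibble: `read_id`, `sequence`) and `truth`
#'   (tibble: `read_id`, `source`, `ref_id`, `strand`, `five_prime`,
#'   `length` — one row per emitted read). Byte-identical given the same
#'   design (including its seed).
#' @export
simulate_sample <- function(design, host, viral_genomes = NULL,
                            hotspot_specs = NULL, n_fragment_species = 2000,
                            background_frac = 0.01, background_sites = 10) {
  stopifnot(is.data.frame(design), nrow(design) == 1)
  fr <- design$fractions[[1]]
  n <- design$total_reads[[1]]
  adapter <- design$adapter[[1]]
  rl <- design$read_length[[1]]

  withr::with_seed(design$seed[[1]], {
    n_per <- as.vector(rmultinom(1, n, fr))
    names(n_per) <- names(fr)
    parts <- list()

    for (src in names(fr)) {
      k <- n_per[[src]]
      if (k == 0) next
      if (src == "host_mirna") {
        w <- host$mature$weight
        ms <- design$mirna_scale[[1]]
        if (!is.null(ms)) {
          idx <- match(names(ms), host$mature$mirna)
          w[idx] <- w[idx] * ms
        }
        pick <- sample.int(nrow(host$mature), k, replace = TRUE,
                           prob = w)
        parts[[src]] <- tibble::tibble(
          source = src, ref_id = host$mature$mirna[pick], strand = "+",
          five_prime = host$mature$arm_start[pick],
          insert = host$mature$arm_seq[pick])
      } else if (src == "host_other") {
        decoys <- dplyr::filter(host$references, .data$role == "genome")
        frag_ref <- sample.int(nrow(decoys), n_fragment_species,
                               replace = TRUE)
        frag_len <- sample(18:32, n_fragment_species, replace = TRUE)
        frag_start <- vapply(seq_len(n_fragment_species), function(i) {
          sample.int(decoys$length[frag_ref[i]] - frag_len[i] + 1L, 1)
        }, integer(1))
        frag_w <- rlnorm(n_fragment_species, 0, 2)
        pick <- sample.int(n_fragment_species, k, replace = TRUE,
                           prob = frag_w)
        parts[[src]] <- tibble::tibble(
          source = src, ref_id = decoys$id[frag_ref[pick]], strand = "+",
          five_prime = frag_start[pick],
          insert = extract_read(decoys$sequence[frag_ref[pick]],
                                frag_start[pick], "+", frag_len[pick]))
      } else if (src == "junk") {
        jl <- sample(10:30, k, replace = TRUE)
        parts[[src]] <- tibble::tibble(
          source = src, ref_id = NA_character_, strand = NA_character_,
          five_prime = NA_integer_, insert = random_dna(k, jl))
      } else { # virus:<species>
        sp <- sub("^virus:", "", src)
        genome <- dplyr::filter(viral_genomes, .data$species == sp)
        if (nrow(genome) == 0) stop("no viral genome for species ", sp,
                                    call. = FALSE)
        specs <- if (is.null(hotspot_specs)) hotspot_specs else
          dplyr::filter(hotspot_specs, .data$ref_id %in% genome$id)
        parts[[src]] <- simulate_viral_reads(
          k, sp, genome, specs, background_frac, background_sites)
      }
    }

    truth <- dplyr::bind_rows(parts)
    truth$length <- nchar(truth$insert)
    truth$read_id <- sprintf("%s_%07d", design$name[[1]],
                             seq_len(nrow(truth)))
    pre <- apply_substitutions(paste0(truth$insert, adapter),
                               design$error_rate[[1]])
    machine <- substr(paste0(pre, strrep("A", rl)), 1L, rl)
    reads <- tibble::tibble(read_id = truth$read_id, sequence = machine)
  })
  list(reads = reads,
       truth = truth[, c("read_id", "source", "ref_id", "strand",
                         "five_prime", "length")])
}

simulate_viral_reads <- function(k, sp, genome, specs, background_frac,
                                 background_sites) {
  src <- paste0("virus:", sp)
  if (is.null(specs) || nrow(specs) == 0) {
    specs <- tibble::tibble(ref_id = character(), strand = character(),
                            five_prime_start = integer(),
                            length_weights = list(), abundance = numeric())
    hot_mass <- 0
    weights <- numeric()
  } else {
    hot_mass <- sum(specs$abundance)
    weights <- specs$abundance
  }
  glen <- genome$length[[1]]
  gseq <- genome$sequence[[1]]
  gid <- genome$id[[1]]
  # preferred background sites: uniform positions, either strand
  bg_strand <- sample(c("+", "-"), background_sites, replace = TRUE)
  bg_pos <- vapply(bg_strand, function(s) {
    if (s == "+") sample.int(glen - 30L, 1) else sample(31:glen, 1)
  }, integer(1))
  bg_mass <- if (hot_mass > 0) background_frac * hot_mass else 1
  w <- c(weights, rep(bg_mass / background_sites, background_sites))
  pick <- sample.int(length(w), k, replace = TRUE, prob = w)
  is_bg <- pick > nrow(specs)
  fp <- integer(k); strand <- character(k); len <- integer(k)
  if (any(!is_bg)) {
    sidx <- pick[!is_bg]
    fp[!is_bg] <- specs$five_prime_start[sidx]
    strand[!is_bg] <- specs$strand[sidx]
    len[!is_bg] <- vapply(sidx, function(i) {
      lw <- specs$length_weights[[i]]
      as.integer(sample(names(lw), 1, prob = lw))
    }, integer(1))
  }
  if (any(is_bg)) {
    bidx <- pick[is_bg] - nrow(specs)
    fp[is_bg] <- bg_pos[bidx]
    strand[is_bg] <- bg_strand[bidx]
    len[is_bg] <- sample(18:24, sum(is_bg), replace = TRUE)
  }
  tibble::tibble(source = src, ref_id = gid, strand = strand,
                 five_prime = fp,
                 insert = extract_read(gseq, fp, strand, len))
}

#' Write simulated reads to FASTQ
#'
#' Phred33 FASTQ with a constant quality string (`I`, Q40); the writer emits
#' byte-identical files for identical inputs.
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", strrep("I", nchar(reads$sequence))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ path (Phred33).
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                 sequence = unname(as.character(x)))
}

#' Simulate a pair of miRNA count libraries with planted regulation
#'
#' Draws a log-normal expression profile over a miRNA catalog and Poisson
#' read counts for two samples at the given depths; `scale_b` multiplies the
#' expectation of selected miRNAs in sample b (e.g. a planted 5.5-fold
#' depletion). Used to exercise the fold-change classifier against known
#' truth without running the full read pipeline.
#'
#' @param n_mirna Catalog size (study catalog: 979).
#' @param depth_a,depth_b Expected total miRNA reads per sample.
#' @param scale_b Named numeric vector of expectation multipliers applied to
#'   sample b (names may be any subset of `mir-0001`...).
#' @param planted_rank Optional abundance rank (1 = most abundant) at which
#'   `planted_scale` is applied to sample b; a rank well inside the catalog
#'   guarantees the planted miRNA sits in the representative count range.
#' @param planted_scale Multiplier used with `planted_rank`.
#' @param seed Integer seed.
#' @return Tibble `mirna`, `sample_a`, `sample_b` with attribute
#'   `lib_sizes` set to the realised column totals and `planted` naming the
#'   rank-planted miRNA (if any).
#' @export
simulate_mirna_counts <- function(n_mirna = 979, depth_a = 5e6,
                                  depth_b = 5e6, scale_b = NULL,
                                  planted_rank = NULL, planted_scale = 1,
                                  seed = 1) {
  planted <- NULL
  withr::with_seed(seed, {
    ids <- sprintf("mir-%04d", seq_len(n_mirna))
    w <- rlnorm(n_mirna, 0, 2)
    w <- w / sum(w)
    wb <- w
    if (!is.null(scale_b)) {
      idx <- match(names(scale_b), ids)
      wb[idx] <- wb[idx] * scale_b
    }
    if (!is.null(planted_rank)) {
      idx <- order(w, decreasing = TRUE)[planted_rank]
      wb[idx] <- wb[idx] * planted_scale
      planted <- ids[idx]
    }
    a <- rpois(n_mirna, w * depth_a)
    b <- rpois(n_mirna, wb * depth_b)
  })
  out <- tibble::tibble(mirna = ids, sample_a = a, sample_b = b)
  attr(out, "lib_sizes") <- c(sample_a = sum(a), sample_b = sum(b))
  attr(out, "planted") <- planted
  out
}
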