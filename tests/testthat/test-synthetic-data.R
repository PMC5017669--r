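test_that("host reference construction embeds mature arms in hairpins", {
  host <- make_host_reference(n_decoys = 2, decoy_len = 500,
                              n_premirnas = 5, seed = 42)
  pre <- dplyr::filter(host$references, role == "pre_mirna")
  expect_equal(nrow(pre), 5)
  for (i in 1:5) {
    hp <- pre$sequence[pre$id == host$mature$mirna[i]]
    arm <- host$mature$arm_seq[i]
    expect_equal(substr(hp, 1, nchar(arm)), arm)
    # the arm's reverse complement sits in the 3' half of the hairpin
    rc_pos <- regexpr(reverse_complement(arm), hp, fixed = TRUE)
    expect_gt(rc_pos, nchar(hp) / 2)
  }
  expect_equal(sum(host$mature$weight), 1)
  expect_identical(host, make_host_reference(n_decoys = 2, decoy_len = 500,
                                             n_premirnas = 5, seed = 42))
})

test_that("ITR genome construction produces the planned ambiguity", {
  itr <- make_itr_genome(core_len = 1000, itr_len = 145, arm_len = 20,
                         seed = 9)
  g <- itr$reference
  # a read taken from plus-strand position 1 has a minus-strand placement
  # with 5' end at 2*arm_len inside the same ITR (exhaustive oracle scan)
  rd <- substr(g$sequence, 1, 20)
  pl <- oracle_placements(rd, g, 0)
  minus_same_itr <- dplyr::filter(pl, strand == "-", five_prime == 40)
  expect_equal(nrow(minus_same_itr), 1)
  # and the package's aligner agrees placement-for-placement
  expect_equal(enumerate_placements(rd, g, 0), pl)
  # the construct's terminal relation is the inverted repeat
  expect_equal(itr$repeats$relation, "reverse_complement")
  expect_identical(g, make_itr_genome(core_len = 1000, itr_len = 145,
                                      arm_len = 20, seed = 9)$reference)
})

test_that("simulated samples honour composition, truth and determinism", {
  host <- make_host_reference(n_decoys = 2, decoy_len = 2000,
                              n_premirnas = 20, seed = 2)
  itr <- make_itr_genome(seed = 3)
  spec <- hotspot_spec("AAV", "+", 500, c("21" = 1), 5000)

  no_virus <- sample_design("nv", 2000,
                            c(host_mirna = .5, host_other = .3,
                              junk = .2), seed = 5)
  sim0 <- simulate_sample(no_virus, host, itr$reference, spec)
  expect_equal(nrow(sim0$reads), 2000)
  expect_equal(nrow(sim0$truth), 2000)
  expect_false(any(startsWith(sim0$truth$source, "virus")))

  des <- sample_design("v", 20000,
                       c(host_mirna = .4, host_other = .3, junk = .05,
                         `virus:AAV2` = .25), error_rate = 0, seed = 6)
  sim <- simulate_sample(des, host, itr$reference, spec)
  n_hot <- sum(sim$truth$five_prime == 500 & sim$truth$strand == "+" &
                 sim$truth$source == "virus:AAV2", na.rm = TRUE)
  # expected hotspot reads: viral fraction times hotspot share of mass
  expected <- 20000 * .25 * (5000 / (5000 * 1.01))
  expect_lt(abs(n_hot - expected), 4 * sqrt(expected))

  # machine reads are fixed length with adapter read-through
  expect_true(all(nchar(sim$reads$sequence) == 51))
  hot_reads <- sim$reads$sequence[sim$truth$source == "virus:AAV2" &
                                    sim$truth$five_prime == 500 &
                                    !is.na(sim$truth$five_prime)]
  ins <- substr(itr$reference$sequence, 500, 520)
  expect_true(all(startsWith(hot_reads, paste0(ins, substr(
    TRUSEQ_3P_ADAPTER, 1, 10)))))

  # identical seeds give byte-identical FASTQ
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(sim$reads, f1)
  write_fastq(simulate_sample(des, host, itr$reference, spec)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_fastq(f1)
  expect_equal(back, sim$reads)
})

test_that("the eight-sample study design is a valid composition", {
  des <- aav_study_design(total_reads = 1000)
  expect_equal(nrow(des), 8)
  for (i in 1:8) expect_equal(sum(des$fractions[[i]]), 1)
  expect_equal(des$name[c(1, 5)], c("cells_8hpi", "cells_27hpi"))
  helper_frac <- vapply(des$fractions, function(f)
    sum(f[startsWith(names(f), "virus:AAV2")]), numeric(1))
  # viral fraction rises by orders of magnitude with helper co-infection
  expect_gt(helper_frac[7] / helper_frac[6], 100)
})
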