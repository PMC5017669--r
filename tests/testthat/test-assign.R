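make_two_refs <- function(seed = 50) {
  set.seed(seed)
  reference_set(c("hostA", "vir"), c(random_seq(400), random_seq(400)),
                species = c("host", "V1"), role = "genome")
}

test_that("placement enumeration finds planted matches on both strands", {
  refs <- make_two_refs()
  rd_plus <- substr(refs$sequence[1], 10, 30)
  pl <- enumerate_placements(rd_plus, refs[1, ], 0)
  expect_equal(nrow(pl), 1)
  expect_equal(pl$strand, "+")
  expect_equal(pl$start, 10L)
  expect_equal(pl$mismatches, 0L)
  expect_equal(pl$five_prime, 10L)

  rd_minus <- reverse_complement(substr(refs$sequence[1], 50, 70))
  pm <- enumerate_placements(rd_minus, refs[1, ], 0)
  expect_equal(pm$strand, "-")
  expect_equal(pm$five_prime, 70L)
  expect_equal(pm$end - pm$start + 1L, nchar(rd_minus))
})

test_that("N never matches, in read or reference", {
  refs <- reference_set("r", "AAAACCCCGGGGTTTTAAAACCCC", "host", "genome")
  rd <- substr(refs$sequence, 3, 20)
  substr(rd, 5, 5) <- "N"
  expect_equal(nrow(enumerate_placements(rd, refs, 0)), 0)
  expect_equal(enumerate_placements(rd, refs, 1)$mismatches, 1L)
  refs_n <- reference_set("r", gsub("^(.{6}).", "\\1N",
                                    refs$sequence), "host", "genome")
  rd2 <- substr(refs$sequence, 3, 20)
  expect_equal(nrow(enumerate_placements(rd2, refs_n, 0)), 0)
})

test_that("indexed enumeration equals the naive Hamming scan", {
  set.seed(52)
  refs <- reference_set(paste0("r", 1:3),
                        replicate(3, random_seq(2000)),
                        species = "host", role = "genome")
  reads <- character(0)
  for (i in 1:140) {
    L <- sample(16:30, 1)
    ref_i <- sample(3, 1)
    s0 <- sample(2000 - L, 1)
    rd <- substr(refs$sequence[ref_i], s0, s0 + L - 1)
    rd <- mutate_bases(rd, sample(0:3, 1))
    if (runif(1) < 0.5) rd <- reverse_complement(rd)
    reads <- c(reads, rd)
  }
  reads <- c(reads, vapply(1:60, function(i) random_seq(sample(16:30, 1)),
                           character(1)))
  reads <- unique(reads)
  for (tier in 0:2) {
    expect_equal(enumerate_placements(reads, refs, tier),
                 oracle_placements(reads, refs, tier),
                 info = paste("tier", tier))
  }
})

test_that("host priority is absolute in the assignment cascade", {
  set.seed(53)
  shared <- random_seq(22)
  host_seq <- paste0(random_seq(100), shared, random_seq(100))
  vir_seq <- paste0(random_seq(50), shared, random_seq(50))
  vir_only <- substr(vir_seq, 10, 30)
  refs <- reference_set(c("h", "v"), c(host_seq, vir_seq),
                        species = c("host", "V1"),
                        role = "genome")
  collapsed <- tibble::tibble(
    sequence = c(shared, vir_only, random_seq(20)),
    count = c(5L, 3L, 2L))
  collapsed <- dplyr::arrange(collapsed, sequence)
  asn <- assign_reads(collapsed, refs, tiers = 0)
  r <- asn$records
  expect_equal(r$category[r$sequence == shared], "human")
  expect_equal(r$category[r$sequence == vir_only], "virus:V1")
  expect_equal(sum(r$category == "unknown"), 1)
  expect_equal(glance(asn)$viral, 3L)
})

test_that("graded tiers assign viral before mismatched host", {
  set.seed(54)
  # read A: exact on virus AND one mismatch from a host window
  a <- random_seq(22)
  host_seq <- paste0(random_seq(100), mutate_bases(a, 1), random_seq(100))
  vir_seq <- paste0(random_seq(50), a, random_seq(50))
  refs <- reference_set(c("h", "v"), c(host_seq, vir_seq),
                        species = c("host", "V1"), role = "genome")
  # read B: 1 mismatch from host, absent from virus
  b <- mutate_bases(substr(host_seq, 10, 31), 1)
  collapsed <- dplyr::arrange(
    tibble::tibble(sequence = c(a, b), count = c(1L, 1L)), sequence)
  asn <- assign_reads(collapsed, refs, tiers = c(0, 1))
  r <- asn$records
  expect_equal(r$category[r$sequence == a], "virus:V1")
  expect_equal(r$tier[r$sequence == a], 0L)
  expect_equal(r$category[r$sequence == b], "human")
  expect_equal(r$tier[r$sequence == b], 1L)
})

test_that("cross-species viral reads are flagged and double-counted", {
  set.seed(55)
  shared <- random_seq(20)
  refs <- reference_set(
    c("v1", "v2", "h"),
    c(paste0(random_seq(40), shared, random_seq(40)),
      paste0(random_seq(30), shared, random_seq(30)),
      random_seq(200)),
    species = c("V1", "V2", "host"), role = "genome")
  collapsed <- tibble::tibble(sequence = shared, count = 4L)
  asn <- assign_reads(collapsed, refs, tiers = 0)
  expect_true(asn$records$cross_species)
  expect_match(asn$records$category, "^virus:V1,V2$|^virus:V2,V1$")
  s <- assignment_summary(asn, n_total = 4, n_ge16 = 4)
  expect_equal(s$V1, 4L)
  expect_equal(s$V2, 4L)
  expect_equal(s$cross_species, 4L)
})

test_that("equivalence classes group all placements of a read", {
  itr <- make_itr_genome(core_len = 800, itr_len = 145, arm_len = 30,
                         seed = 56)
  rd_arm <- substr(itr$reference$sequence, 5, 24)
  pl <- enumerate_placements(rd_arm, itr$reference, 0)
  ec <- equivalence_classes(pl)
  expect_gte(nrow(ec), 2)
  expect_equal(unique(ec$group), 1L)
  expect_setequal(unique(ec$strand), c("+", "-"))
  expect_equal(sum(ec$canonical), 1)
  # canonical is the lowest 5' coordinate, '+' preferred
  can <- ec[ec$canonical, ]
  expect_equal(can$five_prime, min(ec$five_prime))

  single <- enumerate_placements(
    substr(itr$reference$sequence, 400, 420), itr$reference, 0)
  ec1 <- equivalence_classes(single)
  expect_equal(nrow(ec1), 1)
  expect_true(ec1$canonical)
})

test_that("summaries partition length-filtered reads", {
  host <- make_host_reference(n_decoys = 1, decoy_len = 2000,
                              n_premirnas = 10, seed = 57)
  reads <- tibble::tibble(sequence = c(
    rep(host$mature$arm_seq[1], 3),
    substr(host$references$sequence[1], 11, 30)))
  collapsed <- collapse_reads(reads)
  asn <- assign_reads(collapsed, host$references, tiers = 0)
  s <- assignment_summary(asn, n_total = 5, n_ge16 = 4)
  expect_equal(s$human, 4L)
  expect_equal(s$human_mirna, 3L)
  expect_equal(s$unknown, 0L)
  expect_error(assignment_summary(asn, n_total = 5, n_ge16 = 7),
               "partition")
})
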