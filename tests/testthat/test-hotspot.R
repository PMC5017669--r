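# small fully-specified assignment fixture: one viral genome, reads planted
# at known 5' ends
hotspot_fixture <- function(seed = 60) {
  set.seed(seed)
  vir <- reference_set("vir", random_seq(3000), species = "V1",
                       role = "genome")
  host <- reference_set("h", random_seq(500), species = "host",
                        role = "genome")
  refs <- dplyr::bind_rows(host, vir)
  mk <- function(fp, strand, len) {
    if (strand == "+") substr(vir$sequence, fp, fp + len - 1)
    else reverse_complement(substr(vir$sequence, fp - len + 1, fp))
  }
  reads <- c(rep(mk(108, "+", 21), 8), rep(mk(108, "+", 22), 4),
             rep(mk(271, "-", 20), 9), rep(mk(1862, "+", 18), 5),
             mk(500, "+", 20))
  asn <- assign_reads(collapse_reads(tibble::tibble(sequence = reads)),
                      refs, tiers = 0)
  list(assignment = asn, refs = refs)
}

test_that("5'-end pileups count reads at their starting nucleotide", {
  fx <- hotspot_fixture()
  plus <- pileup_five_prime(fx$assignment, "vir", "+")
  expect_equal(plus$count[plus$pos == 108], 12L)   # spans 108..128 etc.
  expect_equal(plus$count[plus$pos == 1862], 5L)
  minus <- pileup_five_prime(fx$assignment, "vir", "-")
  # a minus-strand read spanning 252..271 contributes at 271
  expect_equal(minus$count[minus$pos == 271], 9L)
  expect_false(108 %in% minus$pos)
  none <- pileup_five_prime(fx$assignment, "h", "+")
  expect_equal(nrow(none), 0)
})

test_that("binning is sum-preserving with closed fixed-width intervals", {
  tr <- make_track(c(3, 7), c(5, 2))
  b10 <- bin_track(tr, 10)
  expect_equal(b10$bin_start, 1L)
  expect_equal(b10$count, 7L)
  b1 <- bin_track(tr, 1)
  expect_equal(b1$bin_start, tr$pos)
  expect_equal(b1$count, tr$count)
  set.seed(61)
  rt <- make_track(sample(5000, 300), rpois(300, 20), ref_length = 5000)
  for (w in c(10, 100)) {
    expect_equal(sum(bin_track(rt, w)$count), sum(rt$count))
  }
  # positions w and w+1 land in adjacent closed intervals
  edge <- bin_track(make_track(c(10, 11), c(1, 1)), 10)
  expect_equal(edge$bin_start, c(1L, 11L))
})

test_that("hotspot calling is strictly above threshold", {
  set.seed(62)
  bg <- make_track(c(108, 271, 1862, sample(3000:4000, 50)),
                   c(12002, 12737, 3780, sample(30, 50, replace = TRUE)),
                   ref_length = 4681)
  hs <- call_hotspots(bg, threshold = 3000)
  expect_equal(hs$name, c("sR-271", "sR-108", "sR-1862"))
  expect_equal(hs$count, c(12737L, 12002L, 3780L))

  at_thr <- make_track(c(5, 9), c(3000, 3001))
  hs2 <- call_hotspots(at_thr, threshold = 3000)
  expect_equal(hs2$five_prime, 9L)  # exactly 3000 is not a hotspot

  empty <- call_hotspots(make_track(integer(), integer()), 3000)
  expect_equal(nrow(empty), 0)
})

test_that("relative mode thresholds at a fold over median background", {
  tr <- make_track(c(1:99, 500), c(rep(30L, 99), 4000L),
                   ref_length = 1000)
  hs <- call_hotspots(tr, mode = "relative", relative_factor = 100)
  expect_equal(attr(hs, "background"), 30)
  expect_equal(attr(hs, "threshold"), 3000)
  expect_equal(hs$five_prime, 500L)
})

test_that("length statistics summarise supporting reads", {
  fx <- hotspot_fixture()
  plus <- pileup_five_prime(fx$assignment, "vir", "+")
  hs <- call_hotspots(plus, threshold = 4)
  st <- hotspot_length_stats(fx$assignment, hs)
  r108 <- st[st$five_prime == 108, ]
  expect_equal(r108$length_histogram[[1]]$length, c(21L, 22L))
  expect_equal(r108$length_histogram[[1]]$count, c(8L, 4L))
  expect_equal(r108$mean_length, round((21 * 8 + 22 * 4) / 12, 1))
  expect_equal(r108$mode_length, 21L)
  r1862 <- st[st$five_prime == 1862, ]
  expect_equal(r1862$length_histogram[[1]],
               tibble::tibble(length = 18L, count = 5L))
  expect_equal(r1862$mean_length, 18)
  expect_equal(r1862$median_length, 18)
})

test_that("mirrored terminal-repeat calls link into one group", {
  itr <- make_itr_genome(core_len = 2000, itr_len = 145, arm_len = 40,
                         seed = 63)
  rd <- substr(itr$reference$sequence, 1, 20)   # inside the palindromic arm
  interior <- substr(itr$reference$sequence, 1000, 1020)
  asn <- assign_reads(
    tibble::tibble(sequence = c(rd, interior), count = c(50L, 40L)) |>
      dplyr::arrange(sequence),
    itr$reference, tiers = 0)
  hs <- dplyr::bind_rows(
    call_hotspots(pileup_five_prime(asn, "AAV", "+"), 10),
    call_hotspots(pileup_five_prime(asn, "AAV", "-"), 10))
  linked <- link_equivalent_hotspots(hs, asn)
  arm_group <- linked$equiv_group[linked$five_prime == 1 &
                                    linked$strand == "+"]
  members <- linked[linked$equiv_group == arm_group, ]
  expect_gte(nrow(members), 2)
  # the sR-1 / sR-(2*arm_len) phenomenon: a minus-strand twin at 80
  expect_true(any(members$strand == "-" & members$five_prime == 80))
  # linked hotspots carry the same reads, so their counts are equal
  expect_equal(length(unique(members$count)), 1)
  solo <- linked[linked$five_prime == 1000, ]
  expect_equal(nrow(solo), 1)
  expect_equal(length(solo$equivalence_partners[[1]]), 0)
})

test_that("top-N candidate tables rank by count with positional ties", {
  fx <- hotspot_fixture()
  top <- top_hotspot_table(fx$assignment, "vir", n = 100)
  expect_equal(nrow(top), 4)
  expect_equal(top$name[1:2], c("sR-108", "sR-271"))
  expect_equal(top$count[1:2], c(12L, 9L))
  expect_equal(top$median_length[top$name == "sR-108"], 21)
  # matches an independent re-sort of the raw pileups
  raw <- dplyr::bind_rows(
    tibble::as_tibble(pileup_five_prime(fx$assignment, "vir", "+")),
    tibble::as_tibble(pileup_five_prime(fx$assignment, "vir", "-")))
  raw <- raw[order(-raw$count, raw$pos), ]
  expect_equal(top$five_prime, raw$pos)
  expect_equal(top$count, raw$count)
  top2 <- top_hotspot_table(fx$assignment, "vir", n = 2)
  expect_equal(nrow(top2), 2)
})
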