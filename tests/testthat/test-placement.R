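make_contig_fixture <- function() {
  withr::with_seed(41, {
    contig <- rnd_dna(5000)
    # plant one read exactly at 1000 (+) and its partner's revcomp at 2000
    list(contig = contig)
  })
}

test_that("exact placement finds forward, reverse and multi-locus hits", {
  withr::with_seed(43, contig <- rnd_dna(5000))
  fwd_read <- substr(contig, 1001, 1150)
  rev_read <- oracle_revcomp(substr(contig, 2001, 2150))
  # duplicate locus for the multi-mapping case
  dup_read <- substr(contig, 3001, 3150)
  contig2 <- paste0(substr(contig, 1, 4000), dup_read,
                    substr(contig, 4151, 5000))
  contigs <- tibble::tibble(contig_id = "c1", sequence = contig2,
                            sample_id = "s1")
  reads <- tibble::tibble(read_ordinal = 1:3, sample_id = "s1",
                          sequence = c(fwd_read, rev_read, dup_read))
  pl <- place_reads(reads, contigs)
  p1 <- pl[pl$read_ordinal == 1, ]
  expect_equal(p1$contig_start, 1000L)
  expect_equal(p1$strand, "+")
  p2 <- pl[pl$read_ordinal == 2, ]
  expect_equal(p2$contig_start, 2000L)
  expect_equal(p2$strand, "-")
  p3 <- pl[pl$read_ordinal == 3, ]
  expect_equal(sort(p3$contig_start), c(3000L, 4000L))
  # brute-force all-offset oracle
  for (i in 1:3) {
    s <- reads$sequence[i]
    want <- integer(0)
    for (off in 0:(nchar(contig2) - 150)) {
      if (substr(contig2, off + 1, off + 150) == s ||
          substr(contig2, off + 1, off + 150) == oracle_revcomp(s)) {
        want <- c(want, off)
      }
    }
    expect_equal(sort(pl$contig_start[pl$read_ordinal == i]), want)
  }
  # an unplaceable read is dropped and reported
  reads2 <- tibble::tibble(read_ordinal = 9L, sample_id = "s1",
                           sequence = rnd_dna(150))
  pl2 <- place_reads(reads2, contigs)
  expect_equal(nrow(pl2), 0)
  expect_equal(attr(pl2, "unplaced"), 9L)
})

test_that("the SAM adapter accepts flags 0/16 and rejects the rest", {
  dir <- withr::local_tempdir()
  reads <- tibble::tibble(read_ordinal = 1:4,
                          read_id = paste0("r", 1:4),
                          sequence = replicate(4, rnd_dna(100)))
  sam <- file.path(dir, "x.sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:c1\tLN:10000",
    "r1\t0\tc1\t1001\t42\t100M\t*\t0\t0\t*\t*",
    "r2\t16\tc1\t2001\t42\t100M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",        # unmapped
    "r4\t0\tc1\t3001\t42\t40M60S\t*\t0\t0\t*\t*" # clipped
  ), sam)
  pl <- read_sam_placements(sam, reads)
  expect_equal(pl$read_ordinal, c(1L, 2L))
  expect_equal(pl$contig_start, c(1000L, 2000L))
  expect_equal(pl$strand, c("+", "-"))
  expect_equal(pl$read_length, c(100L, 100L))
})

test_that("repeat projection follows the strand arithmetic", {
  withr::with_seed(47, contig <- rnd_dna(3000))
  contigs <- tibble::tibble(contig_id = "c1", sequence = contig,
                            sample_id = "s1", length = 3000L)
  base <- tibble::tibble(read_ordinal = 1L, contig_id = "c1",
                         sample_id = "s1", contig_start = 1000L,
                         read_length = 150L, contig_length = 3000L)
  rr <- tibble::tibble(read_ordinal = 1L, repeat_start = 30L,
                       repeat_end = 60L)
  plus <- project_repeats(dplyr::mutate(base, strand = "+"), rr, contigs)
  expect_equal(c(plus$start, plus$end), c(1030L, 1060L))
  minus <- project_repeats(dplyr::mutate(base, strand = "-"), rr, contigs)
  expect_equal(c(minus$start, minus$end), c(1090L, 1120L))
  expect_equal(plus$sequence, substr(contig, 1031, 1060))
  expect_equal(minus$sequence, substr(contig, 1091, 1120))
})

test_that("plant-a-repeat round trip recovers contig coordinates exactly", {
  withr::with_seed(53, {
    for (i in 1:40) {
      contig <- rnd_dna(2000)
      rep_start <- sample(300:1500, 1) # 0-based repeat interval
      rep_len <- sample(25:50, 1)
      read_start <- rep_start - sample(20:80, 1) # covers with margin
      read <- substr(contig, read_start + 1, read_start + 150)
      strand <- sample(c("+", "-"), 1)
      within_start <- rep_start - read_start
      if (strand == "-") {
        read_seq <- oracle_revcomp(read)
        rs <- 150 - (within_start + rep_len)
      } else {
        read_seq <- read
        rs <- within_start
      }
      contigs <- tibble::tibble(contig_id = "c1", sequence = contig,
                                sample_id = "s1")
      reads <- tibble::tibble(read_ordinal = 1L, sample_id = "s1",
                              sequence = read_seq)
      rr <- tibble::tibble(read_ordinal = 1L, repeat_start = rs,
                           repeat_end = rs + rep_len)
      pl <- place_reads(reads, contigs)
      cand <- project_repeats(pl, rr, contigs)
      expect_equal(cand$start, rep_start)
      expect_equal(cand$end, rep_start + rep_len)
      expect_equal(cand$sequence,
                   substr(contig, rep_start + 1, rep_start + rep_len))
    }
  })
})

test_that("candidates projecting outside the contig are dropped", {
  contigs <- tibble::tibble(contig_id = "c1", sequence = rnd_dna(200),
                            sample_id = "s1")
  pl <- tibble::tibble(read_ordinal = 1L, contig_id = "c1",
                       sample_id = "s1", contig_start = 100L,
                       strand = "+", read_length = 150L,
                       contig_length = 200L)
  rr <- tibble::tibble(read_ordinal = 1L, repeat_start = 80L,
                       repeat_end = 120L)
  expect_equal(nrow(project_repeats(pl, rr, contigs)), 0)
})

test_that("proximity pairing applies the span window", {
  cand <- tibble::tibble(
    candidate_id = c("a", "b", "c"), sample_id = "s1", contig_id = "c1",
    start = c(100L, 250L, 1500L), end = c(130L, 280L, 1530L),
    sequence = "X", read_ordinal = 1L)
  pairs <- pair_candidates(cand, 500, 3000)
  expect_equal(nrow(pairs), 2) # a-c (span 1430) and b-c (span 1280)
  expect_equal(pairs$span, c(1430L, 1280L))
  expect_false(any(pairs$itr1_id == "a" & pairs$itr2_id == "b")) # span 180
})

test_that("pairing equals an exhaustive double loop on random candidates", {
  withr::with_seed(59, {
    n <- 50
    cand <- tibble::tibble(
      candidate_id = paste0("k", 1:n),
      sample_id = sample(c("s1", "s2"), n, TRUE),
      contig_id = sample(c("c1", "c2"), n, TRUE),
      start = sample(0:5000, n), sequence = "X", read_ordinal = 1L) |>
      dplyr::mutate(end = start + sample(25:50, n, TRUE))
  })
  got <- pair_candidates(cand, 500, 3000)
  want <- 0L
  for (i in 1:50) {
    for (j in 1:50) {
      same <- cand$sample_id[i] == cand$sample_id[j] &&
        cand$contig_id[i] == cand$contig_id[j]
      if (same && cand$start[i] < cand$start[j]) {
        span <- cand$end[j] - cand$start[i]
        if (span >= 500 && span <= 3000) want <- want + 1L
      }
    }
  }
  expect_equal(nrow(got), want)
})
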