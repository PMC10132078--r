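test_that("stride follows the sparse-sampling rule and params validate", {
  expect_equal(mem_params()$stride, 11L)
  expect_equal(mem_params(min_itr_length = 20, kmer_length = 10)$stride, 11L)
  expect_error(mem_params(kmer_length = 30), "kmer_length <= min_itr_length")
  expect_error(mem_params(min_itr_length = 60, max_itr_length = 50),
               "min_itr_length <= max_itr_length")
})

test_that("sparse index holds k-mers at stride multiples, fully inside reads", {
  withr::with_seed(3, seqs <- c(rnd_dna(150), rnd_dna(14), rnd_dna(40)))
  st <- two_bit_store(reads_tbl(seqs), min_usable_length = 1)
  idx <- build_sparse_index(st, mem_params())
  expect_equal(idx$position[idx$read_ordinal == 1],
               seq(0L, 135L, by = 11L))
  # a 14-nt read cannot host a 15-mer
  expect_false(2L %in% idx$read_ordinal)
  expect_equal(idx$position[idx$read_ordinal == 3], c(0L, 11L, 22L))
  # indexed k-mers decode to the true subsequences (never cross spacers)
  expect_equal(idx$kmer,
               substr(seqs[idx$read_ordinal], idx$position + 1,
                      idx$position + 15))
})

test_that("every window of length >= L contains an indexed k-mer start", {
  withr::with_seed(21, seqs <- replicate(50, rnd_dna(150)))
  st <- two_bit_store(reads_tbl(seqs))
  p <- mem_params()
  idx <- build_sparse_index(st, p)
  windows <- 0:(150 - p$min_itr_length)
  covered <- vapply(split(idx$position, idx$read_ordinal), function(pos) {
    all(vapply(windows, function(w) {
      any(pos >= w & pos + p$kmer_length <= w + p$min_itr_length)
    }, TRUE))
  }, TRUE)
  expect_length(covered, 50)
  expect_true(all(covered))
})

test_that("seed extension equals naive base-by-base extension", {
  withr::with_seed(9, {
    # planted 30-nt shared block with guarded flanks: mismatching bases at
    # both boundaries so the MEM is exactly the block
    blk <- rnd_dna(30)
    r1 <- paste0(rnd_dna(39), "A", blk, "G", rnd_dna(79))
    r2 <- paste0(rnd_dna(59), "C", blk, "T", rnd_dna(59))
    st <- two_bit_store(reads_tbl(c(r1, r2)))
    m <- extend_seed(st, 1, 45, 2, 65, 15)
    expect_equal(m$start_a, 40L)
    expect_equal(m$start_b, 60L)
    expect_equal(m$length, 30L)

    # identical reads seeded at the same window span the full read
    r3 <- rnd_dna(150)
    st2 <- two_bit_store(reads_tbl(c(r3, r3)))
    m2 <- extend_seed(st2, 1, 50, 2, 50, 15)
    expect_equal(m2$length, 150L)
    expect_equal(m2$start_a, 0L)

    # randomized agreement with the naive oracle
    for (i in 1:200) {
      la <- sample(60:150, 1)
      lb <- sample(60:150, 1)
      sa <- rnd_dna(la)
      sb <- rnd_dna(lb)
      k <- 8
      pa <- sample(0:(la - k), 1)
      pb <- sample(0:(lb - k), 1)
      substr(sb, pb + 1, pb + k) <- substr(sa, pa + 1, pa + k)
      sti <- two_bit_store(reads_tbl(c(sa, sb)), min_usable_length = k)
      got <- extend_seed(sti, 1, pa, 2, pb, k)
      want <- oracle_extend(sa, pa, sb, pb, k)
      expect_equal(got$start_a, want$start_a)
      expect_equal(got$start_b, want$start_b)
      expect_equal(got$length, want$length)
    }
  })
})

test_that("repeat reads match the planted block and satisfy the filters", {
  withr::with_seed(13, {
    blk <- rnd_dna(30)
    r1 <- paste0(rnd_dna(39), "A", blk, "G", rnd_dna(79))
    r2 <- paste0(rnd_dna(59), "C", blk, "T", rnd_dna(59))
    filler <- replicate(5, rnd_dna(150))
  })
  st <- two_bit_store(reads_tbl(c(r1, r2, filler)))
  rr <- find_repeat_reads(st, mem_params())
  expect_equal(rr$read_ordinal, c(1L, 2L))
  expect_equal(rr$repeat_sequence, c(blk, blk))
  expect_equal(rr$repeat_start, c(40L, 60L))
  mems <- attr(rr, "mems")
  # maximality: no reported MEM extends by one base either way
  for (i in seq_len(nrow(mems))) {
    m <- mems[i, ]
    sa <- st$reads$sequence[m$read_a]
    sb <- st$reads$sequence[m$read_b]
    left_ok <- m$start_a == 0 || m$start_b == 0 ||
      substr(sa, m$start_a, m$start_a) != substr(sb, m$start_b, m$start_b)
    ra <- m$start_a + m$length
    rb <- m$start_b + m$length
    right_ok <- ra >= nchar(sa) || rb >= nchar(sb) ||
      substr(sa, ra + 1, ra + 1) != substr(sb, rb + 1, rb + 1)
    expect_true(left_ok && right_ok)
  }
})

test_that("exact duplicate reads are suppressed by the end-buffer rule", {
  withr::with_seed(17, r <- rnd_dna(150))
  st <- two_bit_store(reads_tbl(c(r, r, r)))
  rr <- find_repeat_reads(st, mem_params())
  expect_equal(nrow(rr), 0)
})

test_that("over-long shared blocks are rejected, not trimmed", {
  withr::with_seed(19, {
    blk <- rnd_dna(60)
    r1 <- paste0(rnd_dna(29), "A", blk, "G", rnd_dna(59))
    r2 <- paste0(rnd_dna(39), "C", blk, "T", rnd_dna(49))
  })
  seqs <- c(r1, r2)
  st <- two_bit_store(reads_tbl(seqs))
  rr <- find_repeat_reads(st, mem_params())
  expect_equal(nrow(rr), 0)
  # the oracle agrees: the only maximal common substring has length 60
  m <- oracle_mcs(r1, r2)
  expect_equal(max(m$length), 60)
  expect_equal(oracle_repeat_reads(seqs, mem_params()), integer(0))
})

test_that("find_repeat_reads equals the brute-force oracle on random pools", {
  p <- mem_params()
  withr::with_seed(29, {
    for (rep in 1:6) {
      n <- 20
      plants <- list(
        list(i = 1, j = 2, pos_i = 40, pos_j = 70,
             len = sample(25:50, 1)), # interior, qualifying
        list(i = 3, j = 4, pos_i = 5, pos_j = 60,
             len = sample(25:40, 1)), # touches the buffer on read 3
        list(i = 5, j = 6, pos_i = 50, pos_j = 50,
             len = sample(20:24, 1)), # below the minimum length
        list(i = 7, j = 8, pos_i = 30, pos_j = 90,
             len = sample(51:60, 1))) # above the maximum length
      seqs <- make_pool(n, 150, plants)
      st <- two_bit_store(reads_tbl(seqs))
      got <- find_repeat_reads(st, p)$read_ordinal
      expect_equal(got, oracle_repeat_reads(seqs, p))
    }
  })
})

test_that("repeat detection is symmetric and deterministic", {
  withr::with_seed(31, seqs <- make_pool(30, 150, list(
    list(i = 2, j = 9, pos_i = 45, pos_j = 80, len = 30),
    list(i = 12, j = 20, pos_i = 60, pos_j = 25, len = 40))))
  st <- two_bit_store(reads_tbl(seqs))
  rr1 <- find_repeat_reads(st, mem_params())
  rr2 <- find_repeat_reads(two_bit_store(reads_tbl(seqs)), mem_params())
  expect_identical(rr1, rr2)
  mems <- attr(rr1, "mems")
  expect_true(all(mems$read_a %in% rr1$read_ordinal))
  expect_true(all(mems$read_b %in% rr1$read_ordinal))
})
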