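make_pair <- function(s1, s2, span = 1430L) {
  tibble::tibble(
    sample_id = "s1", contig_id = "c1",
    itr1_id = "k1", itr1_start = 100L, itr1_end = 100L + nchar(s1),
    itr1_sequence = s1,
    itr2_id = "k2", itr2_start = 100L + span - nchar(s2),
    itr2_end = 100L + span, itr2_sequence = s2, span = span)
}

two_clusters <- function(same = TRUE) {
  tibble::tibble(id = c("k1", "k2"),
                 cluster_id = if (same) c(1L, 1L) else c(1L, 2L))
}

test_that("ITR pair validation enforces all four conditions", {
  withr::with_seed(97, s <- rnd_dna(30))
  # perfect reverse-complementary pair in one cluster
  v <- validate_itr_pairs(make_pair(s, oracle_revcomp(s)), two_clusters())
  expect_true(v$valid)
  expect_equal(v$revcomp_identities, 30L)

  # direct repeat (identical sequences) is not reverse-complementary
  withr::with_seed(101, {
    fails <- vapply(1:20, function(i) {
      d <- rnd_dna(30)
      vv <- validate_itr_pairs(make_pair(d, d), two_clusters())
      vv$revcomp_identities < 25
    }, TRUE)
  })
  expect_true(all(fails))

  # reverse complement with 3 interior mismatches keeps >= 25 identities
  withr::with_seed(103, {
    s2 <- oracle_revcomp(s)
    for (pos in c(8, 16, 23)) {
      cur <- substr(s2, pos, pos)
      substr(s2, pos, pos) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
  })
  v3 <- validate_itr_pairs(make_pair(s, s2), two_clusters())
  expect_true(v3$valid)
  expect_gte(v3$revcomp_identities, 27L)

  # same sequences, different clusters
  v4 <- validate_itr_pairs(make_pair(s, oracle_revcomp(s)),
                           two_clusters(same = FALSE))
  expect_false(v4$valid)
  expect_true(v4$revcomp_ok)

  # span outside the IS window
  v5 <- validate_itr_pairs(make_pair(s, oracle_revcomp(s), span = 400L),
                           two_clusters())
  expect_false(v5$valid)

  # a candidate missing from the clustering is an internal error
  expect_error(
    validate_itr_pairs(make_pair(s, oracle_revcomp(s)),
                       tibble::tibble(id = "k1", cluster_id = 1L)),
    class = "itrseek_error_internal")
})

test_that("IS records extract the contig span between the ITRs inclusive", {
  withr::with_seed(107, {
    itr <- rnd_dna(30)
    contig <- rnd_dna(5000)
  })
  substr(contig, 1001, 1030) <- itr
  substr(contig, 2401, 2430) <- oracle_revcomp(itr)
  contigs <- tibble::tibble(contig_id = "c1", sequence = contig,
                            sample_id = "s1")
  pairs <- tibble::tibble(
    sample_id = "s1", contig_id = "c1",
    itr1_id = "k1", itr1_start = 1000L, itr1_end = 1030L,
    itr1_sequence = itr,
    itr2_id = "k2", itr2_start = 2400L, itr2_end = 2430L,
    itr2_sequence = oracle_revcomp(itr), span = 1430L, valid = TRUE)
  recs <- call_insertion_sequences(pairs, contigs)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$length, 1430L)
  expect_equal(nchar(recs$sequence), 1430L)
  expect_equal(recs$itr1_start, 1001L)
  expect_equal(recs$itr2_end, 2430L)
  # the record's first and last segments equal the two candidate ITRs
  expect_equal(substr(recs$sequence, 1, 30), itr)
  expect_equal(substr(recs$sequence, 1401, 1430), oracle_revcomp(itr))

  # empty input is an empty, well-formed result
  expect_equal(nrow(call_insertion_sequences(pairs[0, ], contigs)), 0)
})

test_that("one ITR shared by two partners yields two records", {
  withr::with_seed(109, {
    itr <- rnd_dna(30)
    contig <- rnd_dna(6000)
  })
  substr(contig, 1001, 1030) <- itr
  substr(contig, 2401, 2430) <- oracle_revcomp(itr)
  substr(contig, 3501, 3530) <- oracle_revcomp(itr)
  contigs <- tibble::tibble(contig_id = "c1", sequence = contig,
                            sample_id = "s1")
  cand <- tibble::tibble(
    candidate_id = c("k1", "k2", "k3"), sample_id = "s1",
    contig_id = "c1", start = c(1000L, 2400L, 3500L),
    end = c(1030L, 2430L, 3530L),
    sequence = c(itr, oracle_revcomp(itr), oracle_revcomp(itr)),
    read_ordinal = 1L)
  clusters <- cluster_greedy(
    dplyr::select(cand, id = "candidate_id", "sequence"), cluster_params())
  pairs <- pair_candidates(cand, 500, 3000)
  v <- validate_itr_pairs(pairs, clusters)
  recs <- call_insertion_sequences(v, contigs)
  expect_equal(nrow(recs), 2)
  expect_equal(sort(recs$length), c(1430L, 2530L))
})

test_that("IS names concatenate accession segments in start order", {
  expect_equal(
    name_is(1391, data.frame(accession = "IPR001207", nt_start = 495,
                             nt_end = 804)),
    "IS_length_1391-IPR001207_495_804")
  hits <- data.frame(
    accession = c("IPR036397", "PTHR35004", "IPR012337"),
    nt_start = c(1291, 877, 1315), nt_end = c(1768, 2065, 1720))
  expect_equal(
    name_is(2555, hits),
    "IS_length_2555-IPR036397_1291_1768-PTHR35004_877_2065-IPR012337_1315_1720")
  # duplicated hits collapse to one segment
  expect_equal(name_is(2555, hits[c(1, 1, 2, 3), ]), name_is(2555, hits))
  expect_equal(name_is(1391, NULL), "IS_length_1391")
  expect_equal(name_is(1391, hits[0, ]), "IS_length_1391")
})
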