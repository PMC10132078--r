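test_that("a minimal ORF is found with the right coordinates", {
  orfs <- extract_orfs("ATGAAATAA", min_aa = 2)
  plus1 <- orfs[orfs$frame == 1L, ]
  expect_equal(plus1$aa_sequence, "MK")
  expect_equal(plus1$nt_start, 1L)
  expect_equal(plus1$nt_end, 6L)
})

test_that("reverse-strand ORF coordinates agree with revcomp-and-rescan", {
  withr::with_seed(113, s <- rnd_dna(300))
  orfs <- extract_orfs(s, min_aa = 10)
  rc_orfs <- extract_orfs(oracle_revcomp(s), min_aa = 10)
  # a -f ORF at [a, b] on s is a +f ORF at [L - b + 1, L - a + 1] on rc(s)
  L <- nchar(s)
  mapped <- data.frame(frame = -rc_orfs$frame,
                       nt_start = L - rc_orfs$nt_end + 1L,
                       nt_end = L - rc_orfs$nt_start + 1L)
  got <- orfs[c("frame", "nt_start", "nt_end")]
  expect_equal(
    got[order(got$nt_start, got$frame), ],
    mapped[order(mapped$nt_start, mapped$frame), ],
    ignore_attr = TRUE)
})

test_that("six-frame ORF sets equal a naive stop-split oracle", {
  withr::with_seed(127, {
    for (i in 1:10) {
      s <- rnd_dna(300)
      got <- extract_orfs(s, min_aa = 15)
      want <- oracle_orfs(s, min_aa = 15)
      expect_equal(got[c("frame", "nt_start", "nt_end")], as_tibble(want),
                   ignore_attr = TRUE)
    }
  })
})

test_that("translating the reported interval reproduces the ORF peptide", {
  withr::with_seed(131, s <- rnd_dna(600))
  orfs <- extract_orfs(s, min_aa = 20)
  for (i in seq_len(nrow(orfs))) {
    nt <- substr(s, orfs$nt_start[i], orfs$nt_end[i])
    if (orfs$frame[i] < 0) nt <- oracle_revcomp(nt)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                             no.init.codon = TRUE))
    expect_equal(aa, orfs$aa_sequence[i])
  }
})

test_that("InterProScan TSV parsing maps aa to nt coordinates", {
  dir <- withr::local_tempdir()
  # an ORF starting at nt 495 in a + frame, long enough for 103 codons
  orfs <- tibble::tibble(orf_id = "IS1_orf1", is_id = "IS1", frame = 3L,
                         nt_start = 495L, nt_end = 854L,
                         aa_sequence = strrep("A", 120))
  tsv <- file.path(dir, "ipr.tsv")
  writeLines(ipr_row("IS1_orf1", analysis = "ProSiteProfiles",
                     sig_acc = "PS50994", sig_desc = "Integrase cat",
                     aa_start = 1, aa_end = 103, ipr_acc = "IPR001207",
                     ipr_desc = "Transposase, mutator type"), tsv)
  hits <- parse_interproscan(tsv, orfs)
  expect_equal(hits$accession, "IPR001207")
  expect_equal(hits$description, "Transposase, mutator type")
  expect_equal(hits$nt_start, 495L)
  expect_equal(hits$nt_end, 495L + 103L * 3L - 1L) # exact codon span
})

test_that("rows without an InterPro accession fall back to the signature", {
  dir <- withr::local_tempdir()
  orfs <- tibble::tibble(orf_id = "IS1_orf1", is_id = "IS1", frame = 1L,
                         nt_start = 1L, nt_end = 300L,
                         aa_sequence = strrep("A", 100))
  tsv <- file.path(dir, "ipr.tsv")
  writeLines(c(
    ipr_row("IS1_orf1", analysis = "PANTHER", sig_acc = "PTHR35004",
            sig_desc = "RV3428C-related Transposase", aa_start = 5,
            aa_end = 50),
    "too\tfew\tcolumns"), tsv)
  expect_warning(hits <- parse_interproscan(tsv, orfs), "malformed")
  expect_equal(hits$accession, "PTHR35004")
  expect_equal(hits$nt_start, 1L + 4L * 3L)
  expect_equal(hits$nt_end, 50L * 3L)
})

test_that("empty annotation files and unknown queries are handled", {
  dir <- withr::local_tempdir()
  orfs <- tibble::tibble(orf_id = "IS1_orf1", is_id = "IS1", frame = 1L,
                         nt_start = 1L, nt_end = 300L,
                         aa_sequence = strrep("A", 100))
  tsv <- file.path(dir, "empty.tsv")
  file.create(tsv)
  expect_equal(nrow(parse_interproscan(tsv, orfs)), 0)
  writeLines(ipr_row("who_dis", sig_acc = "PTHR1", sig_desc = "x",
                     aa_start = 1, aa_end = 10), tsv)
  expect_error(parse_interproscan(tsv, orfs), "unknown query",
               class = "itrseek_error_input")
})

test_that("the mock annotator finds the planted marker ORF", {
  withr::with_seed(137, {
    body <- rnd_dna(800)
    substr(body, 301, 300 + nchar(marker_orf()$nt)) <- marker_orf()$nt
  })
  recs <- tibble::tibble(is_id = "IS1", sequence = body, length = 800L)
  ann <- annotate_is(recs, annotation = "mock")
  hits <- ann$protein_hits[[1]]
  expect_equal(nrow(hits), 1)
  expect_equal(hits$accession, "IPR990001")
  expect_match(hits$description, "Transposase")
  # the motif's nt interval translates back to the motif peptide
  nt <- substr(body, hits$nt_start, hits$nt_end)
  if (hits$source_frame < 0) nt <- oracle_revcomp(nt)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           no.init.codon = TRUE))
  expect_equal(aa, "DDENHKRAGTW")
})

test_that("the transposase description filter keeps only keyword matches", {
  mk <- function(desc) {
    tibble::tibble(accession = "X", description = desc, nt_start = 1L,
                   nt_end = 30L, source_frame = 1L)
  }
  recs <- tibble::tibble(
    is_id = paste0("IS", 1:4),
    sequence = "ACGT", length = 4L,
    protein_hits = list(mk("Transposase, mutator type"),
                        mk("ABC transporter ATP-binding protein"),
                        mk("Ribonuclease H-like superfamily"),
                        mk("HTH-type integrase-like domain")))
  kept <- filter_transposase(recs)
  expect_equal(kept$is_id, c("IS1", "IS3", "IS4"))
  expect_equal(attr(kept, "dropped")$is_id, "IS2")
  # idempotent and order-independent
  expect_equal(filter_transposase(kept)$is_id, kept$is_id)
  kept_rev <- filter_transposase(recs[4:1, ])
  expect_setequal(kept_rev$is_id, kept$is_id)
})
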