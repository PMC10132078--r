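# Synthetic truth sets: contigs carrying planted ISs (ITR pair + body with
# an optional transposase marker ORF), tiled into error-free reads on both
# strands, with optional exact duplicate reads emulating technical repeats.
# Planted coordinates are exact ground truth: the bases flanking every ITR
# occurrence are chosen so that no exact match can extend past the planted
# boundaries, and ITR mismatches are placed at evenly spaced interior
# positions so no residual exact run reaches the minimum ITR length.

#' Specification for a planted-IS truth set
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in nt.
#' @param n_is Number of planted IS elements (families).
#' @param itr_len_range Inclusive range of ITR lengths in nt (default
#'   25-50).
#' @param is_len_range Inclusive range of IS lengths (first ITR start
#'   through second ITR end) in nt (default 500-3000).
#' @param itr_mismatches Substitutions between the second ITR and the
#'   reverse complement of the first (default 0). A single-copy element
#'   with imperfect ITRs carries no exact inter-read repeat, so with
#'   `itr_mismatches > 0` use `copies_per_is = 2`: the copies share the
#'   ITR pair but have independent bodies, giving the exact cross-locus
#'   repeats the method detects in real communities.
#' @param copies_per_is Planted copies per element (1 or 2).
#' @param transposase_stub Embed the [marker_orf()] in each IS body so the
#'   mock annotator recognizes the element (default TRUE).
#' @param duplicate_read_fraction Fraction of reads duplicated verbatim as
#'   technical repeats (default 0).
#' @param read_length Read length in nt (default 150).
#' @param tiling_step Read start spacing in nt on each strand (default 10).
#' @param seed Seed for all randomness in the generator.
#' @return A validated list of class `plant_spec`.
#' @export
plant_spec <- function(n_contigs = 10L, contig_length = 50000L, n_is = 15L,
                       itr_len_range = c(25L, 50L),
                       is_len_range = c(500L, 3000L), itr_mismatches = 0L,
                       copies_per_is = 1L, transposase_stub = TRUE,
                       duplicate_read_fraction = 0,
                       read_length = 150L, tiling_step = 10L, seed = 1L) {
  spec <- list(n_contigs = as.integer(n_contigs),
               contig_length = as.integer(contig_length),
               n_is = as.integer(n_is),
               itr_len_range = as.integer(itr_len_range),
               is_len_range = as.integer(is_len_range),
               itr_mismatches = as.integer(itr_mismatches),
               copies_per_is = as.integer(copies_per_is),
               transposase_stub = isTRUE(transposase_stub),
               duplicate_read_fraction = duplicate_read_fraction,
               read_length = as.integer(read_length),
               tiling_step = as.integer(tiling_step),
               seed = as.integer(seed))
  if (spec$n_contigs < 1 || spec$contig_length < 4 * spec$read_length) {
    stop_input("contigs must be at least 4 read lengths long")
  }
  if (spec$copies_per_is < 1 || spec$copies_per_is > 2) {
    stop_input("copies_per_is must be 1 or 2")
  }
  max_itr <- spec$read_length - 2L * 20L - 1L
  if (spec$itr_len_range[1] < 1 || spec$itr_len_range[2] > max_itr ||
      spec$itr_len_range[1] > spec$itr_len_range[2]) {
    stop_input(paste0("itr_len_range must be within [1, ", max_itr,
                      "] so planted ITRs can survive the end-buffer rule"))
  }
  if (spec$n_is > 0 &&
      spec$is_len_range[1] < 2 * spec$itr_len_range[2] + 200L) {
    stop_input("is_len_range too small for two ITRs and a body")
  }
  if (spec$itr_mismatches < 0 ||
      (spec$n_is > 0 && spec$itr_mismatches >= spec$itr_len_range[1])) {
    stop_input("itr_mismatches must be in [0, min ITR length)")
  }
  if (spec$duplicate_read_fraction < 0 || spec$duplicate_read_fraction > 1) {
    stop_input("duplicate_read_fraction must be in [0, 1]")
  }
  if (spec$tiling_step < 1) stop_input("tiling_step must be >= 1")
  class(spec) <- "plant_spec"
  spec
}

BASES <- c("A", "C", "G", "T")
comp_base <- function(b) unname(c(A = "T", C = "G", G = "C", T = "A")[b])

# sample() without the scalar-x surprise
resample <- function(x, n = 1L) x[sample.int(length(x), n)]

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# substitute at evenly spaced interior positions so residual exact runs
# between the two ITRs stay short
mutate_evenly <- function(seq, m) {
  if (m == 0) return(seq)
  len <- nchar(seq)
  pos <- unique(pmin(pmax(round(seq_len(m) * (len + 1) / (m + 1)), 2L),
                     len - 1L))
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# layout of one planted IS copy inside its contig, all 1-based inclusive
plant_layout <- function(is_start, itr_len, is_len) {
  list(itr1_start = is_start, itr1_end = is_start + itr_len - 1L,
       itr2_start = is_start + is_len - itr_len,
       itr2_end = is_start + is_len - 1L)
}

#' Generate a planted-IS truth set on disk
#'
#' Writes, under `dir`: an assembly FASTA, a pair of gzipped FASTQ files
#' (forward-strand tiles as mate 1, reverse-strand tiles as mate 2), a
#' tab-delimited truth table of every planted IS copy, and a ready-to-run
#' manifest. All truth coordinates are 1-based inclusive contig positions.
#' The same spec (including its seed) always reproduces byte-identical
#' files.
#'
#' @param spec A [plant_spec()].
#' @param dir Output directory (created if needed).
#' @param sample_id,lane_id Identifiers used in file names and the
#'   manifest.
#' @return A list with `manifest` (path), `truth` (tibble), `contigs`
#'   (tibble) and the individual file paths.
#' @export
generate_truth_set <- function(spec, dir, sample_id = "sampleA",
                               lane_id = "lane1") {
  stopifnot(inherits(spec, "plant_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- withr::with_seed(spec$seed, build_truth_set(spec, sample_id))
  contigs <- res$contigs
  truth <- res$truth
  reads <- res$reads

  assembly_path <- file.path(dir, paste0(sample_id, "_assembly.fasta"))
  write_fasta(contigs, assembly_path, id_col = "contig_id")
  fq1 <- file.path(dir, paste0(lane_id, "_1.fastq.gz"))
  fq2 <- file.path(dir, paste0(lane_id, "_2.fastq.gz"))
  write_fastq_gz(reads[reads$mate == 1L, ], fq1, spec$read_length)
  write_fastq_gz(reads[reads$mate == 2L, ], fq2, spec$read_length)
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(truth, truth_path, progress = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(tibble(lane_id = lane_id, fastq1_path = fq1,
                          fastq2_path = fq2, sample_id = sample_id,
                          assembly_path = assembly_path),
                   manifest_path, progress = FALSE)
  list(manifest = manifest_path, truth = truth, contigs = contigs,
       assembly = assembly_path, fastq1 = fq1, fastq2 = fq2,
       truth_path = truth_path)
}

write_fastq_gz <- function(reads, path, read_length) {
  con <- gzfile(path, open = "wb")
  on.exit(close(con))
  if (nrow(reads) == 0) return(invisible(path))
  qual <- strrep("I", nchar(reads$sequence))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, con)
  invisible(path)
}

# all randomness already seeded by the caller
build_truth_set <- function(spec, sample_id) {
  rl <- spec$read_length
  margin <- 2L * rl
  marker <- marker_orf()$nt

  # element anatomy per family; both copies of a family share the ITR pair
  families <- purrr::map(seq_len(spec$n_is), function(fam) {
    itr_len <- resample(seq(spec$itr_len_range[1], spec$itr_len_range[2]))
    lo <- max(spec$is_len_range[1], 2L * itr_len + nchar(marker) + 20L)
    is_len <- resample(seq(lo, spec$is_len_range[2]))
    itr1 <- random_dna(itr_len)
    itr2 <- mutate_evenly(revcomp(itr1), spec$itr_mismatches)
    # flank letters enforcing sharp repeat boundaries: for every pair of
    # occurrences of the shared ITR strings, left-adjacent bases differ and
    # right-adjacent bases differ, so MEMs cannot extend past the ITR
    lperm <- sample(BASES)
    rperm <- sample(BASES)
    list(itr_len = itr_len, is_len = is_len, itr1 = itr1, itr2 = itr2,
         # copy c: contig base before ITR1 = lperm[c]; base after ITR2 =
         # comp(lperm[2 + c]); body first base = rperm[c]; body last base =
         # comp(rperm[2 + c])
         lperm = lperm, rperm = rperm)
  })

  plants <- tidyr::crossing(family = seq_len(spec$n_is),
                            copy = seq_len(spec$copies_per_is)) |>
    arrange(.data$family, .data$copy)
  n_plants <- nrow(plants)
  plants$contig <- if (n_plants > 0) {
    (seq_len(n_plants) - 1L) %% spec$n_contigs + 1L
  } else integer(0)
  plants$is_len <- if (n_plants > 0) {
    purrr::map_int(plants$family, ~ families[[.x]]$is_len)
  } else integer(0)

  # position plants: non-overlapping, >= margin from contig ends and
  # between neighbouring elements
  plants$is_start <- NA_integer_
  usable <- spec$contig_length - 2L * margin
  for (ci in seq_len(spec$n_contigs)) {
    rows <- which(plants$contig == ci)
    if (length(rows) == 0) next
    lens <- plants$is_len[rows]
    m <- length(lens)
    leftover <- usable - sum(lens) - (m - 1L) * margin
    if (leftover < 0) {
      stop_input("planted ISs cannot fit (reduce n_is or lengthen contigs)")
    }
    cuts <- sort(sample.int(leftover + 1L, m, replace = TRUE) - 1L)
    offset <- margin + 1L
    for (j in seq_len(m)) {
      pos <- offset + cuts[j] +
        (if (j > 1) sum(lens[seq_len(j - 1L)]) + (j - 1L) * margin else 0L)
      plants$is_start[rows[j]] <- pos
    }
  }

  # build contigs as character vectors, then plant
  contig_chars <- purrr::map(seq_len(spec$n_contigs),
                             ~ sample(BASES, spec$contig_length,
                                      replace = TRUE))
  truth_rows <- vector("list", n_plants)
  for (i in seq_len(n_plants)) {
    fam <- families[[plants$family[i]]]
    cc <- plants$copy[i]
    ci <- plants$contig[i]
    is_start <- plants$is_start[i]
    body_len <- fam$is_len - 2L * fam$itr_len
    body <- random_dna(body_len)
    if (spec$transposase_stub) {
      mpos <- resample(seq(2L, body_len - nchar(marker)))
      substr(body, mpos, mpos + nchar(marker) - 1L) <- marker
    }
    # sharp boundaries (see family construction)
    substr(body, 1L, 1L) <- fam$rperm[cc]
    substr(body, body_len, body_len) <- comp_base(fam$rperm[2L + cc])
    is_seq <- paste0(fam$itr1, body, fam$itr2)
    chars <- strsplit(is_seq, "")[[1]]
    lay <- plant_layout(is_start, fam$itr_len, fam$is_len)
    contig_chars[[ci]][seq(is_start, lay$itr2_end)] <- chars
    contig_chars[[ci]][is_start - 1L] <- fam$lperm[cc]
    contig_chars[[ci]][lay$itr2_end + 1L] <- comp_base(fam$lperm[2L + cc])
    truth_rows[[i]] <- tibble(
      family = plants$family[i], copy = cc, sample_id = sample_id,
      contig_id = paste0("contig", ci),
      itr1_start = lay$itr1_start, itr1_end = lay$itr1_end,
      itr2_start = lay$itr2_start, itr2_end = lay$itr2_end,
      itr_length = fam$itr_len, is_length = fam$is_len,
      itr_mismatches = spec$itr_mismatches)
  }
  truth <- if (n_plants > 0) bind_rows(truth_rows) else
    tibble(family = integer(), copy = integer(), sample_id = character(),
           contig_id = character(), itr1_start = integer(),
           itr1_end = integer(), itr2_start = integer(),
           itr2_end = integer(), itr_length = integer(),
           is_length = integer(), itr_mismatches = integer())

  contigs <- tibble(
    contig_id = paste0("contig", seq_len(spec$n_contigs)),
    sequence = purrr::map_chr(contig_chars, paste, collapse = ""),
    sample_id = sample_id,
    length = spec$contig_length)

  # tile error-free reads on both strands
  starts <- seq(1L, spec$contig_length - rl + 1L, by = spec$tiling_step)
  read_rows <- purrr::map(seq_len(spec$n_contigs), function(ci) {
    fwd <- substring(contigs$sequence[ci], starts, starts + rl - 1L)
    rev <- revcomp(fwd)
    tibble(
      read_id = c(sprintf("c%d_f_%d", ci, starts),
                  sprintf("c%d_r_%d", ci, starts)),
      sequence = c(fwd, rev),
      mate = rep(c(1L, 2L), each = length(starts)))
  })
  reads <- bind_rows(read_rows)
  ndup <- round(spec$duplicate_read_fraction * nrow(reads))
  if (ndup > 0) {
    dup_idx <- sample.int(nrow(reads), ndup, replace = FALSE)
    dups <- reads[dup_idx, ] |>
      mutate(read_id = paste0("dup_", .data$read_id))
    reads <- bind_rows(reads, dups)
  }
  list(contigs = contigs, truth = truth, reads = reads)
}
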