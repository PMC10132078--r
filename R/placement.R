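# Placing repeat-containing reads on their sample's assembly contigs and
# projecting repeat intervals into contig coordinates, then pairing
# candidate ITRs by proximity.

#' Place reads on contigs by exact matching
#'
#' The internal mapper reports every position where the full read matches a
#' contig exactly, on either strand (synthetic reads are error-free; for
#' real data, supply placements from an external aligner through
#' [read_sam_placements()]). Multi-mapping reads keep all placements.
#'
#' @param reads Tibble with `read_ordinal`, `sequence` and (if present)
#'   `sample_id`; typically the output of [find_repeat_reads()].
#' @param contigs Contig tibble from [read_assembly()]. When both sides
#'   carry `sample_id`, reads are only matched against contigs of their own
#'   sample.
#' @return A tibble of placements: `read_ordinal`, `contig_id`,
#'   `sample_id`, `contig_start` (0-based), `strand` (`"+"`/`"-"`),
#'   `read_length`, `contig_length`. Reads mapping nowhere are dropped and
#'   reported in attribute `"unplaced"`.
#' @export
place_reads <- function(reads, contigs) {
  stopifnot(is.data.frame(reads), is.data.frame(contigs))
  empty <- tibble(read_ordinal = integer(), contig_id = character(),
                  sample_id = character(), contig_start = integer(),
                  strand = character(), read_length = integer(),
                  contig_length = integer())
  if (nrow(reads) == 0 || nrow(contigs) == 0) {
    attr(empty, "unplaced") <- integer(0)
    return(empty)
  }
  by_sample <- "sample_id" %in% names(reads) && "sample_id" %in% names(contigs) &&
    !anyNA(reads$sample_id) && !anyNA(contigs$sample_id)
  groups <- if (by_sample) unique(reads$sample_id) else NA_character_
  out <- vector("list", 0)
  for (g in groups) {
    r <- if (by_sample) reads[reads$sample_id == g, ] else reads
    ct <- if (by_sample) contigs[contigs$sample_id == g, ] else contigs
    if (nrow(r) == 0 || nrow(ct) == 0) next
    subject <- Biostrings::DNAStringSet(ct$sequence)
    uniq <- unique(r$sequence)
    for (s in uniq) {
      hits_one <- function(pattern, strand) {
        m <- Biostrings::vmatchPattern(pattern, subject)
        st <- BiocGenerics::unlist(m)
        if (length(st) == 0) return(NULL)
        ci <- rep(seq_along(m), lengths(m))
        tibble(contig_idx = ci,
               contig_start = BiocGenerics::start(st) - 1L,
               strand = strand)
      }
      fw <- hits_one(s, "+")
      rv <- hits_one(revcomp(s), "-")
      hits <- bind_rows(fw, rv)
      if (is.null(hits) || nrow(hits) == 0) next
      ridx <- which(r$sequence == s)
      hits <- hits |>
        mutate(contig_id = ct$contig_id[.data$contig_idx],
               sample_id = ct$sample_id[.data$contig_idx],
               contig_length = nchar(ct$sequence)[.data$contig_idx],
               read_length = nchar(s)) |>
        select(-"contig_idx")
      out[[length(out) + 1L]] <- tidyr::crossing(
        tibble(read_ordinal = r$read_ordinal[ridx]), hits)
    }
  }
  if (length(out) == 0) {
    attr(empty, "unplaced") <- sort(unique(reads$read_ordinal))
    return(empty)
  }
  pl <- bind_rows(out) |>
    relocate("read_ordinal", "contig_id", "sample_id", "contig_start",
             "strand", "read_length", "contig_length") |>
    arrange(.data$read_ordinal, .data$contig_id, .data$contig_start,
            .data$strand)
  attr(pl, "unplaced") <- sort(setdiff(reads$read_ordinal, pl$read_ordinal))
  pl
}

#' Ingest placements from a minimal SAM file
#'
#' Accepts records with FLAG 0 (forward) or 16 (reverse) whose CIGAR is a
#' single full-length match (`<len>M`); unmapped (FLAG 4) and clipped or
#' gapped alignments are dropped. QNAMEs are matched against `read_id` in
#' `reads` to recover read ordinals and lengths.
#'
#' @param path SAM file.
#' @param reads Tibble with `read_ordinal`, `read_id`, `sequence`.
#' @param contigs Optional contig tibble used to attach `sample_id` and
#'   `contig_length`.
#' @return A placement tibble with the same schema as [place_reads()].
#' @export
read_sam_placements <- function(path, reads, contigs = NULL) {
  if (!file.exists(path)) stop_input(paste0("SAM not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  empty <- tibble(read_ordinal = integer(), contig_id = character(),
                  sample_id = character(), contig_start = integer(),
                  strand = character(), read_length = integer(),
                  contig_length = integer())
  if (length(lines) == 0) return(empty)
  f <- stringr::str_split_fixed(lines, "\t", 7)
  flag <- suppressWarnings(as.integer(f[, 2]))
  pos <- suppressWarnings(as.integer(f[, 4]))
  keep <- flag %in% c(0L, 16L)
  qname <- f[keep, 1]
  rn <- f[keep, 3]
  pos <- pos[keep]
  cigar <- f[keep, 6]
  strand <- if_else(flag[keep] == 16L, "-", "+")
  ord <- reads$read_ordinal[match(qname, reads$read_id)]
  rlen <- nchar(reads$sequence)[match(qname, reads$read_id)]
  full_match <- !is.na(rlen) & cigar == paste0(rlen, "M")
  if (anyNA(ord)) {
    warn(paste0("SAM records for unknown read IDs dropped: ",
                paste(utils::head(unique(qname[is.na(ord)]), 5),
                      collapse = ", ")))
  }
  keep2 <- !is.na(ord) & full_match & !is.na(pos)
  pl <- tibble(read_ordinal = ord[keep2], contig_id = rn[keep2],
               sample_id = NA_character_, contig_start = pos[keep2] - 1L,
               strand = strand[keep2], read_length = rlen[keep2],
               contig_length = NA_integer_)
  if (!is.null(contigs)) {
    pl <- pl |>
      select(-"sample_id", -"contig_length") |>
      left_join(contigs |>
                  transmute(contig_id = .data$contig_id,
                            sample_id = .data$sample_id,
                            contig_length = nchar(.data$sequence)),
                by = "contig_id") |>
      relocate("read_ordinal", "contig_id", "sample_id", "contig_start",
               "strand", "read_length", "contig_length")
  }
  arrange(pl, .data$read_ordinal, .data$contig_id, .data$contig_start)
}

#' Project repeat intervals from reads onto contigs
#'
#' For a forward placement the contig interval is
#' `[contig_start + repeat_start, contig_start + repeat_end)`; for a
#' reverse placement it is reflected through the read:
#' `[contig_start + read_length - repeat_end,
#'    contig_start + read_length - repeat_start)`. The candidate sequence
#' is always read off the contig forward strand. Candidates projecting
#' outside the contig are dropped; duplicates (same contig interval from
#' different reads) collapse to one, keeping the first source read.
#'
#' @param placements Placement tibble from [place_reads()] or
#'   [read_sam_placements()].
#' @param repeat_reads Repeat-read tibble from [find_repeat_reads()].
#' @param contigs Contig tibble from [read_assembly()].
#' @return A candidate-ITR tibble: `candidate_id`, `sample_id`,
#'   `contig_id`, `start`, `end` (0-based half-open), `sequence`,
#'   `read_ordinal` (first source read).
#' @export
project_repeats <- function(placements, repeat_reads, contigs) {
  empty <- tibble(candidate_id = character(), sample_id = character(),
                  contig_id = character(), start = integer(),
                  end = integer(), sequence = character(),
                  read_ordinal = integer())
  if (nrow(placements) == 0 || nrow(repeat_reads) == 0) return(empty)
  x <- inner_join(placements,
                  repeat_reads |>
                    select("read_ordinal", "repeat_start", "repeat_end"),
                  by = "read_ordinal") |>
    mutate(
      start = if_else(.data$strand == "+",
                      .data$contig_start + .data$repeat_start,
                      .data$contig_start + .data$read_length - .data$repeat_end),
      end = if_else(.data$strand == "+",
                    .data$contig_start + .data$repeat_end,
                    .data$contig_start + .data$read_length - .data$repeat_start)
    ) |>
    filter(.data$start >= 0, .data$end <= .data$contig_length)
  if (nrow(x) == 0) return(empty)
  contig_seq <- contigs$sequence[match(paste(x$sample_id, x$contig_id),
                                       paste(contigs$sample_id,
                                             contigs$contig_id))]
  x |>
    mutate(sequence = substr(contig_seq, .data$start + 1L, .data$end)) |>
    arrange(.data$sample_id, .data$contig_id, .data$start, .data$end,
            .data$read_ordinal) |>
    distinct(.data$sample_id, .data$contig_id, .data$start, .data$end,
             .keep_all = TRUE) |>
    mutate(candidate_id = paste0(.data$sample_id, "|", .data$contig_id, "|",
                                 .data$start, "-", .data$end)) |>
    select("candidate_id", "sample_id", "contig_id", "start", "end",
           "sequence", "read_ordinal")
}

#' Pair candidate ITRs by proximity
#'
#' Emits unordered pairs of candidates on the same contig, ordered so that
#' `itr1_start < itr2_start`, whose span from the start of the first ITR to
#' the end of the second (the putative IS including both ITRs) lies within
#' `[min_is_length, max_is_length]`. A candidate may participate in several
#' pairs.
#'
#' @param candidates Candidate tibble from [project_repeats()].
#' @param min_is_length,max_is_length IS length window in nt (defaults 500
#'   and 3000).
#' @return A tibble of pairs with `itr1_*` and `itr2_*` columns and `span`.
#' @export
pair_candidates <- function(candidates, min_is_length = 500L,
                            max_is_length = 3000L) {
  empty <- tibble(sample_id = character(), contig_id = character(),
                  itr1_id = character(), itr1_start = integer(),
                  itr1_end = integer(), itr1_sequence = character(),
                  itr2_id = character(), itr2_start = integer(),
                  itr2_end = integer(), itr2_sequence = character(),
                  span = integer())
  if (nrow(candidates) < 2) return(empty)
  lhs <- candidates |>
    select(itr1_id = "candidate_id", "sample_id", "contig_id",
           itr1_start = "start", itr1_end = "end", itr1_sequence = "sequence")
  rhs <- candidates |>
    select(itr2_id = "candidate_id", "sample_id", "contig_id",
           itr2_start = "start", itr2_end = "end", itr2_sequence = "sequence")
  inner_join(lhs, rhs, by = c("sample_id", "contig_id"),
             relationship = "many-to-many") |>
    filter(.data$itr1_start < .data$itr2_start) |>
    mutate(span = .data$itr2_end - .data$itr1_start) |>
    filter(.data$span >= min_is_length, .data$span <= max_is_length) |>
    select("sample_id", "contig_id", "itr1_id", "itr1_start", "itr1_end",
           "itr1_sequence", "itr2_id", "itr2_start", "itr2_end",
           "itr2_sequence", "span") |>
    arrange(.data$sample_id, .data$contig_id, .data$itr1_start,
            .data$itr2_start)
}
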