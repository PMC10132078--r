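# Validating candidate ITR pairs and building named IS records: a pair is
# an IS iff both ITRs fall in the same cluster, have lengths within the ITR
# window, span an IS-sized interval, and are reverse complements of each
# other (checked by local alignment against the reverse complement).

#' Validate candidate ITR pairs
#'
#' A pair passes iff (1) both candidates belong to the same cluster,
#' (2) both ITR lengths are within `[min_itr_length, max_itr_length]`,
#' (3) the span is within `[min_is_length, max_is_length]` (already
#' enforced by [pair_candidates()] but re-checked), and (4) the two
#' sequences are reverse complements of each other: a local alignment of
#' the first ITR against the reverse complement of the second (blastn-style
#' scoring, reward +2 / penalty -3 / gap open 5 / gap extend 2) yields at
#' least `min_itr_length` identical aligned bases.
#'
#' @param pairs Pair tibble from [pair_candidates()].
#' @param clusters Cluster assignment from [cluster_greedy()] run on the
#'   candidate pool (`id` = `candidate_id`).
#' @param params A [mem_params()] object supplying the ITR length window.
#' @param min_is_length,max_is_length IS length window in nt.
#' @return The pair tibble with logical columns `same_cluster`,
#'   `itr_len_ok`, `span_ok`, `revcomp_identities`, `revcomp_ok`, `valid`.
#' @export
validate_itr_pairs <- function(pairs, clusters, params = mem_params(),
                               min_is_length = 500L, max_is_length = 3000L) {
  if (nrow(pairs) == 0) {
    return(mutate(pairs, same_cluster = logical(), itr_len_ok = logical(),
                  span_ok = logical(), revcomp_identities = integer(),
                  revcomp_ok = logical(), valid = logical()))
  }
  cl <- clusters$cluster_id[match(pairs$itr1_id, clusters$id)]
  c2 <- clusters$cluster_id[match(pairs$itr2_id, clusters$id)]
  if (anyNA(cl) || anyNA(c2)) {
    abort("candidate missing from the clustering result",
          class = c("itrseek_error_internal", "itrseek_error"))
  }
  len1 <- pairs$itr1_end - pairs$itr1_start
  len2 <- pairs$itr2_end - pairs$itr2_start
  ident <- purrr::map2_int(pairs$itr1_sequence, pairs$itr2_sequence,
                           revcomp_identities)
  pairs |>
    mutate(
      same_cluster = cl == c2,
      itr_len_ok = len1 >= params$min_itr_length &
        len1 <= params$max_itr_length &
        len2 >= params$min_itr_length & len2 <= params$max_itr_length,
      span_ok = .data$span >= min_is_length & .data$span <= max_is_length,
      revcomp_identities = ident,
      revcomp_ok = ident >= params$min_itr_length,
      valid = .data$same_cluster & .data$itr_len_ok & .data$span_ok &
        .data$revcomp_ok
    )
}

# identical aligned bases in the best plus/minus local alignment
revcomp_identities <- function(seq1, seq2) {
  aln <- Biostrings::pairwiseAlignment(
    seq1, revcomp(seq2), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2)
  as.integer(Biostrings::nmatch(aln))
}

#' Build IS records from validated pairs
#'
#' One record per validated pair; the IS sequence is the contig slice from
#' the start of the first ITR through the end of the second, inclusive.
#' Records duplicated at the same contig coordinates collapse to one.
#' Coordinates in the result are 1-based inclusive.
#'
#' @param pairs Validated pair tibble from [validate_itr_pairs()]; only
#'   rows with `valid == TRUE` are used.
#' @param contigs Contig tibble from [read_assembly()].
#' @return An IS record tibble: `is_id`, `sample_id`, `contig_id`,
#'   `itr1_start`, `itr1_end`, `itr2_start`, `itr2_end` (1-based
#'   inclusive), `length`, `sequence`.
#' @export
call_insertion_sequences <- function(pairs, contigs) {
  empty <- tibble(is_id = character(), sample_id = character(),
                  contig_id = character(), itr1_start = integer(),
                  itr1_end = integer(), itr2_start = integer(),
                  itr2_end = integer(), length = integer(),
                  sequence = character())
  ok <- pairs[isTRUE_v(pairs$valid), , drop = FALSE]
  if (nrow(ok) == 0) return(empty)
  contig_seq <- contigs$sequence[match(paste(ok$sample_id, ok$contig_id),
                                       paste(contigs$sample_id,
                                             contigs$contig_id))]
  ok |>
    mutate(sequence = substr(contig_seq, .data$itr1_start + 1L,
                             .data$itr2_end),
           length = .data$itr2_end - .data$itr1_start) |>
    transmute(
      sample_id = .data$sample_id, contig_id = .data$contig_id,
      itr1_start = .data$itr1_start + 1L, itr1_end = .data$itr1_end,
      itr2_start = .data$itr2_start + 1L, itr2_end = .data$itr2_end,
      length = .data$length, sequence = .data$sequence
    ) |>
    distinct(.data$sample_id, .data$contig_id, .data$itr1_start,
             .data$itr2_end, .keep_all = TRUE) |>
    mutate(is_id = paste0(.data$sample_id, "|", .data$contig_id, "|",
                          .data$itr1_start, "-", .data$itr2_end)) |>
    relocate("is_id")
}

isTRUE_v <- function(x) !is.na(x) & x

#' Compose an IS name from its length and protein hits
#'
#' The name is `IS_length_<len>` followed by one `-<accession>_<start>_<end>`
#' segment per protein hit, in the (deterministic) order the annotation
#' source reported them, deduplicated; with no hits the name is just
#' `IS_length_<len>`.
#'
#' @param length IS length in nt.
#' @param hits Data frame with columns `accession`, `nt_start`, `nt_end`
#'   (1-based nucleotide coordinates on the IS), or NULL / zero rows.
#' @return A single name string.
#' @export
#' @examples
#' name_is(1391, data.frame(accession = "IPR001207",
#'                          nt_start = 495, nt_end = 804))
name_is <- function(length, hits = NULL) {
  base <- paste0("IS_length_", length)
  if (is.null(hits) || nrow(hits) == 0) return(base)
  hits <- distinct(as_tibble(hits), .data$accession, .data$nt_start,
                   .data$nt_end)
  paste0(base, paste0("-", hits$accession, "_", hits$nt_start, "_",
                      hits$nt_end, collapse = ""))
}

#' Attach names and descriptions to annotated IS records
#'
#' @param records IS record tibble carrying a `protein_hits` list-column
#'   (as produced by [annotate_is()]).
#' @return The records with `name` and `description` columns; duplicate
#'   names on distinct loci are disambiguated downstream by provenance
#'   columns, not by the name.
#' @export
finalize_is_records <- function(records) {
  if (nrow(records) == 0) {
    return(mutate(records, name = character(), description = character()))
  }
  hits <- if ("protein_hits" %in% names(records)) records$protein_hits else
    rep(list(NULL), nrow(records))
  records |>
    mutate(
      name = purrr::map2_chr(.data$length, hits, name_is),
      description = purrr::map_chr(hits, function(h) {
        if (is.null(h) || nrow(h) == 0) return(NA_character_)
        paste(unique(h$description), collapse = ";")
      })
    ) |>
    relocate("name")
}
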