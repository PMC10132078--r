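# Greedy incremental identity clustering of nucleotide sequences with
# CD-HIT-EST-style parameter semantics: identity threshold c, global/local
# alignment switch G, coverage constraints aL / aS, minimal alignment
# length A. Both strands are compared by default, as is conventional for
# nucleotide clustering, which is what lets the two reverse-complementary
# ITRs of one element fall in the same cluster.

#' Clustering parameters
#'
#' @param identity Sequence identity threshold c in (0, 1] (ITR stage
#'   default 0.9; catalogue dereplication uses 0.95).
#' @param global Use global alignment (`G = 1`) instead of local
#'   (`G = 0`, the default for the ITR stage).
#' @param cov_long Minimum alignment coverage of the longer sequence aL
#'   (default 0).
#' @param cov_short Minimum alignment coverage of the shorter sequence aS
#'   (default 0.9).
#' @param min_aln Minimal alignment length A in nt for both sequences
#'   (default 0).
#' @param both_strands Also try the reverse complement of the incoming
#'   sequence and keep the better alignment (default TRUE).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring (defaults
#'   +2 / -2 / 4 / 1, penalties positive).
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(identity = 0.9, global = FALSE, cov_long = 0,
                           cov_short = 0.9, min_aln = 0L,
                           both_strands = TRUE, match = 2, mismatch = -2,
                           gap_open = 4, gap_extend = 1) {
  if (identity <= 0 || identity > 1) stop_input("identity must be in (0, 1]")
  if (cov_long < 0 || cov_long > 1 || cov_short < 0 || cov_short > 1) {
    stop_input("coverages must be in [0, 1]")
  }
  p <- list(identity = identity, global = isTRUE(global),
            cov_long = cov_long, cov_short = cov_short,
            min_aln = as.integer(min_aln), both_strands = isTRUE(both_strands),
            match = match, mismatch = mismatch, gap_open = gap_open,
            gap_extend = gap_extend)
  class(p) <- "cluster_params"
  p
}

pa_type <- function(params) if (params$global) "global" else "local"

sub_matrix <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch,
                                           baseOnly = TRUE)
}

#' Pairwise identity and coverage statistics
#'
#' Aligns two sequences (locally for `G = 0`, globally for `G = 1`) with
#' the scoring in `params` and reports identity (identical bases over
#' alignment length including gaps), coverage of the longer and shorter
#' sequence by the alignment span, and the alignment length.
#'
#' @param seq_a,seq_b DNA strings (vectorised over `seq_a`).
#' @param params A [cluster_params()] object.
#' @return A tibble with columns `identity`, `cov_long`, `cov_short`,
#'   `aln_len`, `n_match`.
#' @export
align_stats <- function(seq_a, seq_b, params = cluster_params()) {
  stopifnot(length(seq_b) == 1, nchar(seq_b) > 0, all(nchar(seq_a) > 0))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seq_a), seq_b, type = pa_type(params),
    substitutionMatrix = sub_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ind <- Biostrings::nindel(aln)
  ins_w <- unname(Biostrings::insertion(ind)[, 2L])
  del_w <- unname(Biostrings::deletion(ind)[, 2L])
  aln_len <- nm + nmm + ins_w + del_w
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  span_a <- BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L
  span_b <- BiocGenerics::end(sub) - BiocGenerics::start(sub) + 1L
  la <- nchar(seq_a)
  lb <- nchar(seq_b)
  cov_a <- span_a / la
  cov_b <- span_b / lb
  tibble(
    identity = if_else(aln_len > 0, nm / aln_len, 0),
    cov_long = if_else(la >= lb, cov_a, cov_b),
    cov_short = if_else(la < lb, cov_a, cov_b),
    aln_len = as.integer(aln_len),
    n_match = as.integer(nm)
  )
}

admits <- function(st, params) {
  st$identity >= params$identity & st$cov_short >= params$cov_short &
    st$cov_long >= params$cov_long & st$aln_len >= params$min_aln
}

# best admissible alignment over the allowed strands: a strand that passes
# the admission predicate wins over one that does not; ties resolved by
# identity, then alignment length
admission_stats <- function(seqs, rep_seq, params) {
  st <- align_stats(seqs, rep_seq, params)
  st$strand <- "+"
  if (params$both_strands) {
    st_rc <- align_stats(revcomp(seqs), rep_seq, params)
    ok_f <- admits(st, params)
    ok_r <- admits(st_rc, params)
    better <- (ok_r & !ok_f) |
      (ok_r == ok_f & (st_rc$identity > st$identity |
                         (st_rc$identity == st$identity &
                            st_rc$aln_len > st$aln_len)))
    st[better, ] <- mutate(st_rc[better, ], strand = "-")
  }
  st
}

#' Greedy incremental clustering
#'
#' Sequences are sorted by length descending (ties: lexicographic, then
#' input order) and processed in order: each sequence joins the first
#' existing cluster whose representative it matches at
#' `identity >= c`, `cov_short >= aS`, `cov_long >= aL` and
#' `aln_len >= A`, otherwise it founds a new cluster with itself as
#' representative. Cluster IDs are assigned in foundation order, so the
#' result is fully deterministic given the input.
#'
#' @param sequences Character vector of DNA sequences, or a data frame
#'   with columns `id` and `sequence`.
#' @param params A [cluster_params()] object.
#' @return A tibble with one row per input sequence: `id`, `sequence`,
#'   `cluster_id`, `representative_id`, `is_representative`, `identity`,
#'   `cov_short`, `cov_long`, `aln_len`, `strand` (alignment strand
#'   against the representative).
#' @export
cluster_greedy <- function(sequences, params = cluster_params()) {
  if (is.character(sequences)) {
    sequences <- tibble(id = paste0("seq", seq_along(sequences)),
                        sequence = sequences)
  }
  stopifnot(all(c("id", "sequence") %in% names(sequences)))
  x <- as_tibble(sequences) |>
    mutate(.input_order = row_number()) |>
    arrange(dplyr::desc(nchar(.data$sequence)), .data$sequence,
            .data$.input_order)
  n <- nrow(x)
  out <- x |>
    mutate(cluster_id = NA_integer_, representative_id = NA_character_,
           is_representative = FALSE, identity = NA_real_,
           cov_short = NA_real_, cov_long = NA_real_,
           aln_len = NA_integer_, strand = NA_character_)
  rep_idx <- integer(0) # row indices (in x) of representatives
  for (i in seq_len(n)) {
    joined <- FALSE
    for (ci in seq_along(rep_idx)) {
      r <- rep_idx[ci]
      st <- admission_stats(x$sequence[i], x$sequence[r], params)
      if (admits(st, params)) {
        out$cluster_id[i] <- ci
        out$representative_id[i] <- x$id[r]
        out$identity[i] <- st$identity
        out$cov_short[i] <- st$cov_short
        out$cov_long[i] <- st$cov_long
        out$aln_len[i] <- st$aln_len
        out$strand[i] <- st$strand
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      rep_idx <- c(rep_idx, i)
      ci <- length(rep_idx)
      out$cluster_id[i] <- ci
      out$representative_id[i] <- x$id[i]
      out$is_representative[i] <- TRUE
      out$identity[i] <- 1
      out$cov_short[i] <- 1
      out$cov_long[i] <- 1
      out$aln_len[i] <- nchar(x$sequence[i])
      out$strand[i] <- "+"
    }
  }
  out |>
    arrange(.data$.input_order) |>
    select(-".input_order")
}

#' Write a .clstr-style cluster report
#'
#' @param clusters Output of [cluster_greedy()].
#' @param path Output text file.
#' @return Invisibly, `path`.
#' @export
write_cluster_report <- function(clusters, path) {
  lines <- character(0)
  for (cid in sort(unique(clusters$cluster_id))) {
    lines <- c(lines, paste0(">Cluster ", cid - 1L))
    mem <- clusters[clusters$cluster_id == cid, ]
    mem <- mem[order(!mem$is_representative, mem$id), ]
    lines <- c(lines, sprintf(
      "%d\t%dnt, >%s... %s", seq_len(nrow(mem)) - 1L, nchar(mem$sequence),
      mem$id,
      if_else(mem$is_representative, "*",
              sprintf("at %s/%.2f%%", mem$strand, 100 * mem$identity))))
  }
  writeLines(lines, path)
  invisible(path)
}
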