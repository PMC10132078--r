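# Sparse-sampled maximal-exact-match search between reads: reference k-mer
# table with stride (L - k) + 1, query scan shifting one base at a time,
# interval-halving extension, ITR length window, end-buffer rule against
# technical repeats, one repeat per query read.

#' MEM search parameters
#'
#' The sparse-index stride is `(min_itr_length - kmer_length) + 1`, which
#' guarantees that every window of at least `min_itr_length` bases contains
#' at least one indexed k-mer start, so no repeat at or above the minimum
#' ITR length can be missed.
#'
#' @param min_itr_length Minimum ITR length L in nt (default 25).
#' @param max_itr_length Maximum ITR length in nt (default 50).
#' @param kmer_length k-mer length used for seeding (default 15).
#' @param end_buffer Matches starting or ending within this many nt of a
#'   read end are discarded as likely technical (duplicate-read) repeats
#'   (default 20).
#' @return A list of class `mem_params` with the derived `stride`.
#' @export
#' @examples
#' mem_params()$stride # (25 - 15) + 1 = 11
mem_params <- function(min_itr_length = 25L, max_itr_length = 50L,
                       kmer_length = 15L, end_buffer = 20L) {
  min_itr_length <- as.integer(min_itr_length)
  max_itr_length <- as.integer(max_itr_length)
  kmer_length <- as.integer(kmer_length)
  end_buffer <- as.integer(end_buffer)
  if (kmer_length < 1 || kmer_length > 31) {
    stop_input("kmer_length must be in 1..31")
  }
  if (kmer_length > min_itr_length || min_itr_length > max_itr_length) {
    stop_input("need kmer_length <= min_itr_length <= max_itr_length")
  }
  if (end_buffer < 0) stop_input("end_buffer must be >= 0")
  p <- list(min_itr_length = min_itr_length, max_itr_length = max_itr_length,
            kmer_length = kmer_length, end_buffer = end_buffer,
            stride = (min_itr_length - kmer_length) + 1L)
  class(p) <- "mem_params"
  p
}

#' Sparse k-mer index positions
#'
#' A k-mer starting at within-read position `p` (0-based) is indexed iff
#' `p %% stride == 0` and the k-mer lies fully inside the read; windows
#' overlapping spacer blocks are never indexed.
#'
#' @param store A [two_bit_store()].
#' @param params A [mem_params()] object.
#' @return A tibble with `read_ordinal`, `position` (0-based within read),
#'   `offset` (store code offset) and the `kmer` string.
#' @export
build_sparse_index <- function(store, params = mem_params()) {
  stopifnot(inherits(store, "two_bit_store"), inherits(params, "mem_params"))
  idx <- as_tibble(cpp_index_positions(store$boundaries$start_offset,
                                       store$boundaries$end_offset,
                                       params$kmer_length, params$stride))
  if (nrow(idx) == 0) return(mutate(idx, kmer = character()))
  idx$kmer <- cpp_decode_span(store$packed, idx$offset,
                              idx$offset + params$kmer_length,
                              store$total_codes)
  idx
}

#' Extend a seed match to the maximal exact match containing it
#'
#' The matching k-length blocks at `(read_a, pos_a)` and `(read_b, pos_b)`
#' are extended in both directions using interval halving (try the full
#' remaining extension; on mismatch halve until a matching block is found;
#' then elongate one base at a time) until no further exact extension is
#' possible without leaving either read. The result is the unique maximal
#' exact match containing the seed.
#'
#' @param store A [two_bit_store()].
#' @param read_a,pos_a,read_b,pos_b Seed coordinates (ordinals 1-based,
#'   positions 0-based within the read).
#' @param k Seed length.
#' @return A one-row tibble with `read_a`, `start_a`, `read_b`, `start_b`,
#'   `length` (0-based start positions).
#' @export
extend_seed <- function(store, read_a, pos_a, read_b, pos_b, k) {
  res <- cpp_extend_seed(store$packed, store$boundaries$start_offset,
                         store$boundaries$end_offset,
                         as.integer(read_a), as.integer(pos_a),
                         as.integer(read_b), as.integer(pos_b), as.integer(k))
  tibble(read_a = as.integer(read_a), start_a = res[["start_a"]],
         read_b = as.integer(read_b), start_b = res[["start_b"]],
         length = res[["length"]])
}

#' Find reads carrying inter-read repeat sequences
#'
#' Scans every query read's k-mer windows left to right against the sparse
#' reference index, extends each hit to its maximal exact match, and
#' accepts a MEM iff (a) its length is within
#' `[min_itr_length, max_itr_length]` and (b) on both participating reads
#' it neither starts within `end_buffer` nt of the read start nor ends
#' within `end_buffer` nt of the read end (prefix/suffix matches typical of
#' duplicated reads are thereby discarded). On the first accepted MEM for a
#' query read, the read and its partner are recorded as repeat reads and
#' the scan advances to the next query read, since a short read is expected
#' to contain at most one ITR.
#'
#' @param store A [two_bit_store()].
#' @param params A [mem_params()] object.
#' @return A tibble of repeat reads with columns `read_ordinal`, `read_id`,
#'   `sample_id`, `sequence`, `repeat_start`, `repeat_end` (0-based
#'   half-open on the read) and `repeat_sequence`. The accepted MEM
#'   evidence is attached as attribute `"mems"`.
#' @export
find_repeat_reads <- function(store, params = mem_params()) {
  stopifnot(inherits(store, "two_bit_store"), inherits(params, "mem_params"))
  empty <- tibble(read_ordinal = integer(), read_id = character(),
                  sample_id = character(), sequence = character(),
                  repeat_start = integer(), repeat_end = integer(),
                  repeat_sequence = character())
  if (nrow(store$reads) == 0) {
    attr(empty, "mems") <- tibble(read_a = integer(), start_a = integer(),
                                  read_b = integer(), start_b = integer(),
                                  length = integer())
    return(empty)
  }
  mems <- as_tibble(cpp_find_repeat_reads(
    store$packed, store$boundaries$start_offset, store$boundaries$end_offset,
    params$kmer_length, params$stride, params$min_itr_length,
    params$max_itr_length, params$end_buffer))
  if (nrow(mems) == 0) {
    attr(empty, "mems") <- mems
    return(empty)
  }
  # both sides of each accepted MEM become repeat reads; a read keeps the
  # interval from the first piece of evidence that mentions it
  side_a <- transmute(mems, .ord = 2L * row_number() - 1L,
                      read_ordinal = .data$read_a,
                      repeat_start = .data$start_a,
                      repeat_end = .data$start_a + .data$length)
  side_b <- transmute(mems, .ord = 2L * row_number(),
                      read_ordinal = .data$read_b,
                      repeat_start = .data$start_b,
                      repeat_end = .data$start_b + .data$length)
  rr <- bind_rows(side_a, side_b) |>
    arrange(.data$.ord) |>
    distinct(.data$read_ordinal, .keep_all = TRUE) |>
    select(-".ord") |>
    arrange(.data$read_ordinal)
  keep_cols <- intersect(c("read_ordinal", "read_id", "sample_id", "sequence"),
                         names(store$reads))
  rr <- left_join(rr, store$reads[keep_cols], by = "read_ordinal") |>
    mutate(repeat_sequence = substr(.data$sequence, .data$repeat_start + 1L,
                                    .data$repeat_end)) |>
    relocate(dplyr::any_of(c("read_ordinal", "read_id", "sample_id",
                             "sequence", "repeat_start", "repeat_end",
                             "repeat_sequence")))
  attr(rr, "mems") <- mems
  rr
}
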