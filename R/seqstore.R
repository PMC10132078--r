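# The 2-bit packed, concatenated read store with pseudo-random spacer blocks
# between reads -- the query data structure behind the MEM finder.

SPACER_CODES <- 10L # 10 two-bit codes = 20 bits between consecutive reads

#' Encode DNA bases as 2-bit codes
#'
#' A maps to 0 (binary 00), C to 1 (01), G to 2 (10), T to 3 (11).
#'
#' @param x A single DNA string over A, C, G, T.
#' @return Integer vector of codes in 0..3.
#' @export
#' @examples
#' encode_bases("ACGT")
encode_bases <- function(x) {
  stopifnot(length(x) == 1)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  codes <- c(A = 0L, C = 1L, G = 2L, T = 3L)[chars]
  if (anyNA(codes)) {
    abort(paste0("sequence contains a non-encodable base: ",
                 chars[which(is.na(codes))[1]]),
          class = c("itrseek_error_nonencodable", "itrseek_error"))
  }
  unname(codes)
}

#' Decode 2-bit codes back to DNA bases
#'
#' @param codes Integer vector of codes in 0..3.
#' @return A single DNA string.
#' @export
decode_bases <- function(codes) {
  stopifnot(all(codes %in% 0:3))
  paste(c("A", "C", "G", "T")[codes + 1L], collapse = "")
}

#' Build the 2-bit packed read store
#'
#' Reads are concatenated into one packed 2-bit code array, separated by
#' 20-bit (10-code) pseudo-random spacer blocks drawn from a seeded
#' generator; a boundaries table records every read's span in code units.
#' Reads containing non-ACGT bases or shorter than `min_usable_length` are
#' excluded (and reported in the `excluded` attribute of the store).
#'
#' @param reads Tibble with at least `read_id` and `sequence` columns;
#'   other columns (`sample_id`, `mate`, ...) are carried along.
#' @param min_usable_length Shortest read worth storing; must be at least
#'   the k-mer length used downstream.
#' @param spacer_seed Seed for the spacer pseudo-random codes (default 1).
#' @return An object of class `two_bit_store`.
#' @export
two_bit_store <- function(reads, min_usable_length = 15L, spacer_seed = 1L) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  reads <- as_tibble(reads)
  ok <- is_acgt(reads$sequence) & nchar(reads$sequence) >= min_usable_length
  excluded <- reads[!ok, , drop = FALSE] |>
    mutate(reason = if_else(is_acgt(.data$sequence), "too_short", "non_acgt")) |>
    select(dplyr::any_of(c("read_id", "reason")))
  kept <- reads[ok, , drop = FALSE] |>
    mutate(read_ordinal = row_number(), length = nchar(.data$sequence)) |>
    relocate("read_ordinal")
  n <- nrow(kept)
  if (n == 0) {
    store <- list(packed = raw(0),
                  boundaries = tibble(read_ordinal = integer(),
                                      start_offset = integer(),
                                      end_offset = integer()),
                  reads = kept, excluded = excluded,
                  spacer_code_length = SPACER_CODES,
                  total_codes = 0L, spacer_seed = spacer_seed)
    class(store) <- "two_bit_store"
    return(store)
  }
  spacers <- withr::with_seed(
    spacer_seed,
    sample(0:3, SPACER_CODES * max(n - 1L, 0L), replace = TRUE)
  )
  built <- cpp_build_store(kept$sequence, as.integer(spacers), SPACER_CODES)
  store <- list(
    packed = built$packed,
    boundaries = tibble(read_ordinal = kept$read_ordinal,
                        start_offset = built$start_offset,
                        end_offset = built$end_offset),
    reads = kept,
    excluded = excluded,
    spacer_code_length = SPACER_CODES,
    total_codes = built$total_codes,
    spacer_seed = spacer_seed
  )
  class(store) <- "two_bit_store"
  store
}

#' @export
print.two_bit_store <- function(x, ...) {
  cat("<two_bit_store>: ", nrow(x$reads), " reads, ", x$total_codes,
      " codes (", nrow(x$excluded), " reads excluded)\n", sep = "")
  invisible(x)
}

#' Decode a stored read from the packed store
#'
#' @param store A `two_bit_store`.
#' @param read_ordinal Ordinal(s) of the read(s) to decode.
#' @return Character vector of sequences.
#' @export
decode_read <- function(store, read_ordinal) {
  b <- store$boundaries[match(read_ordinal, store$boundaries$read_ordinal), ]
  if (anyNA(b$start_offset)) stop_input("unknown read ordinal")
  cpp_decode_span(store$packed, b$start_offset, b$end_offset,
                  store$total_codes)
}

#' Map store offsets back to reads
#'
#' Inverts the concatenation map: each code offset lands either inside a
#' stored read (giving the read ordinal and within-read position) or inside
#' a spacer block.
#'
#' @param store A `two_bit_store`.
#' @param offset Integer vector of 0-based code offsets.
#' @return A tibble with columns `offset`, `read_ordinal` (NA in spacers),
#'   `position` (0-based within the read; NA in spacers), `is_spacer`.
#' @export
locate_offset <- function(store, offset) {
  offset <- as.integer(offset)
  if (any(offset < 0 | offset >= store$total_codes)) {
    stop_input("offset out of range", class = "itrseek_error_bounds")
  }
  starts <- store$boundaries$start_offset
  ends <- store$boundaries$end_offset
  idx <- findInterval(offset, starts)
  inside <- idx >= 1 & offset < ends[pmax(idx, 1L)]
  tibble(
    offset = offset,
    read_ordinal = if_else(inside, store$boundaries$read_ordinal[pmax(idx, 1L)],
                           NA_integer_),
    position = if_else(inside, offset - starts[pmax(idx, 1L)], NA_integer_),
    is_spacer = !inside
  )
}
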