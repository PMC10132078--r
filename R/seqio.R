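# Reading and writing the standard formats the pipeline touches: manifest
# TSV, FASTQ(.gz), FASTA, and the final IS FASTA + info TSV.

manifest_columns <- c("lane_id", "fastq1_path", "fastq2_path", "sample_id",
                      "assembly_path")

#' Read a run manifest
#'
#' The manifest is a tab-delimited file with a header row and columns
#' `lane_id`, `fastq1_path`, `fastq2_path`, `sample_id`, `assembly_path`:
#' one row per read set, with each `sample_id` mapping to exactly one
#' assembly FASTA.
#'
#' @param path Path to the manifest TSV.
#' @param check_paths Verify that all referenced files exist (default TRUE).
#' @return A tibble with the five manifest columns.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop_input(paste0("manifest not found: ", path))
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  missing <- setdiff(manifest_columns, names(m))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = c("itrseek_error_config", "itrseek_error"))
  }
  m <- as_tibble(m[manifest_columns])
  if (anyDuplicated(m$lane_id) > 0) {
    stop_input(paste0("duplicate lane_id in manifest: ",
                      paste(unique(m$lane_id[duplicated(m$lane_id)]),
                            collapse = ", ")))
  }
  multi <- m |>
    distinct(.data$sample_id, .data$assembly_path) |>
    dplyr::count(.data$sample_id) |>
    filter(.data$n > 1)
  if (nrow(multi) > 0) {
    stop_input(paste0("sample_id maps to more than one assembly: ",
                      paste(multi$sample_id, collapse = ", ")))
  }
  if (check_paths) {
    paths <- unique(c(m$fastq1_path, m$fastq2_path, m$assembly_path))
    bad <- paths[!file.exists(paths)]
    if (length(bad) > 0) {
      stop_input(paste0("manifest references missing file(s): ",
                        paste(bad, collapse = ", ")))
    }
  }
  m
}

#' Stream reads from a FASTQ file
#'
#' Parses a (possibly gzipped) 4-line-record FASTQ file and assigns ordinal
#' internal IDs `Seq1`, `Seq2`, ... in file order; the original header is
#' retained in `read_id`.
#'
#' @param path FASTQ or FASTQ.gz file.
#' @param mate Mate number (1 or 2) recorded alongside each read.
#' @param sample_id Sample the reads belong to.
#' @return A tibble with columns `seq_id`, `read_id`, `sequence`, `mate`,
#'   `sample_id`.
#' @export
read_fastq_reads <- function(path, mate = 1L, sample_id = NA_character_) {
  if (!file.exists(path)) stop_input(paste0("FASTQ not found: ", path))
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4 != 0) {
    stop_input(sprintf(
      "truncated FASTQ record at record %d in %s",
      length(lines) %/% 4 + 1, path), class = "itrseek_error_parse")
  }
  n <- length(lines) %/% 4
  if (n == 0) {
    return(tibble(seq_id = character(), read_id = character(),
                  sequence = character(), mate = integer(),
                  sample_id = character()))
  }
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(qual) != nchar(seqs))
  if (length(bad) > 0) {
    stop_input(sprintf("malformed FASTQ record %d in %s", bad[1], path),
               class = "itrseek_error_parse")
  }
  tibble(
    seq_id = paste0("Seq", seq_len(n)),
    read_id = stringr::str_remove(sub("^@", "", hdr), "\\s.*$"),
    sequence = seqs,
    mate = as.integer(mate),
    sample_id = as.character(sample_id)
  )
}

#' Read an assembly FASTA into a contig tibble
#'
#' @param path FASTA file of contigs.
#' @param sample_id Sample the assembly belongs to.
#' @return A tibble with columns `contig_id`, `sequence`, `sample_id`,
#'   `length`.
#' @export
read_assembly <- function(path, sample_id = NA_character_) {
  if (!file.exists(path)) stop_input(paste0("assembly not found: ", path))
  ss <- Biostrings::readDNAStringSet(path)
  ids <- stringr::str_remove(names(ss), "\\s.*$")
  if (anyDuplicated(ids) > 0) {
    stop_input(paste0("duplicate contig_id in ", path))
  }
  tibble(contig_id = ids, sequence = toupper(as.character(ss)),
         sample_id = as.character(sample_id),
         length = BiocGenerics::width(ss))
}

#' Write a FASTA file from a tibble
#'
#' @param df Data frame with at least the columns named by `id_col` and
#'   `seq_col`.
#' @param path Output path.
#' @param id_col,seq_col Column names holding the record ID and sequence.
#' @param width Line width for wrapping (default 80).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(df, path, id_col = "name", seq_col = "sequence",
                        width = 80L) {
  ss <- Biostrings::DNAStringSet(df[[seq_col]])
  names(ss) <- df[[id_col]]
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

is_info_columns <- c("name", "sample_id", "contig", "itr1_start_position",
                     "itr1_end_position", "itr2_start_position",
                     "itr2_end_position", "description")

#' Write the final IS FASTA and info TSV
#'
#' FASTA headers equal each record's `name`; the TSV has the columns
#' `name`, `sample_id`, `contig`, `itr1_start_position`,
#' `itr1_end_position`, `itr2_start_position`, `itr2_end_position`,
#' `description`, with 1-based inclusive ITR coordinates on the contig.
#'
#' @param records IS record tibble as produced by [finalize_is_records()].
#' @param fasta_path,tsv_path Output file paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_is_outputs <- function(records, fasta_path, tsv_path) {
  info <- tibble(
    name = character(), sample_id = character(), contig = character(),
    itr1_start_position = integer(), itr1_end_position = integer(),
    itr2_start_position = integer(), itr2_end_position = integer(),
    description = character()
  )
  if (nrow(records) > 0) {
    info <- records |>
      transmute(name = .data$name, sample_id = .data$sample_id,
                contig = .data$contig_id,
                itr1_start_position = .data$itr1_start,
                itr1_end_position = .data$itr1_end,
                itr2_start_position = .data$itr2_start,
                itr2_end_position = .data$itr2_end,
                description = .data$description)
  }
  readr::write_tsv(info, tsv_path, progress = FALSE)
  if (nrow(records) > 0) {
    write_fasta(records, fasta_path)
  } else {
    file.create(fasta_path)
  }
  invisible(list(fasta = fasta_path, tsv = tsv_path))
}

#' Re-read an IS info TSV written by [write_is_outputs()]
#'
#' @param tsv_path Path to the info TSV.
#' @return A tibble with the output schema.
#' @export
read_is_info <- function(tsv_path) {
  readr::read_tsv(tsv_path, col_types = readr::cols(
    name = "c", sample_id = "c", contig = "c",
    itr1_start_position = "i", itr1_end_position = "i",
    itr2_start_position = "i", itr2_end_position = "i",
    description = "c"), progress = FALSE)
}
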