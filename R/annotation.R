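# Transposase evidence for candidate ISs: six-frame ORF extraction, an
# ingestion port for InterProScan-format TSVs, a bundled keyword-table
# annotator for offline runs, and the description-keyword filter.

#' Extract stop-to-stop open reading frames in all six frames
#'
#' Maximal stop-to-stop segments of at least `min_aa` residues are
#' reported for all six frames (bacterial code; stop codons TAA, TAG, TGA;
#' a start codon is not required). Nucleotide coordinates are mapped back
#' to the forward strand, 1-based inclusive, excluding the stop codon.
#'
#' @param sequence A DNA string.
#' @param min_aa Minimum ORF length in amino acids (default 30).
#' @return A tibble with `frame` (+1,+2,+3,-1,-2,-3), `aa_sequence`,
#'   `nt_start`, `nt_end`.
#' @export
#' @examples
#' extract_orfs("ATGAAATAA", min_aa = 2)
extract_orfs <- function(sequence, min_aa = 30L) {
  stopifnot(length(sequence) == 1)
  L <- nchar(sequence)
  out <- list()
  scan_strand <- function(seq, sign) {
    for (off in 0:2) {
      n_cod <- (nchar(seq) - off) %/% 3
      if (n_cod < 1) next
      sub <- substr(seq, off + 1L, off + 3L * n_cod)
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), no.init.codon = TRUE))
      # maximal stop-to-stop segments
      segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
      pos <- 1L
      for (s in segs) {
        len <- nchar(s)
        if (len >= min_aa) {
          a0 <- pos
          a1 <- pos + len - 1L
          nt_start_local <- off + (a0 - 1L) * 3L + 1L
          nt_end_local <- off + a1 * 3L
          if (sign > 0) {
            nt_start <- nt_start_local
            nt_end <- nt_end_local
          } else {
            nt_start <- L - nt_end_local + 1L
            nt_end <- L - nt_start_local + 1L
          }
          out[[length(out) + 1L]] <<- tibble(
            frame = sign * (off + 1L), aa_sequence = s,
            nt_start = nt_start, nt_end = nt_end)
        }
        pos <- pos + len + 1L
      }
    }
  }
  scan_strand(sequence, 1L)
  scan_strand(revcomp(sequence), -1L)
  if (length(out) == 0) {
    return(tibble(frame = integer(), aa_sequence = character(),
                  nt_start = integer(), nt_end = integer()))
  }
  bind_rows(out) |> arrange(.data$nt_start, .data$frame)
}

# ORF registry across a set of IS records: one row per ORF with a stable id
orf_registry <- function(records, min_aa = 30L) {
  if (nrow(records) == 0) {
    return(tibble(orf_id = character(), is_id = character(),
                  frame = integer(), aa_sequence = character(),
                  nt_start = integer(), nt_end = integer()))
  }
  purrr::map2_dfr(records$is_id, records$sequence, function(id, seq) {
    orfs <- extract_orfs(seq, min_aa = min_aa)
    if (nrow(orfs) == 0) return(NULL)
    orfs |> mutate(is_id = id,
                   orf_id = paste0(id, "_orf", row_number())) |>
      relocate("orf_id", "is_id")
  })
}

#' Export ORFs of IS records as a protein FASTA
#'
#' Writes the amino-acid sequences of all six-frame ORFs, with headers
#' equal to the registry `orf_id`, for annotation by an external protein
#' family scanner whose TSV output can then be ingested with
#' [parse_interproscan()].
#'
#' @param records IS record tibble from [call_insertion_sequences()].
#' @param path Output FASTA path.
#' @param min_aa Minimum ORF length in amino acids.
#' @return Invisibly, the ORF registry tibble.
#' @export
export_orf_fasta <- function(records, path, min_aa = 30L) {
  reg <- orf_registry(records, min_aa = min_aa)
  ss <- Biostrings::AAStringSet(reg$aa_sequence)
  names(ss) <- reg$orf_id
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(reg)
}

#' Parse an InterProScan-format TSV of protein-domain hits
#'
#' Expects the tab-separated InterProScan dialect (query accession, MD5,
#' length, analysis, signature accession, signature description, start,
#' stop, score, status, date, InterPro accession, InterPro description,
#' ...). The InterPro accession and description are preferred; rows
#' without one fall back to the member-database signature (e.g. PANTHER)
#' accession and description. Amino-acid coordinates are converted to
#' nucleotide coordinates on the IS through the ORF registry.
#'
#' @param path TSV file (no header row).
#' @param orfs ORF registry from [export_orf_fasta()] (or
#'   `itrseek:::orf_registry()`), with `orf_id`, `is_id`, `frame`,
#'   `nt_start`, `nt_end`.
#' @return A tibble of protein hits: `is_id`, `accession`, `description`,
#'   `nt_start`, `nt_end` (1-based on the IS), `source_frame`.
#' @export
parse_interproscan <- function(path, orfs) {
  empty <- tibble(is_id = character(), accession = character(),
                  description = character(), nt_start = integer(),
                  nt_end = integer(), source_frame = integer())
  if (!file.exists(path)) stop_input(paste0("annotation TSV not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty)
  f <- stringr::str_split(lines, "\t")
  out <- list()
  for (i in seq_along(f)) {
    row <- f[[i]]
    if (length(row) < 8) {
      warn(sprintf("skipping malformed annotation row %d (%d columns)",
                   i, length(row)))
      next
    }
    query <- row[1]
    sig_acc <- row[5]
    sig_desc <- row[6]
    aa_start <- suppressWarnings(as.integer(row[7]))
    aa_end <- suppressWarnings(as.integer(row[8]))
    ipr_acc <- if (length(row) >= 12) row[12] else ""
    ipr_desc <- if (length(row) >= 13) row[13] else ""
    if (is.na(aa_start) || is.na(aa_end) || aa_start < 1 ||
        aa_end < aa_start) {
      warn(sprintf("skipping annotation row %d with bad coordinates", i))
      next
    }
    if (grepl("^IPR", ipr_acc)) {
      acc <- ipr_acc
      desc <- ipr_desc
    } else if (nzchar(sig_acc) && sig_acc != "-") {
      acc <- sig_acc
      desc <- sig_desc
    } else {
      warn(sprintf("skipping annotation row %d without an accession", i))
      next
    }
    reg <- orfs[orfs$orf_id == query, , drop = FALSE]
    if (nrow(reg) == 0) {
      stop_input(paste0("annotation refers to unknown query ID: ", query))
    }
    nt <- aa_to_nt(reg$frame[1], reg$nt_start[1], reg$nt_end[1],
                   aa_start, aa_end)
    out[[length(out) + 1L]] <- tibble(
      is_id = reg$is_id[1], accession = acc, description = desc,
      nt_start = nt$start, nt_end = nt$end, source_frame = reg$frame[1])
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

# amino-acid coordinates within an ORF -> forward-strand nucleotide
# coordinates on the IS (1-based inclusive, exact codon span)
aa_to_nt <- function(frame, orf_nt_start, orf_nt_end, aa_start, aa_end) {
  if (frame > 0) {
    list(start = orf_nt_start + (aa_start - 1L) * 3L,
         end = orf_nt_start + aa_end * 3L - 1L)
  } else {
    list(start = orf_nt_end - aa_end * 3L + 1L,
         end = orf_nt_end - (aa_start - 1L) * 3L)
  }
}

# -- mock annotator -----------------------------------------------------------

# deterministic reverse translation for building marker ORFs
AA_CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

MARKER_MOTIF <- "DDENHKRAGTW"
MARKER_PEPTIDE <- paste0("MSKLEQVRTY", "AGWIDPLNHE", MARKER_MOTIF,
                         "QFSVCMYKLR", "TGANPDWHIE", "VLSKRQ")

#' The built-in transposase marker ORF
#'
#' A fixed 57-residue open reading frame (start codon through stop codon)
#' that the default mock annotator recognizes through the motif
#' `DDENHKRAGTW`. The synthetic-data generator embeds it in planted IS
#' bodies so that offline runs exercise the annotation filter.
#'
#' @return A list with `nt` (the 174-nt coding sequence including the stop
#'   codon) and `peptide`.
#' @export
marker_orf <- function() {
  aa <- strsplit(MARKER_PEPTIDE, "")[[1]]
  nt <- paste0(paste(AA_CODON[aa], collapse = ""), "TAA")
  list(nt = nt, peptide = MARKER_PEPTIDE)
}

#' Default mock-annotator keyword table
#'
#' @return A tibble with `pattern` (amino-acid motif regex), `accession`
#'   and `description`; the default single row flags the built-in marker
#'   ORF as a transposase.
#' @export
mock_keyword_table <- function() {
  tibble(pattern = MARKER_MOTIF, accession = "IPR990001",
         description = "Transposase, synthetic marker")
}

#' Read a mock-annotator keyword table from TSV
#'
#' Columns `pattern` and `description` are required; `accession` is
#' optional and synthesized (`MOCK0001`, ...) when absent.
#'
#' @param path TSV file with a header row.
#' @return A keyword tibble as in [mock_keyword_table()].
#' @export
read_keyword_table <- function(path) {
  k <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!all(c("pattern", "description") %in% names(k))) {
    stop_input("keyword table needs 'pattern' and 'description' columns")
  }
  if (!"accession" %in% names(k)) {
    k$accession <- sprintf("MOCK%04d", seq_len(nrow(k)))
  }
  as_tibble(k[c("pattern", "accession", "description")])
}

# scan ORFs for keyword motifs; hit coordinates cover the matched motif
mock_hits <- function(orfs, keywords) {
  empty <- tibble(is_id = character(), accession = character(),
                  description = character(), nt_start = integer(),
                  nt_end = integer(), source_frame = integer())
  if (nrow(orfs) == 0 || nrow(keywords) == 0) return(empty)
  out <- list()
  for (ki in seq_len(nrow(keywords))) {
    loc <- stringr::str_locate_all(orfs$aa_sequence, keywords$pattern[ki])
    for (oi in seq_along(loc)) {
      m <- loc[[oi]]
      if (nrow(m) == 0) next
      for (r in seq_len(nrow(m))) {
        nt <- aa_to_nt(orfs$frame[oi], orfs$nt_start[oi], orfs$nt_end[oi],
                       m[r, 1], m[r, 2])
        out[[length(out) + 1L]] <- tibble(
          is_id = orfs$is_id[oi], accession = keywords$accession[ki],
          description = keywords$description[ki], nt_start = nt$start,
          nt_end = nt$end, source_frame = orfs$frame[oi])
      }
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

#' Annotate IS records with protein-family hits
#'
#' Attaches a `protein_hits` list-column to each record. Three annotation
#' sources are supported: `"none"` (empty hits), a mock annotator driven
#' by an amino-acid keyword table (offline runs and tests), or ingestion
#' of an InterProScan-format TSV produced externally on the ORF FASTA from
#' [export_orf_fasta()].
#'
#' @param records IS record tibble from [call_insertion_sequences()].
#' @param annotation `"none"`, `"mock"`, a keyword tibble, or
#'   `list(type = "interproscan", path = <tsv>)`.
#' @param min_aa Minimum ORF length in amino acids for the six-frame scan.
#' @return The records with a `protein_hits` list-column (tibbles with
#'   `accession`, `description`, `nt_start`, `nt_end`, `source_frame`).
#' @export
annotate_is <- function(records, annotation = "mock", min_aa = 30L) {
  if (nrow(records) == 0) {
    return(mutate(records, protein_hits = list()))
  }
  hits <- NULL
  if (identical(annotation, "none")) {
    hits <- mock_hits(orf_registry(records[0, ], min_aa), mock_keyword_table())
  } else if (identical(annotation, "mock") || is.data.frame(annotation)) {
    kw <- if (is.data.frame(annotation)) as_tibble(annotation) else
      mock_keyword_table()
    hits <- mock_hits(orf_registry(records, min_aa), kw)
  } else if (is.list(annotation) &&
             identical(annotation$type, "interproscan")) {
    reg <- orf_registry(records, min_aa)
    hits <- parse_interproscan(annotation$path, reg)
  } else {
    stop_input("unknown annotation source")
  }
  hit_cols <- c("accession", "description", "nt_start", "nt_end",
                "source_frame")
  records |>
    mutate(protein_hits = purrr::map(.data$is_id, function(id) {
      h <- hits[hits$is_id == id, hit_cols, drop = FALSE]
      as_tibble(h)
    }))
}

TRANSPOSASE_KEYWORDS <- c("transposase", "integrase-like", "ribonuclease h")

#' Keep only records with transposase-like protein evidence
#'
#' A record is kept iff at least one of its protein-hit descriptions
#' contains "Transposase", "Integrase-like" or "Ribonuclease H"
#' (case-insensitive substring match). The filter is idempotent and
#' order-independent.
#'
#' @param records Annotated IS record tibble from [annotate_is()].
#' @return The filtered records; dropped records are reported in attribute
#'   `"dropped"`.
#' @export
filter_transposase <- function(records) {
  if (nrow(records) == 0) {
    attr(records, "dropped") <- records
    return(records)
  }
  keep <- purrr::map_lgl(records$protein_hits, function(h) {
    if (is.null(h) || nrow(h) == 0) return(FALSE)
    any(stringr::str_detect(
      stringr::str_to_lower(h$description),
      stringr::fixed(TRANSPOSASE_KEYWORDS[1])) |
        stringr::str_detect(stringr::str_to_lower(h$description),
                            stringr::fixed(TRANSPOSASE_KEYWORDS[2])) |
        stringr::str_detect(stringr::str_to_lower(h$description),
                            stringr::fixed(TRANSPOSASE_KEYWORDS[3])))
  })
  out <- records[keep, , drop = FALSE]
  attr(out, "dropped") <- records[!keep, , drop = FALSE]
  out
}
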