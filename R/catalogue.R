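# Dereplication of ISs pooled across runs into a non-redundant catalogue,
# plus summaries. Dereplication clusters full IS sequences at a 0.95
# global-identity threshold with no coverage constraints (the nucleotide
# clustering defaults), keeping the longest member of each cluster as its
# representative.

#' Dereplicate IS records into a catalogue
#'
#' @param records Pooled, finalized IS record tibble (needs `name`,
#'   `sequence`, `sample_id`; typically rows from one or more runs of
#'   [discover_insertion_sequences()]).
#' @param identity Identity threshold (default 0.95).
#' @return An object of class `is_catalogue`: a list with
#'   `representatives` (one row per cluster representative),
#'   `membership` (`representative_name`, `member_name`, `sample_id`,
#'   `identity_to_representative`) and `params`.
#' @export
dereplicate_catalogue <- function(records, identity = 0.95) {
  params <- cluster_params(identity = identity, global = TRUE,
                           cov_long = 0, cov_short = 0, min_aln = 0L)
  if (nrow(records) == 0) {
    out <- list(representatives = records,
                membership = tibble(representative_name = character(),
                                    member_name = character(),
                                    sample_id = character(),
                                    identity_to_representative = double()),
                params = params)
    class(out) <- "is_catalogue"
    return(out)
  }
  stopifnot(all(c("name", "sequence") %in% names(records)))
  records <- records |> mutate(.member = paste0("m", row_number()))
  cl <- cluster_greedy(
    records |> select(id = ".member", "sequence"), params)
  membership <- cl |>
    left_join(records |> select(".member", "name",
                                dplyr::any_of("sample_id")),
              by = c(id = ".member")) |>
    left_join(records |> select(".member", rep_name = "name"),
              by = c(representative_id = ".member")) |>
    transmute(representative_name = .data$rep_name,
              member_name = .data$name,
              sample_id = if ("sample_id" %in% names(records))
                .data$sample_id else NA_character_,
              identity_to_representative = .data$identity,
              cluster_id = .data$cluster_id)
  reps <- records[records$.member %in%
                    cl$id[cl$is_representative], , drop = FALSE] |>
    select(-".member")
  out <- list(representatives = reps, membership = membership,
              params = params)
  class(out) <- "is_catalogue"
  out
}

#' @export
print.is_catalogue <- function(x, ...) {
  cat("<is_catalogue>: ", nrow(x$representatives), " representative ISs from ",
      nrow(x$membership), " input records (c = ", x$params$identity, ")\n",
      sep = "")
  invisible(x)
}

#' Summarize a catalogue
#'
#' Per-representative length and accession list, with aggregate counts of
#' unique accessions, for downstream tabulation or plotting.
#'
#' @param catalogue An `is_catalogue`.
#' @return A tibble with `name`, `length`, `accessions` (semicolon-joined)
#'   per representative; the number of unique accessions across the
#'   catalogue is attached as attribute `"n_unique_accessions"`.
#' @export
summarize_catalogue <- function(catalogue) {
  reps <- catalogue$representatives
  if (nrow(reps) == 0) {
    out <- tibble(name = character(), length = integer(),
                  accessions = character())
    attr(out, "n_unique_accessions") <- 0L
    return(out)
  }
  accs <- if ("protein_hits" %in% names(reps)) {
    purrr::map_chr(reps$protein_hits, function(h) {
      if (is.null(h) || nrow(h) == 0) return(NA_character_)
      paste(sort(unique(h$accession)), collapse = ";")
    })
  } else {
    rep(NA_character_, nrow(reps))
  }
  out <- tibble(name = reps$name, length = nchar(reps$sequence),
                accessions = accs)
  all_accs <- unlist(stringr::str_split(accs[!is.na(accs)], ";"))
  attr(out, "n_unique_accessions") <- length(unique(all_accs))
  out
}

#' Write catalogue FASTA and membership TSV
#'
#' @param catalogue An `is_catalogue`.
#' @param fasta_path,membership_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_catalogue <- function(catalogue, fasta_path, membership_path) {
  if (nrow(catalogue$representatives) > 0) {
    write_fasta(catalogue$representatives, fasta_path)
  } else {
    file.create(fasta_path)
  }
  readr::write_tsv(catalogue$membership |> select(-dplyr::any_of("cluster_id")),
                   membership_path, progress = FALSE)
  invisible(list(fasta = fasta_path, membership = membership_path))
}

#' Broom-style accessors for IS catalogues
#'
#' `tidy()` returns the membership table; `glance()` a one-row summary.
#'
#' @param x An `is_catalogue`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.is_catalogue <- function(x, ...) {
  x$membership
}

#' @rdname tidy.is_catalogue
#' @export
glance.is_catalogue <- function(x, ...) {
  s <- summarize_catalogue(x)
  tibble(
    n_records = nrow(x$membership),
    n_representatives = nrow(x$representatives),
    min_length = if (nrow(s) > 0) min(s$length) else NA_integer_,
    max_length = if (nrow(s) > 0) max(s$length) else NA_integer_,
    n_unique_accessions = attr(s, "n_unique_accessions"),
    identity_threshold = x$params$identity
  )
}

#' Plot a catalogue's IS length distribution
#'
#' @param object An `is_catalogue`.
#' @param binwidth Histogram bin width in nt.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.is_catalogue <- function(object, binwidth = 100, ...) {
  s <- summarize_catalogue(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "grey20") +
    ggplot2::labs(x = "Insertion sequence length (bp)",
                  y = "Number of representative ISs") +
    ggplot2::theme_minimal()
}

#' Plot transposase accession counts in a catalogue
#'
#' @param catalogue An `is_catalogue`.
#' @return A ggplot object.
#' @export
plot_transposase_counts <- function(catalogue) {
  s <- summarize_catalogue(catalogue)
  accs <- s$accessions[!is.na(s$accessions)]
  df <- tibble(accession = unlist(stringr::str_split(accs, ";"))) |>
    dplyr::count(.data$accession, sort = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$accession,
                                                      .data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "Protein family accession",
                  y = "Representative ISs carrying the accession") +
    ggplot2::theme_minimal()
}
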