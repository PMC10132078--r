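# End-to-end orchestration: read store -> repeat reads -> placement ->
# candidate ITRs -> clustering -> pair validation -> annotation filter ->
# named outputs. Candidate ITRs are clustered across the whole run (all
# manifest rows), which maximizes cross-sample sensitivity.

#' Pipeline parameters
#'
#' Defaults mirror the conventional settings for short-read IS discovery:
#' ITR window 25-50 nt, k-mer 15, IS window 500-3000 nt, ITR clustering at
#' local identity 0.9 with 0.9 coverage of the shorter sequence.
#'
#' @param min_itr_length,max_itr_length,kmer_length,end_buffer See
#'   [mem_params()].
#' @param min_is_length,max_is_length IS span window in nt.
#' @param cd_hit_c,cd_hit_G,cd_hit_aL,cd_hit_aS,cd_hit_A ITR clustering
#'   parameters in CD-HIT-EST notation (identity threshold, global/local
#'   switch, coverage of longer / shorter sequence, minimal alignment
#'   length).
#' @param min_orf_aa Minimum ORF length in amino acids for annotation.
#' @return A list of class `is_pipeline_params`.
#' @export
pipeline_params <- function(min_itr_length = 25L, max_itr_length = 50L,
                            kmer_length = 15L, end_buffer = 20L,
                            min_is_length = 500L, max_is_length = 3000L,
                            cd_hit_c = 0.9, cd_hit_G = 0L, cd_hit_aL = 0.0,
                            cd_hit_aS = 0.9, cd_hit_A = 0L,
                            min_orf_aa = 30L) {
  mem <- mem_params(min_itr_length, max_itr_length, kmer_length, end_buffer)
  if (min_is_length > max_is_length || min_is_length < 1) {
    stop_input("need 1 <= min_is_length <= max_is_length")
  }
  p <- list(mem = mem,
            min_is_length = as.integer(min_is_length),
            max_is_length = as.integer(max_is_length),
            cluster = cluster_params(identity = cd_hit_c,
                                     global = cd_hit_G == 1L,
                                     cov_long = cd_hit_aL,
                                     cov_short = cd_hit_aS,
                                     min_aln = cd_hit_A),
            min_orf_aa = as.integer(min_orf_aa))
  class(p) <- "is_pipeline_params"
  p
}

#' Discover insertion sequences from a run manifest
#'
#' Runs the full pipeline: for each manifest row, reads are ingested,
#' packed into the 2-bit store, scanned for inter-read repeats, and the
#' repeat-containing reads are placed on the sample's assembly to give
#' candidate ITR intervals. Candidates pooled across the run are
#' clustered, paired by proximity per contig, validated (same cluster +
#' reverse complementarity), annotated, filtered for transposase evidence
#' (unless `annotation = "none"`), named, and written out as a FASTA plus
#' info TSV.
#'
#' @param manifest Manifest path or tibble (see [read_manifest()]).
#' @param params A [pipeline_params()] object.
#' @param annotation Annotation source passed to [annotate_is()]:
#'   `"mock"` (default; built-in keyword table), `"none"`, a keyword
#'   tibble, or `list(type = "interproscan", path = ...)`.
#' @param out_dir Output directory; `NULL` skips writing files.
#' @param seed Seed for the store's spacer generator (the only source of
#'   randomness in the pipeline).
#' @return An object of class `is_run`: list with `records` (finalized IS
#'   tibble), `candidates`, `clusters`, `pairs`, `counts` (per-stage
#'   record counts) and `paths`.
#' @export
discover_insertion_sequences <- function(manifest,
                                         params = pipeline_params(),
                                         annotation = "mock",
                                         out_dir = NULL, seed = 1L) {
  stopifnot(inherits(params, "is_pipeline_params"))
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  counts <- list()
  note <- function(stage, n) counts[[length(counts) + 1L]] <<-
    tibble(stage = stage, n = as.integer(n))

  all_candidates <- list()
  all_contigs <- list()
  n_reads <- 0L
  n_repeat <- 0L
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    reads <- bind_rows(
      read_fastq_reads(row$fastq1_path, mate = 1L,
                       sample_id = row$sample_id),
      read_fastq_reads(row$fastq2_path, mate = 2L,
                       sample_id = row$sample_id)) |>
      mutate(seq_id = paste0("Seq", row_number()),
             lane_id = row$lane_id)
    n_reads <- n_reads + nrow(reads)
    store <- two_bit_store(reads, min_usable_length = params$mem$kmer_length,
                           spacer_seed = seed)
    rr <- find_repeat_reads(store, params$mem)
    n_repeat <- n_repeat + nrow(rr)
    if (is.null(all_contigs[[row$assembly_path]])) {
      all_contigs[[row$assembly_path]] <-
        read_assembly(row$assembly_path, sample_id = row$sample_id)
    }
    contigs <- all_contigs[[row$assembly_path]]
    pl <- place_reads(rr, contigs)
    cand <- project_repeats(pl, rr, contigs)
    all_candidates[[length(all_candidates) + 1L]] <- cand
  }
  contigs <- bind_rows(all_contigs) |>
    distinct(.data$sample_id, .data$contig_id, .keep_all = TRUE)
  candidates <- bind_rows(all_candidates) |>
    distinct(.data$candidate_id, .keep_all = TRUE)
  note("reads", n_reads)
  note("repeat_reads", n_repeat)
  note("candidate_itrs", nrow(candidates))

  clusters <- cluster_greedy(
    candidates |> select(id = "candidate_id", "sequence"), params$cluster)
  note("itr_clusters", if (nrow(clusters)) max(clusters$cluster_id) else 0L)

  pairs <- pair_candidates(candidates, params$min_is_length,
                           params$max_is_length)
  note("proximity_pairs", nrow(pairs))
  validated <- validate_itr_pairs(pairs, clusters, params$mem,
                                  params$min_is_length, params$max_is_length)
  note("validated_pairs", sum(validated$valid))

  records <- call_insertion_sequences(validated, contigs)
  note("is_records", nrow(records))
  records <- annotate_is(records, annotation, min_aa = params$min_orf_aa)
  if (!identical(annotation, "none")) {
    records <- filter_transposase(records)
  }
  note("is_records_with_transposase", nrow(records))
  records <- finalize_is_records(records)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_is_outputs(records,
                              file.path(out_dir, "insertion_sequences.fasta"),
                              file.path(out_dir, "insertion_sequences_info.tsv"))
    count_tbl <- bind_rows(counts)
    readr::write_tsv(count_tbl, file.path(out_dir, "stage_counts.tsv"),
                     progress = FALSE)
    paths$counts <- file.path(out_dir, "stage_counts.tsv")
  }
  run <- list(records = records, candidates = candidates,
              clusters = clusters, pairs = validated,
              counts = bind_rows(counts), params = params, seed = seed,
              paths = paths)
  class(run) <- "is_run"
  run
}

#' @export
print.is_run <- function(x, ...) {
  cat("<is_run>: ", nrow(x$records), " insertion sequences\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Broom-style accessors for pipeline runs
#'
#' `tidy()` returns the finalized IS record table; `glance()` a one-row
#' tibble of per-stage record counts.
#'
#' @param x An `is_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.is_run <- function(x, ...) {
  x$records
}

#' @rdname tidy.is_run
#' @export
glance.is_run <- function(x, ...) {
  cts <- stats::setNames(as.list(x$counts$n), x$counts$stage)
  as_tibble(cts)
}

#' Plot called IS spans along their contigs
#'
#' @param object An `is_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.is_run <- function(object, ...) {
  r <- object$records
  ggplot2::ggplot(r, ggplot2::aes(x = .data$itr1_start,
                                  xend = .data$itr2_end,
                                  y = .data$contig_id,
                                  yend = .data$contig_id)) +
    ggplot2::geom_segment(linewidth = 3, colour = "steelblue") +
    ggplot2::labs(x = "Contig position (bp)", y = NULL,
                  title = "Called insertion sequences") +
    ggplot2::theme_minimal()
}

#' Build a dereplicated catalogue from one or more runs
#'
#' Pools finalized IS records (from `is_run` objects, record tibbles, or
#' output FASTA + info TSV pairs) and dereplicates them at the given
#' identity threshold.
#'
#' @param inputs A list whose elements are `is_run` objects, record
#'   tibbles, or `list(fasta = ..., tsv = ...)` path pairs.
#' @param identity Dereplication identity threshold (default 0.95).
#' @param out_dir Optional directory for catalogue FASTA + membership TSV.
#' @return An [dereplicate_catalogue()] `is_catalogue`.
#' @export
build_is_catalogue <- function(inputs, identity = 0.95, out_dir = NULL) {
  pool <- purrr::map_dfr(inputs, function(x) {
    if (inherits(x, "is_run")) return(x$records)
    if (is.data.frame(x)) return(as_tibble(x))
    if (is.list(x) && !is.null(x$fasta) && !is.null(x$tsv)) {
      info <- read_is_info(x$tsv)
      ss <- Biostrings::readDNAStringSet(x$fasta)
      return(info |>
               mutate(sequence = as.character(ss)[match(.data$name,
                                                        names(ss))]) |>
               rename(contig_id = "contig"))
    }
    stop_input("unsupported catalogue input")
  })
  cat_obj <- dereplicate_catalogue(pool, identity = identity)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_catalogue(cat_obj, file.path(out_dir, "catalogue.fasta"),
                    file.path(out_dir, "catalogue_membership.tsv"))
  }
  cat_obj
}
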