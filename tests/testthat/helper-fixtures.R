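# Small in-code fixtures shared across tests.

write_tiny_fastq <- function(seqs, path, ids = NULL, quals = NULL) {
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
  invisible(path)
}

write_tiny_fasta <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  invisible(path)
}

# a pool of random reads with shared blocks planted at stated positions;
# plant = list(i, j, pos_i, pos_j, len) with 0-based positions
make_pool <- function(n_reads, read_len, plants = list()) {
  seqs <- vapply(seq_len(n_reads), function(i) rnd_dna(read_len), "")
  block_of <- function(len) rnd_dna(len)
  for (p in plants) {
    blk <- block_of(p$len)
    substr(seqs[p$i], p$pos_i + 1, p$pos_i + p$len) <- blk
    substr(seqs[p$j], p$pos_j + 1, p$pos_j + p$len) <- blk
  }
  seqs
}

reads_tbl <- function(seqs, sample_id = "s1") {
  tibble::tibble(read_id = paste0("r", seq_along(seqs)), sequence = seqs,
                 sample_id = sample_id)
}

# deterministic InterProScan-style TSV row (15 columns)
ipr_row <- function(query, analysis = "PANTHER", sig_acc = "-",
                    sig_desc = "-", aa_start, aa_end, ipr_acc = "-",
                    ipr_desc = "-") {
  paste(query, "md5", "999", analysis, sig_acc, sig_desc, aa_start, aa_end,
        "1e-30", "T", "01-01-2026", ipr_acc, ipr_desc, "-", "-", sep = "\t")
}
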