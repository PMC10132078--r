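# Independent oracles used to verify the package's algorithms: these share
# no code with the implementation paths they check.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# naive base-by-base extension of an equal k-block to the maximal exact
# match containing it
oracle_extend <- function(s1, p1, s2, p2, k) {
  c1 <- strsplit(s1, "")[[1]]
  c2 <- strsplit(s2, "")[[1]]
  a <- p1 + 1L
  b <- p2 + 1L
  stopifnot(identical(c1[a:(a + k - 1)], c2[b:(b + k - 1)]))
  while (a > 1 && b > 1 && c1[a - 1] == c2[b - 1]) {
    a <- a - 1L
    b <- b - 1L
  }
  ea <- p1 + k
  eb <- p2 + k
  while (ea < length(c1) && eb < length(c2) && c1[ea + 1] == c2[eb + 1]) {
    ea <- ea + 1L
    eb <- eb + 1L
  }
  list(start_a = a - 1L, start_b = b - 1L, length = ea - a + 1L)
}

# all maximal common substrings between two strings: match runs along the
# diagonals of the character-equality matrix, found by marking cells whose
# up-left (run start) or down-right (run end) diagonal neighbour mismatches
oracle_mcs <- function(s1, s2, exclude_main_diagonal = FALSE) {
  a <- if (is.character(s1) && length(s1) == 1) strsplit(s1, "")[[1]] else s1
  b <- if (is.character(s2) && length(s2) == 1) strsplit(s2, "")[[1]] else s2
  n <- length(a)
  m <- length(b)
  M <- outer(a, b, "==")
  up_left <- rbind(FALSE, cbind(FALSE, M[-n, -m, drop = FALSE]))
  down_right <- rbind(cbind(M[-1, -1, drop = FALSE], FALSE), FALSE)
  S <- arrayInd(which(M & !up_left), dim(M))
  E <- arrayInd(which(M & !down_right), dim(M))
  ds <- S[, 1] - S[, 2]
  de <- E[, 1] - E[, 2]
  S <- S[order(ds, S[, 1]), , drop = FALSE]
  E <- E[order(de, E[, 1]), , drop = FALSE] # k-th start pairs with k-th end
  out <- data.frame(start_a = S[, 1] - 1L, start_b = S[, 2] - 1L,
                    length = E[, 1] - S[, 1] + 1L)
  if (exclude_main_diagonal) out <- out[S[, 1] != S[, 2], , drop = FALSE]
  out
}

# brute-force all-pairs repeat-read oracle applying the MEM length window
# and the end-buffer rule on both reads; returns the sorted set of read
# indices carrying at least one qualifying maximal common substring
oracle_repeat_reads <- function(seqs, params) {
  n <- length(seqs)
  lens <- nchar(seqs)
  buf <- params$end_buffer
  hit <- logical(n)
  chars <- strsplit(seqs, "")
  qualifies <- function(m, i, j) {
    len <- m$length
    ok_len <- len >= params$min_itr_length & len <= params$max_itr_length
    ok_i <- m$start_a >= buf & (m$start_a + len) <= lens[i] - buf
    ok_j <- m$start_b >= buf & (m$start_b + len) <= lens[j] - buf
    ok_len & ok_i & ok_j
  }
  for (i in seq_len(n)) {
    for (j in i:n) {
      m <- oracle_mcs(chars[[i]], chars[[j]], exclude_main_diagonal = i == j)
      if (nrow(m) == 0) next
      q <- qualifies(m, i, j)
      if (any(q)) {
        hit[i] <- TRUE
        hit[j] <- TRUE
      }
    }
  }
  which(hit)
}

# Gotoh local alignment (affine gaps) returning the optimal score; gap of
# length ell costs gap_open + ell * gap_ext, matching the package scoring
oracle_local_score <- function(s1, s2, match = 2, mismatch = -2,
                               gap_open = 4, gap_ext = 1) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1) # gap in s1 (horizontal)
  F <- matrix(NEG, n + 1, m + 1) # gap in s2 (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      sc <- if (a[i - 1] == b[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# gapless best local alignment statistics (for audits of short, gap-free
# repeat sequences): best-scoring contiguous diagonal segment
oracle_gapless_local <- function(s1, s2, match = 2, mismatch = -2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  best <- list(score = 0, n_match = 0L, aln_len = 0L,
               span_a = 0L, span_b = 0L)
  for (off in (-(length(a) - 1)):(length(b) - 1)) {
    i <- max(1, 1 - off)
    j <- i + off
    len <- min(length(a) - i, length(b) - j) + 1
    if (len < 1) next
    eq <- a[i:(i + len - 1)] == b[j:(j + len - 1)]
    sc <- ifelse(eq, match, mismatch)
    # Kadane with segment bookkeeping
    cur <- 0
    cur_start <- 1
    for (t in seq_len(len)) {
      cur <- cur + sc[t]
      if (cur <= 0) {
        cur <- 0
        cur_start <- t + 1
      } else if (cur > best$score) {
        seg <- cur_start:t
        best <- list(score = cur, n_match = sum(eq[seg]),
                     aln_len = length(seg), span_a = length(seg),
                     span_b = length(seg))
      }
    }
  }
  best
}

# naive six-frame stop-to-stop ORF scan using a hand-built codon table
oracle_orfs <- function(sequence, min_aa) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(sequence)
  res <- list()
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
  for (strand in c(1L, -1L)) {
    s <- if (strand > 0) sequence else rc
    for (off in 0:2) {
      codon_starts <- seq(off + 1L, nchar(s) - 2L, by = 3L)
      if (length(codon_starts) == 0) next
      codons <- substring(s, codon_starts, codon_starts + 2L)
      is_stop <- codons %in% stops
      # stop-to-stop segments of codon indices
      seg_start <- 1L
      bounds <- c(which(is_stop), length(codons) + 1L)
      for (bnd in bounds) {
        seg <- seq_len(bnd - seg_start) + seg_start - 1L
        if (length(seg) >= min_aa) {
          nt_s_local <- off + (seg[1] - 1L) * 3L + 1L
          nt_e_local <- off + seg[length(seg)] * 3L
          if (strand > 0) {
            res[[length(res) + 1L]] <- c(frame = strand * (off + 1L),
                                         nt_start = nt_s_local,
                                         nt_end = nt_e_local)
          } else {
            res[[length(res) + 1L]] <- c(frame = strand * (off + 1L),
                                         nt_start = L - nt_e_local + 1L,
                                         nt_end = L - nt_s_local + 1L)
          }
        }
        seg_start <- bnd + 1L
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(frame = integer(), nt_start = integer(),
                      nt_end = integer()))
  }
  df <- as.data.frame(do.call(rbind, res))
  df[order(df$nt_start, df$frame), ]
}

# reverse complement without Biostrings (for cross-checks)
oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", sapply(lapply(strsplit(x, ""), rev), paste,
                                collapse = ""))
}
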