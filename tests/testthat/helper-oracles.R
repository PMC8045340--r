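# Independent oracles and small generators used across the suite. These are
# deliberately naive re-derivations (enumeration / dynamic programming),
# kept separate from the package's own code paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# hand-rolled reverse complement, independent of the package's
oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Needleman-Wunsch with a linear gap penalty (score only)
oracle_nw_linear <- function(a, b, match = 5, mismatch = -4, gap = 2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- -gap * (0:n)
  D[1, ] <- -gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] - gap,
                             D[i + 1, j] - gap)
    }
  }
  D[n + 1, m + 1]
}

# test every substring of the allowed widths against an independently
# spelled-out pattern definition
oracle_motif_hits <- function(protein, motif) {
  widths <- switch(motif, A = 6:7, B = 8:9, C = 3L)
  check <- function(s) {
    r <- strsplit(s, "")[[1]]
    std <- all(r %in% AA20)
    if (!std) return(FALSE)
    w <- length(r)
    switch(motif,
      A = r[1] == "D" && r[w] == "D",
      B = r[1] == "G" && r[w - 4] == "T" && r[w] == "N",
      C = identical(r, c("G", "D", "D")))
  }
  out <- NULL
  L <- nchar(protein)
  for (w in widths) {
    for (s in seq_len(max(0L, L - w + 1L))) {
      sub <- substr(protein, s, s + w - 1L)
      if (check(sub)) {
        out <- rbind(out, data.frame(motif = motif, start = s,
                                     end = s + w - 1L, matched = sub,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# scan every genome offset for every read, both strands
oracle_map <- function(read, genome_seq) {
  L <- nchar(genome_seq)
  w <- nchar(read)
  hits <- NULL
  rc <- oracle_revcomp(read)
  for (s in seq_len(L - w + 1L)) {
    sub <- substr(genome_seq, s, s + w - 1L)
    if (sub == read) {
      hits <- rbind(hits, data.frame(seq = read, strand = "+", start = s,
                                     end = s + w - 1L,
                                     stringsAsFactors = FALSE))
    }
    if (sub == rc) {
      hits <- rbind(hits, data.frame(seq = read, strand = "-", start = s,
                                     end = s + w - 1L,
                                     stringsAsFactors = FALSE))
    }
  }
  hits
}

# a small self-consistent genome configuration used where the full-size
# default would be wastefully large
small_config <- function(seed = 1L, motif_order = "A-B-C") {
  positions <- if (motif_order == "A-B-C") {
    c(A = 420L, B = 470L, C = 520L)
  } else {
    c(C = 420L, A = 470L, B = 520L)
  }
  genome_config(
    length = 3000L,
    orfs = list(c(21L, 2120L), c(2200L, 2841L)),
    motif_order = motif_order, motif_orf = 1L,
    motif_positions = positions,
    tm_orf = 2L, tm_islands = list(c(60L, 79L)),
    seed = seed)
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
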