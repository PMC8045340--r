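#' Find open reading frames on the plus strand
#'
#' Scans the three plus-strand frames. Within each frame, an ORF runs from
#' the first `ATG` after the previous in-frame stop (or the frame start) to
#' the next in-frame stop, stop codon included. ORFs with no downstream
#' stop are discarded. Negeviruses are positive-sense, so the reverse
#' strand is never scanned.
#'
#' @param genome A [genome_record()].
#' @param min_len_codons Minimum ORF length in codons, stop included
#'   (default 150).
#' @return A data.frame with columns `start`, `end` (1-based inclusive,
#'   `end` is the last base of the stop codon), `frame` (1-3),
#'   `n_codons`, `protein` (stop stripped), sorted by `start`. May have
#'   zero rows.
#' @export
find_orfs <- function(genome, min_len_codons = 150L) {
  stopifnot(inherits(genome, "genome_record"))
  min_len_codons <- as.integer(min_len_codons)
  if (min_len_codons < 2L) stop("min_len_codons must be >= 2")
  seq <- genome$seq
  L <- nchar(seq)
  if (L < 6L) stop("genome too short to contain an ORF")
  rows <- list()
  for (f in 1:3) {
    n_cod <- (L - f + 1L) %/% 3L
    if (n_cod < 2L) next
    cod_start <- seq.int(f, by = 3L, length.out = n_cod)
    codons <- substring(seq, cod_start, cod_start + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    prev_stop <- 0L
    for (si in which(is_stop)) {
      seg <- (prev_stop + 1L):si
      atg_in_seg <- seg[is_atg[seg]]
      if (length(atg_in_seg) > 0L) {
        a <- atg_in_seg[1L]
        ncod <- si - a + 1L
        if (ncod >= min_len_codons) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = cod_start[a], end = cod_start[si] + 2L,
            frame = f, n_codons = ncod, stringsAsFactors = FALSE)
        }
      }
      prev_stop <- si
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      n_codons = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, rows)
  orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
  orfs$protein <- vapply(seq_len(nrow(orfs)), function(i) {
    aa <- translate_dna(substr(seq, orfs$start[i], orfs$end[i]))
    sub("\\*$", "", aa)
  }, character(1))
  rownames(orfs) <- NULL
  orfs
}

#' Trim a terminal poly(A) tail
#'
#' Removes a trailing run of `A`s when the run is at least `min_run` long;
#' genome sizes in this family are conventionally reported excluding the
#' poly(A) tail.
#'
#' @param genome A [genome_record()].
#' @param min_run Minimum run length to trim (default 10).
#' @return A [genome_record()] (possibly unchanged).
#' @export
trim_polya <- function(genome, min_run = 10L) {
  m <- regmatches(genome$seq, regexpr("A+$", genome$seq))
  if (length(m) == 1L && nchar(m) >= min_run) {
    genome$seq <- substr(genome$seq, 1L, nchar(genome$seq) - nchar(m))
  }
  genome
}

#' Annotate the major-ORF organization of a viral genome
#'
#' Selects major ORFs (all plus-strand ORFs of at least `min_len_codons`
#' codons; when two selected ORFs are nested, only the longer is kept),
#' then derives the 5' and 3' UTR lengths and, for every consecutive ORF
#' pair, the relation between them: an `overlap` of
#' `end_i - start_j + 1` nt when they intersect, otherwise an `intergenic`
#' gap, with a same-frame flag.
#'
#' @param genome A [genome_record()].
#' @param min_len_codons Minimum ORF length in codons (default 150).
#' @param expected_orfs If given and the major-ORF count differs, a warning
#'   is attached to the annotation (and emitted); annotation still returned.
#' @param trim_polya Trim a terminal poly(A) run of >= 10 nt first
#'   (default `FALSE`).
#' @return An object of class `genome_annotation`: `genome_id`,
#'   `genome_length`, `orfs` (as [find_orfs()], plus `index`),
#'   `utr5_len`, `utr3_len`, `relations` (data.frame `i`, `j`, `kind`,
#'   `length`, `same_frame`), `warnings`.
#' @export
annotate_genome <- function(genome, min_len_codons = 150L,
                            expected_orfs = NULL, trim_polya = FALSE) {
  stopifnot(inherits(genome, "genome_record"))
  if (isTRUE(trim_polya)) genome <- trim_polya(genome)
  orfs <- find_orfs(genome, min_len_codons = min_len_codons)
  if (nrow(orfs) == 0L) {
    stop("no ORF of >= ", min_len_codons,
         " codons found; consider lowering min_len_codons")
  }
  # drop ORFs nested inside a longer selected ORF
  keep <- rep(TRUE, nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    for (j in seq_len(nrow(orfs))) {
      if (i != j && keep[j] &&
          orfs$start[i] >= orfs$start[j] && orfs$end[i] <= orfs$end[j] &&
          orfs$n_codons[i] < orfs$n_codons[j]) {
        keep[i] <- FALSE
      }
    }
  }
  orfs <- orfs[keep, , drop = FALSE]
  orfs <- orfs[order(orfs$start), , drop = FALSE]
  orfs$index <- seq_len(nrow(orfs))
  rownames(orfs) <- NULL
  warnings <- character()
  if (!is.null(expected_orfs) && nrow(orfs) != expected_orfs) {
    w <- sprintf("expected %d major ORFs but found %d",
                 expected_orfs, nrow(orfs))
    warning(w)
    warnings <- c(warnings, w)
  }
  L <- nchar(genome$seq)
  relations <- if (nrow(orfs) >= 2L) {
    do.call(rbind, lapply(seq_len(nrow(orfs) - 1L), function(i) {
      j <- i + 1L
      ov <- max(0L, orfs$end[i] - orfs$start[j] + 1L)
      data.frame(
        i = i, j = j,
        kind = if (ov > 0L) "overlap" else "intergenic",
        length = if (ov > 0L) ov else orfs$start[j] - orfs$end[i] - 1L,
        same_frame = orfs$frame[i] == orfs$frame[j],
        stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(i = integer(), j = integer(), kind = character(),
               length = integer(), same_frame = logical(),
               stringsAsFactors = FALSE)
  }
  ann <- structure(list(
    genome_id = genome$id,
    genome_length = L,
    orfs = orfs,
    utr5_len = orfs$start[1L] - 1L,
    utr3_len = L - orfs$end[nrow(orfs)],
    relations = relations,
    warnings = warnings), class = "genome_annotation")
  validate_annotation(ann, genome)
  ann
}

#' Validate a genome annotation against its genome
#'
#' Checks every structural invariant: ATG starts, stop ends, codon-multiple
#' spans, protein lengths, UTR arithmetic, and the length-conservation
#' identity `utr5 + sum(ORF) - sum(overlaps) + sum(gaps) + utr3 = genome
#' length` over consecutive pairs.
#'
#' @param ann A `genome_annotation`.
#' @param genome The [genome_record()] it annotates (optional; sequence
#'   checks skipped if absent).
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_annotation <- function(ann, genome = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  o <- ann$orfs
  stopifnot(all((o$end - o$start + 1L) %% 3L == 0L),
            all(nchar(o$protein) == (o$end - o$start + 1L) / 3L - 1L),
            all(o$start >= 1L), all(o$end <= ann$genome_length),
            ann$utr5_len == o$start[1L] - 1L,
            ann$utr3_len == ann$genome_length - o$end[nrow(o)])
  if (!is.null(genome)) {
    stopifnot(all(substring(genome$seq, o$start, o$start + 2L) == "ATG"),
              all(substring(genome$seq, o$end - 2L, o$end) %in% STOP_CODONS))
  }
  r <- ann$relations
  ov <- sum(r$length[r$kind == "overlap"])
  gap <- sum(r$length[r$kind == "intergenic"])
  lhs <- ann$utr5_len + sum(o$end - o$start + 1L) - ov + gap + ann$utr3_len
  stopifnot(lhs == ann$genome_length)
  invisible(TRUE)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s (%d nt), %d major ORF(s)\n",
              x$genome_id, x$genome_length, nrow(x$orfs)))
  cat(sprintf("  5' UTR %d nt | 3' UTR %d nt\n", x$utr5_len, x$utr3_len))
  for (i in seq_len(nrow(x$orfs))) {
    cat(sprintf("  ORF%d: %d-%d nt (frame %d, %d aa)\n", i,
                x$orfs$start[i], x$orfs$end[i], x$orfs$frame[i],
                nchar(x$orfs$protein[i])))
  }
  for (i in seq_len(nrow(x$relations))) {
    r <- x$relations[i, ]
    cat(sprintf("  ORF%d-ORF%d: %s %d nt (%s frame)\n", r$i, r$j, r$kind,
                r$length, if (r$same_frame) "same" else "different"))
  }
  invisible(x)
}

#' Export an annotation as TSV and GFF3
#'
#' Writes one TSV row per ORF and a GFF3 file (written through
#' [rtracklayer::export()]) with `five_prime_UTR`, `CDS` and
#' `three_prime_UTR` features on the plus strand, phase 0.
#'
#' @param ann A `genome_annotation`.
#' @param tsv_path,gff3_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, a list with the TSV data.frame and the
#'   [GenomicRanges::GRanges] written to GFF3.
#' @export
report_annotation <- function(ann, tsv_path = NULL, gff3_path = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  tsv <- data.frame(
    genome_id = ann$genome_id,
    orf = paste0("ORF", ann$orfs$index),
    start = ann$orfs$start, end = ann$orfs$end, frame = ann$orfs$frame,
    length_nt = ann$orfs$end - ann$orfs$start + 1L,
    protein_length_aa = nchar(ann$orfs$protein),
    stringsAsFactors = FALSE)
  if (!is.null(tsv_path)) {
    utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  feats <- data.frame(
    start = ann$orfs$start, end = ann$orfs$end, type = "CDS",
    ID = paste0("ORF", ann$orfs$index), stringsAsFactors = FALSE)
  if (ann$utr5_len > 0L) {
    feats <- rbind(data.frame(start = 1L, end = ann$utr5_len,
                              type = "five_prime_UTR", ID = "UTR5",
                              stringsAsFactors = FALSE), feats)
  }
  if (ann$utr3_len > 0L) {
    feats <- rbind(feats, data.frame(
      start = ann$genome_length - ann$utr3_len + 1L, end = ann$genome_length,
      type = "three_prime_UTR", ID = "UTR3", stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ann$genome_id,
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    strand = "+")
  S4Vectors::mcols(gr)$type <- feats$type
  S4Vectors::mcols(gr)$ID <- feats$ID
  S4Vectors::mcols(gr)$phase <- ifelse(feats$type == "CDS", 0L, NA_integer_)
  if (!is.null(gff3_path)) rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(list(tsv = tsv, gff3 = gr))
}
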