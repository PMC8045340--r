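#' Construct a genome record
#'
#' A genome record is the package's unit of nucleotide sequence: an id, an
#' optional free-text description, and an uppercase DNA-alphabet sequence
#' (`A/C/G/T/N`). RNA input (`U`) is converted to `T`; all internal
#' computation is in the DNA alphabet.
#'
#' @param id Non-empty sequence identifier.
#' @param seq Nucleotide sequence string; case-folded, `U` converted to `T`.
#' @param description Optional description (rest of the FASTA header).
#' @return A list of class `genome_record` with fields `id`, `description`,
#'   `seq`.
#' @export
genome_record <- function(id, seq, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- normalize_dna(seq)
  if (!nzchar(seq)) stop("genome record '", id, "' has an empty sequence")
  structure(list(id = id, description = description, seq = seq),
            class = "genome_record")
}

normalize_dna <- function(seq) {
  seq <- gsub("[[:space:]]", "", toupper(seq))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N,U}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  seq
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%d nt)\n", x$id, nchar(x$seq)))
  invisible(x)
}

#' Construct a protein record
#'
#' @param id Identifier.
#' @param seq Amino-acid string over the 20 standard residues plus `X`
#'   (ambiguous) and `*` (stop). For a translated ORF product at most one
#'   trailing `*` is allowed and internal stops are rejected.
#' @param check_internal_stops Reject internal `*` (default `TRUE`).
#' @return A list of class `protein_record` with fields `id`, `seq`.
#' @export
protein_record <- function(id, seq, check_internal_stops = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- gsub("[[:space:]]", "", toupper(seq))
  bad <- gsub(paste0("[", paste(AA_STANDARD, collapse = ""), "X*]"), "", seq)
  if (nzchar(bad)) {
    stop("protein sequence contains illegal characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  body <- sub("\\*$", "", seq)
  if (check_internal_stops && grepl("*", body, fixed = TRUE)) {
    stop("internal stop codon in translated ORF product '", id, "'")
  }
  structure(list(id = id, seq = seq), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$seq)))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Parses with [Biostrings::readBStringSet()], then normalizes: uppercase,
#' `U` to `T`, whitespace stripped. Duplicate ids get a numeric suffix with
#' a warning.
#'
#' @param path Path to a FASTA file.
#' @return A list of [genome_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop("FASTA format error in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) stop("FASTA format error: no records in '", path, "'")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids in '", path, "'; de-duplicated with suffixes")
    ids <- make.unique(ids, sep = "_")
  }
  lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]), descs[i])
  })
}

#' Write genome records to FASTA
#'
#' @param records A single [genome_record()] or list of them.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "genome_record") || inherits(records, "protein_record")) {
    records <- list(records)
  }
  lines <- unlist(lapply(records, function(r) {
    header <- if (!is.null(r$description) && nzchar(r$description)) {
      paste(r$id, r$description)
    } else r$id
    body <- substring(r$seq, seq(1L, nchar(r$seq), by = width),
                      pmin(seq(1L, nchar(r$seq), by = width) + width - 1L,
                           nchar(r$seq)))
    c(paste0(">", header), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' `N` maps to `N`; length is preserved and the operation is an involution.
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}` (vectorized).
#' @return Reverse complement string(s).
#' @export
revcomp <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) stop("alphabet error: revcomp input outside {A,C,G,T,N}")
  unname(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq))))
}

#' Translate a coding sequence
#'
#' Standard genetic code (NCBI table 1); stop codons become `*`; any codon
#' containing `N` becomes `X`. Length must be divisible by 3.
#'
#' @param seq Nucleotide string, length divisible by 3.
#' @return Amino-acid string of length `nchar(seq)/3`.
#' @export
translate_dna <- function(seq) {
  seq <- normalize_dna(seq)
  if (nchar(seq) %% 3L != 0L) {
    stop("frame error: sequence length ", nchar(seq), " not divisible by 3")
  }
  if (nchar(seq) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     if.fuzzy.codon = "X"))
}

#' Read and length-filter a small-RNA read library
#'
#' Reads FASTA or FASTQ (qualities parsed but discarded), keeps reads whose
#' length lies in `[min_len, max_len]` (bounds inclusive), and collapses
#' identical sequences. The collapsing key is the exact sequence string;
#' only the first read id per distinct sequence is retained.
#'
#' @param path Input file.
#' @param fmt `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @param min_len,max_len Inclusive length bounds (defaults 18 and 30 nt).
#' @return A list of class `read_set`: `reads` (data.frame with columns
#'   `id`, `seq`, `length`, `count`, one row per distinct in-range
#'   sequence), `n_input` (reads parsed), `n_removed` (reads outside the
#'   length window), `n_kept` (`sum(count)`).
#' @export
read_reads <- function(path, fmt = c("auto", "fasta", "fastq"),
                       min_len = 18L, max_len = 30L) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else "fasta"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = fmt),
                  error = function(e) {
                    stop(toupper(fmt), " format error in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) stop(toupper(fmt), " format error: no records in '",
                              path, "'")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  read_set(ids, seqs, min_len = min_len, max_len = max_len)
}

#' Build a read set from id/sequence vectors
#'
#' Programmatic counterpart of [read_reads()] used by the synthetic-data
#' generator; applies the same length filter and collapsing.
#'
#' @param ids,seqs Parallel character vectors.
#' @param min_len,max_len Inclusive length bounds.
#' @return A `read_set` (see [read_reads()]).
#' @export
read_set <- function(ids, seqs, min_len = 18L, max_len = 30L) {
  stopifnot(length(ids) == length(seqs))
  n_input <- length(seqs)
  len <- nchar(seqs)
  keep <- len >= min_len & len <= max_len
  n_removed <- sum(!keep)
  if (n_removed > 0L) {
    message(n_removed, " read(s) outside [", min_len, ", ", max_len,
            "] nt removed")
  }
  ids <- ids[keep]; seqs <- seqs[keep]
  if (length(seqs) == 0L) {
    reads <- data.frame(id = character(), seq = character(),
                        length = integer(), count = integer(),
                        stringsAsFactors = FALSE)
  } else {
    first <- !duplicated(seqs)
    counts <- table(factor(seqs, levels = seqs[first]))
    reads <- data.frame(id = ids[first], seq = seqs[first],
                        length = nchar(seqs[first]),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
  }
  out <- structure(list(reads = reads, n_input = n_input,
                        n_removed = n_removed, n_kept = sum(reads$count),
                        min_len = as.integer(min_len),
                        max_len = as.integer(max_len)),
                   class = "read_set")
  stopifnot(out$n_kept == n_input - n_removed)
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf(
    "<read_set> %d reads in range (%d distinct); %d of %d input removed\n",
    x$n_kept, nrow(x$reads), x$n_removed, x$n_input))
  invisible(x)
}

#' Write a collapsed read table as TSV
#'
#' @param rs A `read_set`.
#' @param path Output path. Columns: `seq`, `length`, `count`.
#' @return `path`, invisibly.
#' @export
write_read_table <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  utils::write.table(rs$reads[, c("seq", "length", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
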