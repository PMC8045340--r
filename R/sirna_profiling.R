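#' Map small-RNA reads to a viral genome with zero mismatches
#'
#' Exact string matching of every distinct read sequence against the plus
#' strand, and of its reverse complement against the plus strand (reported
#' as minus-strand hits). Every hit satisfies the zero-mismatch guarantee:
#' the genomic span equals the read (plus) or its reverse complement
#' (minus).
#'
#' @param rs A `read_set` (see [read_reads()]); reads are expected to be
#'   length-filtered already.
#' @param genome A [genome_record()].
#' @return data.frame of hits with columns `seq` (read sequence),
#'   `strand` (`"+"`/`"-"`), `start`, `end` (plus-strand coordinates of
#'   the covered span), `pos5` (plus-strand coordinate of the read's 5'
#'   end: `start` for plus hits, `end` for minus hits). Unmapped reads
#'   contribute no rows.
#' @export
map_reads <- function(rs, genome) {
  stopifnot(inherits(rs, "read_set"), inherits(genome, "genome_record"))
  empty <- data.frame(seq = character(), strand = character(),
                      start = integer(), end = integer(), pos5 = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(rs$reads) == 0L) return(empty)
  seqs <- rs$reads$seq
  subject <- Biostrings::DNAString(genome$seq)
  # constant-width dictionaries (Aho-Corasick) per read length for large
  # width groups; small groups and reads with ambiguous bases use a plain
  # fixed-string scan, which has no per-dictionary overhead
  locate <- function(patterns) {
    out <- vector("list", length(patterns))
    has_n <- grepl("N", patterns, fixed = TRUE)
    widths <- nchar(patterns)
    grp_size <- table(widths[!has_n])
    small <- has_n | grp_size[as.character(widths)] < 32L
    if (any(small)) {
      out[small] <- stringi::stri_locate_all_fixed(
        genome$seq, patterns[small], overlap = TRUE)
    }
    idx_pdict <- which(!small)
    for (w in unique(widths[idx_pdict])) {
      grp <- idx_pdict[widths[idx_pdict] == w]
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns[grp]))
      m <- Biostrings::matchPDict(pd, subject)
      starts <- Biostrings::startIndex(m)
      for (k in seq_along(grp)) {
        s <- starts[[k]]
        out[[grp[k]]] <- if (length(s) == 0L) {
          matrix(NA_integer_, 1L, 2L)
        } else cbind(s, s + w - 1L)
      }
    }
    out
  }
  plus <- locate(seqs)
  minus <- locate(revcomp(seqs))
  one_strand <- function(locs, strand) {
    n_hits <- vapply(locs, function(m) {
      if (is.na(m[1, 1])) 0L else nrow(m)
    }, integer(1))
    if (sum(n_hits) == 0L) return(empty)
    idx <- rep.int(seq_along(locs), n_hits)
    coords <- do.call(rbind, locs[n_hits > 0L])
    data.frame(seq = seqs[idx], strand = strand,
               start = as.integer(coords[, 1]),
               end = as.integer(coords[, 2]),
               pos5 = as.integer(if (strand == "+") coords[, 1] else
                                 coords[, 2]),
               stringsAsFactors = FALSE)
  }
  hits <- rbind(one_strand(plus, "+"), one_strand(minus, "-"))
  hits <- hits[order(match(hits$seq, seqs), hits$strand, hits$start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Profile virus-derived small RNAs
#'
#' Aggregates exact-match hits into the standard vsiRNA summaries: size
#' distribution per strand (total and unique), strand counts, 5'-terminal
#' nucleotide composition per strand (RNA alphabet), per-position genome
#' coverage per strand, and mapped fractions of the library.
#'
#' A read mapping to several loci contributes its full count once to
#' totals, size and 5'-nucleotide tallies — on the strand carrying the
#' majority of its loci under the default `multi = "majority"` policy
#' (tie, including palindromic both-strand reads, resolved to `"+"` and
#' flagged) — and contributes `count / n_loci` fractional weight to
#' coverage at each locus on that locus's own strand.
#'
#' @param hits Output of [map_reads()].
#' @param rs The `read_set` the hits came from.
#' @param genome_length Genome length in nt.
#' @param multi Multi-locus strand policy: `"majority"` (default) or
#'   `"first"` (strand of the leftmost locus).
#' @return Object of class `sirna_profile` with fields `n_total_mapped`,
#'   `n_unique_mapped`, `n_library`, `n_unique_library`, `frac_total`,
#'   `frac_unique`, `size_dist` (data.frame `length` x `strand` with
#'   `total`/`unique` counts), `five_prime` (data.frame `nt` in RNA
#'   alphabet x `strand`, total counts), `coverage` (matrix `2 x
#'   genome_length`, rows `+`/`-`), `n_ambiguous_strand` (flagged ties),
#'   `min_len`, `max_len`.
#' @export
sirna_profile <- function(hits, rs, genome_length,
                          multi = c("majority", "first")) {
  multi <- match.arg(multi)
  stopifnot(inherits(rs, "read_set"))
  if (nrow(hits) > 0L && !all(hits$seq %in% rs$reads$seq)) {
    stop("consistency error: hits reference reads absent from the read set")
  }
  lens <- rs$min_len:rs$max_len
  strands <- c("+", "-")
  size_dist <- expand.grid(length = lens, strand = strands,
                           stringsAsFactors = FALSE)
  size_dist$total <- 0
  size_dist$unique <- 0
  five_prime <- expand.grid(nt = c("A", "C", "G", "U"), strand = strands,
                            stringsAsFactors = FALSE)
  five_prime$count <- 0
  coverage <- matrix(0, nrow = 2L, ncol = genome_length,
                     dimnames = list(strands, NULL))
  n_total_mapped <- 0L
  n_unique_mapped <- 0L
  n_ambiguous <- 0L
  if (nrow(hits) > 0L) {
    counts <- stats::setNames(rs$reads$count, rs$reads$seq)
    idx_by_seq <- split(seq_len(nrow(hits)), hits$seq)
    mapped_seqs <- names(idx_by_seq)
    n_loci <- lengths(idx_by_seq)
    is_plus <- hits$strand == "+"
    n_plus <- vapply(idx_by_seq, function(ix) sum(is_plus[ix]), integer(1))
    n_minus <- n_loci - n_plus
    if (multi == "majority") {
      strand <- ifelse(n_plus >= n_minus, "+", "-")
      tie <- n_plus == n_minus
      n_ambiguous <- sum(tie)
    } else {
      strand <- vapply(idx_by_seq, function(ix) {
        hits$strand[ix[which.min(hits$start[ix])]]
      }, character(1))
    }
    cnt <- unname(counts[mapped_seqs])
    n_total_mapped <- sum(cnt)
    n_unique_mapped <- length(mapped_seqs)
    len <- nchar(mapped_seqs)
    key <- paste(len, strand)
    sd_key <- paste(size_dist$length, size_dist$strand)
    tot <- tapply(cnt, key, sum)
    uni <- tapply(rep(1L, length(key)), key, sum)
    size_dist$total <- as.numeric(ifelse(is.na(tot[sd_key]), 0, tot[sd_key]))
    size_dist$unique <- as.numeric(ifelse(is.na(uni[sd_key]), 0,
                                          uni[sd_key]))
    nt5 <- chartr("T", "U", substr(mapped_seqs, 1L, 1L))
    fp_key <- paste(nt5, strand)
    fp <- tapply(cnt, fp_key, sum)
    fp_all <- paste(five_prime$nt, five_prime$strand)
    five_prime$count <- as.numeric(ifelse(is.na(fp[fp_all]), 0, fp[fp_all]))
    w_seq <- cnt / n_loci
    w_hit <- w_seq[match(hits$seq, mapped_seqs)]
    for (k in seq_len(nrow(hits))) {
      span <- hits$start[k]:hits$end[k]
      coverage[hits$strand[k], span] <-
        coverage[hits$strand[k], span] + w_hit[k]
    }
  }
  out <- structure(list(
    n_total_mapped = n_total_mapped,
    n_unique_mapped = n_unique_mapped,
    n_library = rs$n_kept,
    n_unique_library = nrow(rs$reads),
    frac_total = if (rs$n_kept > 0L) n_total_mapped / rs$n_kept else 0,
    frac_unique = if (nrow(rs$reads) > 0L) {
      n_unique_mapped / nrow(rs$reads)
    } else 0,
    size_dist = size_dist,
    five_prime = five_prime,
    coverage = coverage,
    n_ambiguous_strand = n_ambiguous,
    min_len = rs$min_len, max_len = rs$max_len,
    genome_length = genome_length),
    class = "sirna_profile")
  validate_profile(out)
  out
}

#' Validate the conservation identities of a vsiRNA profile
#'
#' Checks that the size distribution sums to the mapped totals, the
#' 5'-nucleotide tallies sum to each strand's total, fractions lie in
#' `[0, 1]`, and total coverage weight equals the summed mapped
#' nucleotides (count x length over mapped reads).
#'
#' @param p A `sirna_profile`.
#' @param mapped_nt Optional known value of `sum(count * length)` over
#'   mapped reads, to check the coverage mass against.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_profile <- function(p, mapped_nt = NULL) {
  stopifnot(inherits(p, "sirna_profile"))
  stopifnot(sum(p$size_dist$total) == p$n_total_mapped,
            sum(p$size_dist$unique) == p$n_unique_mapped,
            p$frac_total >= 0, p$frac_total <= 1,
            p$frac_unique >= 0, p$frac_unique <= 1)
  for (s in c("+", "-")) {
    stopifnot(isTRUE(all.equal(
      sum(p$five_prime$count[p$five_prime$strand == s]),
      sum(p$size_dist$total[p$size_dist$strand == s]))))
  }
  mass <- sum(p$size_dist$total * p$size_dist$length)
  stopifnot(isTRUE(all.equal(sum(p$coverage), mass)))
  if (!is.null(mapped_nt)) stopifnot(isTRUE(all.equal(mass, mapped_nt)))
  invisible(TRUE)
}

#' @export
print.sirna_profile <- function(x, ...) {
  cat(sprintf("<sirna_profile> %d mapped reads (%d unique) of %d (%d unique)\n",
              x$n_total_mapped, x$n_unique_mapped, x$n_library,
              x$n_unique_library))
  cat(sprintf("  mapped fraction: %.4f total, %.4f unique\n",
              x$frac_total, x$frac_unique))
  by_len <- tapply(x$size_dist$total, x$size_dist$length, sum)
  if (sum(by_len) > 0) {
    mode_len <- names(by_len)[which.max(by_len)]
    cat(sprintf("  modal length: %s nt (%.1f%% of mapped)\n", mode_len,
                100 * max(by_len) / sum(by_len)))
    plus <- sum(x$size_dist$total[x$size_dist$strand == "+"])
    cat(sprintf("  strand split: %d (+) / %d (-)\n", plus,
                x$n_total_mapped - plus))
  }
  invisible(x)
}

#' Write a vsiRNA profile as TSV panels plus a JSON summary
#'
#' Emits `<prefix>_size_dist.tsv`, `<prefix>_five_prime.tsv`,
#' `<prefix>_coverage.tsv` (one row per genome position per strand) and
#' `<prefix>_summary.json`.
#'
#' @param p A `sirna_profile`.
#' @param prefix Output path prefix.
#' @return Named character vector of paths, invisibly.
#' @export
write_profile <- function(p, prefix) {
  validate_profile(p)
  paths <- c(size_dist = paste0(prefix, "_size_dist.tsv"),
             five_prime = paste0(prefix, "_five_prime.tsv"),
             coverage = paste0(prefix, "_coverage.tsv"),
             summary = paste0(prefix, "_summary.json"))
  utils::write.table(p$size_dist, paths["size_dist"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(p$five_prime, paths["five_prime"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cov <- data.frame(
    position = rep(seq_len(ncol(p$coverage)), times = 2L),
    strand = rep(rownames(p$coverage), each = ncol(p$coverage)),
    weight = c(p$coverage["+", ], p$coverage["-", ]),
    stringsAsFactors = FALSE)
  utils::write.table(cov, paths["coverage"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- p[c("n_total_mapped", "n_unique_mapped", "n_library",
                 "n_unique_library", "frac_total", "frac_unique",
                 "n_ambiguous_strand", "min_len", "max_len",
                 "genome_length")]
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Re-read profile panels written by [write_profile()]
#'
#' @param prefix The prefix given to [write_profile()].
#' @return A `sirna_profile` rebuilt from the TSV/JSON files.
#' @export
read_profile <- function(prefix) {
  size_dist <- utils::read.table(paste0(prefix, "_size_dist.tsv"),
                                 sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
  five_prime <- utils::read.table(paste0(prefix, "_five_prime.tsv"),
                                  sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  cov <- utils::read.table(paste0(prefix, "_coverage.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  summary <- jsonlite::read_json(paste0(prefix, "_summary.json"),
                                 simplifyVector = TRUE)
  gl <- summary$genome_length
  coverage <- matrix(0, 2L, gl, dimnames = list(c("+", "-"), NULL))
  for (s in c("+", "-")) {
    rows <- cov[cov$strand == s, ]
    coverage[s, rows$position] <- rows$weight
  }
  out <- c(summary[c("n_total_mapped", "n_unique_mapped", "n_library",
                     "n_unique_library", "frac_total", "frac_unique")],
           list(size_dist = size_dist, five_prime = five_prime,
                coverage = coverage),
           summary[c("n_ambiguous_strand", "min_len", "max_len",
                     "genome_length")])
  structure(out, class = "sirna_profile")
}
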