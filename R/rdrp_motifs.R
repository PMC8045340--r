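#' Motif specifications for the RdRP catalytic motifs
#'
#' Motif A is `D X(4-5) D`, motif B is `G X(2-3) T X(3) N`, motif C is
#' `GDD`, where `X` is any of the 20 standard amino acids.
#'
#' @return A named list (`A`, `B`, `C`); each element has `name`,
#'   `widths` (allowed match lengths) and `regex_for_width`, a function
#'   mapping a width to an anchored regular expression.
#' @export
motif_specs <- function() {
  x <- AA20_CLASS
  list(
    A = list(name = "A", widths = 6:7,
             regex_for_width = function(w) {
               sprintf("D%s{%d}D", x, w - 2L)
             }),
    B = list(name = "B", widths = 8:9,
             regex_for_width = function(w) {
               sprintf("G%s{%d}T%s{3}N", x, w - 6L, x)
             }),
    C = list(name = "C", widths = 3L,
             regex_for_width = function(w) "GDD")
  )
}

#' Scan a protein for one RdRP motif
#'
#' Reports every match, including overlapping alternatives of the
#' variable-width patterns, sorted by start position.
#'
#' @param protein Amino-acid string (no internal stops).
#' @param motif `"A"`, `"B"` or `"C"`.
#' @return data.frame with columns `motif`, `start`, `end` (1-based
#'   inclusive), `matched`; zero rows when the motif is absent.
#' @export
scan_motif <- function(protein, motif = c("A", "B", "C")) {
  motif <- match.arg(motif)
  protein <- toupper(protein)
  if (!nzchar(protein)) stop("protein sequence is empty")
  if (grepl("\\*.", protein)) stop("internal stop in protein sequence")
  spec <- motif_specs()[[motif]]
  rows <- list()
  for (w in spec$widths) {
    # lookahead regex finds overlapping occurrences of this concrete width
    re <- paste0("(?=(", spec$regex_for_width(w), "))")
    m <- gregexpr(re, protein, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      starts <- as.integer(m)
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, start = starts, end = starts + w - 1L,
        matched = substring(protein, starts, starts + w - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the RdRP motif architecture of a protein
#'
#' Scans a region of the protein (default: its C-terminal half, where the
#' RdRP domain sits in these polyproteins) for motifs A, B and C,
#' enumerates candidate triples (one hit per motif, mutually
#' non-overlapping, consecutive gaps within `[gap_min, gap_max]` residues),
#' and keeps the surviving triple of minimal span (tie broken by leftmost
#' start). The architecture label is the motif names sorted by hit start:
#' `"A-B-C"` (canonical), `"C-A-B"` (permuted), or any other order as
#' spelled; `"undetermined"` when no triple survives.
#'
#' @param protein Amino-acid string.
#' @param region Optional `c(start, end)` 1-based residue interval to scan;
#'   default is the C-terminal half.
#' @param gap_min,gap_max Allowed residue gap between consecutive chosen
#'   motifs (defaults 5 and 300); bounds prevent pairing motifs from
#'   opposite ends of a multi-domain polyprotein.
#' @param max_hits_per_motif Safety cap on candidates per motif before
#'   triple enumeration (default 60; nearest hits kept).
#' @return Object of class `motif_order`: `order` (label), `hits` (chosen
#'   triple as a data.frame, or `NULL`), `all_candidates` (named counts of
#'   raw hits per motif within the region), `region`.
#' @export
classify_order <- function(protein, region = NULL, gap_min = 5L,
                           gap_max = 300L, max_hits_per_motif = 60L) {
  protein <- toupper(protein)
  L <- nchar(protein)
  if (is.null(region)) region <- c(L %/% 2L + 1L, L)
  stopifnot(length(region) == 2L, region[1] >= 1L, region[2] <= L,
            region[1] <= region[2])
  sub <- substr(protein, region[1], region[2])
  hits <- lapply(c(A = "A", B = "B", C = "C"), function(m) {
    h <- scan_motif(sub, m)
    if (nrow(h) > 0L) {
      h$start <- h$start + region[1] - 1L
      h$end <- h$end + region[1] - 1L
    }
    h
  })
  counts <- vapply(hits, nrow, integer(1))
  result <- structure(list(order = "undetermined", hits = NULL,
                           all_candidates = counts, region = region),
                      class = "motif_order")
  if (any(counts == 0L)) return(result)
  hits <- lapply(hits, function(h) utils::head(h, max_hits_per_motif))
  combos <- expand.grid(a = seq_len(nrow(hits$A)), b = seq_len(nrow(hits$B)),
                        cc = seq_len(nrow(hits$C)))
  best <- NULL
  for (k in seq_len(nrow(combos))) {
    triple <- rbind(hits$A[combos$a[k], ], hits$B[combos$b[k], ],
                    hits$C[combos$cc[k], ])
    triple <- triple[order(triple$start), , drop = FALSE]
    gaps <- triple$start[-1L] - triple$end[-3L] - 1L
    if (any(gaps < gap_min) || any(gaps > gap_max)) next
    span <- triple$end[3L] - triple$start[1L] + 1L
    if (is.null(best) || span < best$span ||
        (span == best$span && triple$start[1L] < best$triple$start[1L])) {
      best <- list(span = span, triple = triple)
    }
  }
  if (is.null(best)) return(result)
  result$hits <- best$triple
  result$order <- paste(best$triple$motif, collapse = "-")
  result
}

#' @export
print.motif_order <- function(x, ...) {
  cat(sprintf("<motif_order> %s (scanned region %d-%d aa)\n", x$order,
              x$region[1], x$region[2]))
  cat(sprintf("  raw hits: A=%d B=%d C=%d\n", x$all_candidates["A"],
              x$all_candidates["B"], x$all_candidates["C"]))
  if (!is.null(x$hits)) {
    for (i in seq_len(nrow(x$hits))) {
      cat(sprintf("  motif %s: %d-%d aa (%s)\n", x$hits$motif[i],
                  x$hits$start[i], x$hits$end[i], x$hits$matched[i]))
    }
  }
  invisible(x)
}

#' Write motif scan results as TSV
#'
#' @param protein Amino-acid string.
#' @param res A `motif_order` from [classify_order()].
#' @param path Output TSV path; columns `motif`, `start`, `end`,
#'   `matched`, `chosen`.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(protein, res, path) {
  stopifnot(inherits(res, "motif_order"))
  all_hits <- do.call(rbind, lapply(c("A", "B", "C"), function(m) {
    h <- scan_motif(substr(protein, res$region[1], res$region[2]), m)
    if (nrow(h) > 0L) {
      h$start <- h$start + res$region[1] - 1L
      h$end <- h$end + res$region[1] - 1L
    }
    h
  }))
  if (is.null(all_hits)) {
    all_hits <- data.frame(motif = character(), start = integer(),
                           end = integer(), matched = character())
  }
  key <- if (!is.null(res$hits)) {
    paste(res$hits$motif, res$hits$start, res$hits$end)
  } else character()
  all_hits$chosen <- paste(all_hits$motif, all_hits$start, all_hits$end) %in% key
  utils::write.table(all_hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
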