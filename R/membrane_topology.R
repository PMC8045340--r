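# Kyte-Doolittle hydropathy scale; X (ambiguous) scores 0.
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
  X =  0.0)

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' @param protein Amino-acid string without internal stops; a single
#'   trailing `*` is stripped.
#' @param window Odd window width in residues (default 19, the classic
#'   transmembrane-helix setting).
#' @return Object of class `hydropathy_profile`: data.frame with columns
#'   `center` (1-based residue position of the window center) and `value`
#'   (windowed mean hydropathy), plus attribute `window`. Profile length is
#'   `nchar(protein) - window + 1`.
#' @export
hydropathy_profile <- function(protein, window = 19L) {
  protein <- sub("\\*$", "", toupper(protein))
  if (grepl("*", protein, fixed = TRUE)) stop("internal stop in protein")
  window <- as.integer(window)
  L <- nchar(protein)
  if (window %% 2L == 0L) stop("parameter error: window must be odd")
  if (window > L) stop("parameter error: window exceeds protein length")
  res <- strsplit(protein, "")[[1]]
  unknown <- !(res %in% names(KD_SCALE))
  if (any(unknown)) stop("residues without hydropathy value: ",
                         paste(unique(res[unknown]), collapse = ", "))
  v <- KD_SCALE[res]
  cs <- c(0, cumsum(v))
  means <- (cs[(window + 1L):(L + 1L)] - cs[1:(L - window + 1L)]) / window
  half <- (window - 1L) %/% 2L
  out <- data.frame(center = (half + 1L):(L - half), value = unname(means))
  attr(out, "window") <- window
  class(out) <- c("hydropathy_profile", "data.frame")
  out
}

#' Predict transmembrane segments by hydropathy scanning
#'
#' Finds maximal runs of window centers whose windowed mean hydropathy is
#' at least `threshold`, expands each run to the full extent of its
#' windows, and merges expansions that overlap or abut (so one helix split
#' by a single-residue dip is not double-counted).
#'
#' @inheritParams hydropathy_profile
#' @param threshold Minimum windowed hydropathy (default 1.6, the classic
#'   cutoff for transmembrane detection).
#' @return data.frame with columns `start`, `end` (1-based inclusive
#'   residue interval, length >= `window`), `length`, `peak` (maximal
#'   windowed hydropathy inside); zero rows when nothing crosses the
#'   threshold. Segments are non-overlapping and sorted.
#' @export
predict_tm <- function(protein, window = 19L, threshold = 1.6) {
  prof <- hydropathy_profile(protein, window = window)
  half <- (window - 1L) %/% 2L
  above <- prof$value >= threshold
  empty <- data.frame(start = integer(), end = integer(),
                      length = integer(), peak = numeric())
  if (!any(above)) return(empty)
  r <- rle(above)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  runs <- data.frame(from = starts[r$values], to = stops[r$values])
  seg <- data.frame(start = prof$center[runs$from] - half,
                    end = prof$center[runs$to] + half)
  # merge expanded extents that overlap or abut
  merged <- seg[1L, , drop = FALSE]
  if (nrow(seg) > 1L) {
    for (i in 2:nrow(seg)) {
      last <- nrow(merged)
      if (seg$start[i] <= merged$end[last] + 1L) {
        merged$end[last] <- max(merged$end[last], seg$end[i])
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }
  merged$length <- merged$end - merged$start + 1L
  merged$peak <- vapply(seq_len(nrow(merged)), function(i) {
    inside <- prof$center >= merged$start[i] & prof$center <= merged$end[i]
    max(prof$value[inside])
  }, numeric(1))
  rownames(merged) <- NULL
  merged
}

#' Write transmembrane segments as TSV
#'
#' @param segments Output of [predict_tm()].
#' @param path Output path; columns `start`, `end`, `length`, `peak`.
#' @return `path`, invisibly.
#' @export
write_tm_table <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
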