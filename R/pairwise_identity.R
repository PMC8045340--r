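#' Alignment scoring scheme
#'
#' Affine gap cost convention: a gap of length `L` costs
#' `gap_open + gap_extend * (L - 1)`. Defaults follow common practice:
#' BLOSUM62 / open 10 / extend 0.5 for protein, match +5 / mismatch -4 /
#' open 10 / extend 0.5 for nucleotide.
#'
#' @param kind `"protein"` or `"nucleotide"`.
#' @param match,mismatch Nucleotide match/mismatch scores (ignored for
#'   protein, which uses BLOSUM62).
#' @param gap_open,gap_extend Affine gap penalties (non-negative,
#'   `gap_open >= gap_extend`).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(kind = c("protein", "nucleotide"), match = 5,
                           mismatch = -4, gap_open = 10, gap_extend = 0.5) {
  kind <- match.arg(kind)
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  if (kind == "protein") {
    mat <- get_blosum62()
  } else {
    letters <- c("A", "C", "G", "T", "N")
    mat <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
    diag(mat) <- match
    mat["N", ] <- mismatch
    mat[, "N"] <- mismatch
  }
  structure(list(kind = kind, substitution = mat, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Optimal global alignment with affine gaps
#'
#' Needleman-Wunsch global alignment via
#' [Biostrings::pairwiseAlignment()], with the scheme's gap convention
#' (gap of length L costs `open + extend*(L-1)`).
#'
#' @param a,b Sequences (character) in the scheme's alphabet.
#' @param scheme A [scoring_scheme()].
#' @return Object of class `pairwise_alignment`: `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `n_identical`,
#'   `n_aligned_cols` (columns with no gap in either row).
#' @export
global_align <- function(a, b, scheme = scoring_scheme("nucleotide")) {
  stopifnot(inherits(scheme, "scoring_scheme"), nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  ok <- rownames(scheme$substitution)
  for (s in c(a, b)) {
    res <- unique(strsplit(s, "")[[1]])
    if (!all(res %in% ok)) {
      stop("alphabet mismatch: sequence contains ",
           paste(setdiff(res, ok), collapse = ","),
           " not scored by the ", scheme$kind, " scheme")
    }
  }
  mk <- if (scheme$kind == "protein") Biostrings::AAString else
    Biostrings::DNAString
  pa <- Biostrings::pairwiseAlignment(
    mk(a), mk(b), type = "global",
    substitutionMatrix = scheme$substitution,
    gapOpening = scheme$gap_open - scheme$gap_extend,
    gapExtension = scheme$gap_extend)
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  out <- structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                        score = Biostrings::score(pa),
                        n_identical = sum(both & ca == cb),
                        n_aligned_cols = sum(both)),
                   class = "pairwise_alignment")
  stopifnot(gsub("-", "", aligned_a, fixed = TRUE) == a,
            gsub("-", "", aligned_b, fixed = TRUE) == b)
  out
}

#' Percent identity of an alignment
#'
#' Default denominator is the number of aligned columns with no gap in
#' either sequence; alternatives (shorter input length; full alignment
#' length) are offered because identity conventions differ between
#' alignment viewers.
#'
#' @param aln A `pairwise_alignment`.
#' @param denominator `"aligned"` (default), `"shorter"` or `"full"`.
#' @return Percent identity in `[0, 100]`, rounded to 1 decimal.
#' @export
percent_identity <- function(aln,
                             denominator = c("aligned", "shorter", "full")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(aln, "pairwise_alignment"))
  den <- switch(denominator,
    aligned = aln$n_aligned_cols,
    shorter = min(nchar(gsub("-", "", aln$aligned_a, fixed = TRUE)),
                  nchar(gsub("-", "", aln$aligned_b, fixed = TRUE))),
    full = nchar(aln$aligned_a))
  if (den == 0L) stop("undefined identity: no aligned columns")
  round(100 * aln$n_identical / den, 1)
}

#' Pairwise percent-identity matrices over a labeled sequence set
#'
#' Aligns every unordered pair globally and fills symmetric matrices
#' (diagonal 100).
#'
#' @param aa_seqs Named character vector of protein sequences, or `NULL`.
#' @param nt_seqs Named character vector of nucleotide sequences, or
#'   `NULL`. When both are given the label sets must match.
#' @param aa_scheme,nt_scheme Scoring schemes.
#' @param denominator Passed to [percent_identity()].
#' @return Object of class `identity_matrix`: `labels`, `aa`, `nt`
#'   (symmetric percent matrices or `NULL`).
#' @export
build_identity_matrix <- function(aa_seqs = NULL, nt_seqs = NULL,
                                  aa_scheme = scoring_scheme("protein"),
                                  nt_scheme = scoring_scheme("nucleotide"),
                                  denominator = "aligned") {
  if (is.null(aa_seqs) && is.null(nt_seqs)) stop("no sequences given")
  if (!is.null(aa_seqs) && !is.null(nt_seqs)) {
    missing <- setdiff(names(aa_seqs), names(nt_seqs))
    missing <- c(missing, setdiff(names(nt_seqs), names(aa_seqs)))
    if (length(missing)) {
      stop("labels missing a matched aa/nt sequence: ",
           paste(unique(missing), collapse = ", "))
    }
  }
  labels <- names(if (is.null(aa_seqs)) nt_seqs else aa_seqs)
  if (length(labels) < 2L) stop("need at least 2 sequences")
  fill <- function(seqs, scheme) {
    if (is.null(seqs)) return(NULL)
    seqs <- seqs[labels]
    n <- length(labels)
    m <- matrix(100, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        pid <- percent_identity(global_align(seqs[[i]], seqs[[j]], scheme),
                                denominator = denominator)
        m[i, j] <- m[j, i] <- pid
      }
    }
    m
  }
  out <- structure(list(labels = labels,
                        aa = fill(aa_seqs, aa_scheme),
                        nt = fill(nt_seqs, nt_scheme)),
                   class = "identity_matrix")
  validate_identity_matrix(out)
  out
}

#' Validate an identity matrix object
#'
#' Symmetry within 1e-9, entries in `[0, 100]`, matching dimnames.
#'
#' @param m An `identity_matrix`.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_identity_matrix <- function(m) {
  stopifnot(inherits(m, "identity_matrix"))
  for (w in c("aa", "nt")) {
    x <- m[[w]]
    if (is.null(x)) next
    stopifnot(identical(rownames(x), m$labels),
              identical(colnames(x), m$labels),
              max(abs(x - t(x))) < 1e-9,
              all(x >= 0), all(x <= 100))
  }
  invisible(TRUE)
}

#' Parse a half-triangle identity table
#'
#' Reads a TSV holding an `n x n` identity table in the journal convention:
#' first column taxon label, upper triangle amino-acid identities, lower
#' triangle nucleotide identities, diagonal `*` (read as 100). Both
#' matrices are symmetrized from their half-triangles.
#'
#' @param path TSV path. Use [inlv1_identity_table_path()] for the
#'   packaged RdRP-domain table of INLV1 and 17 related nege/kita-like
#'   viruses.
#' @return An `identity_matrix` with both `aa` and `nt` filled.
#' @export
parse_identity_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           row.names = 1, comment.char = "")
  labels <- rownames(raw)
  if (!identical(labels, colnames(raw))) {
    stop("format error: row and column labels differ")
  }
  n <- length(labels)
  x <- as.matrix(raw)
  aa <- nt <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        if (!(x[i, j] %in% c("*", "100", "100.0"))) {
          stop("format error: diagonal must be '*' or 100")
        }
        next
      }
      v <- suppressWarnings(as.numeric(x[i, j]))
      if (is.na(v)) stop("format error: non-numeric cell at ", labels[i],
                         "/", labels[j])
      if (i < j) {
        aa[i, j] <- aa[j, i] <- v
      } else {
        nt[i, j] <- nt[j, i] <- v
      }
    }
  }
  out <- structure(list(labels = labels, aa = aa, nt = nt),
                   class = "identity_matrix")
  validate_identity_matrix(out)
  out
}

#' Path to the packaged INLV1 RdRP identity table
#'
#' An 18-taxon amino-acid (upper triangle) / nucleotide (lower triangle)
#' percent-identity table of the RdRP domain of INLV1 and related
#' nege/kita-like viruses, transcribed from the published comparison.
#'
#' @return File path within the installed package.
#' @export
inlv1_identity_table_path <- function() {
  system.file("extdata", "table1_rdrp_identity.tsv", package = "negeseek",
              mustWork = TRUE)
}

#' Write identity matrices as TSV
#'
#' @param m An `identity_matrix`.
#' @param prefix Output path prefix; writes `<prefix>_aa.tsv` /
#'   `<prefix>_nt.tsv` for the matrices present.
#' @return Character vector of written paths, invisibly.
#' @export
write_identity_matrix <- function(m, prefix) {
  validate_identity_matrix(m)
  paths <- character()
  for (w in c("aa", "nt")) {
    if (is.null(m[[w]])) next
    p <- paste0(prefix, "_", w, ".tsv")
    utils::write.table(m[[w]], p, sep = "\t", quote = FALSE,
                       col.names = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Neighbor-joining tree from an identity matrix
#'
#' Converts identities to distances `d = (100 - identity) / 100` and runs
#' standard neighbor joining (Saitou-Nei Q-criterion, via [ape::nj()]).
#' Negative branch lengths are clamped to 0 and flagged.
#'
#' @param m An `identity_matrix` (or a plain symmetric numeric percent
#'   matrix with dimnames).
#' @param which `"aa"` or `"nt"` (ignored for a plain matrix).
#' @return An [ape::phylo] tree (unrooted) with attribute
#'   `"clamped_branches"`, the number of negative branch lengths clamped.
#' @export
nj_tree <- function(m, which = c("aa", "nt")) {
  which <- match.arg(which)
  x <- if (inherits(m, "identity_matrix")) m[[which]] else m
  if (is.null(x)) stop("matrix '", which, "' not present")
  if (nrow(x) < 3L) stop("need at least 3 taxa")
  if (max(abs(x - t(x))) > 1e-9) stop("non-symmetric identity matrix")
  d <- (100 - x) / 100
  diag(d) <- 0
  tr <- ape::nj(stats::as.dist(d))
  n_neg <- sum(tr$edge.length < 0)
  if (n_neg > 0L) tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_branches") <- n_neg
  tr
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with 6 decimals; unrooted trees keep their
#' trifurcating root.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Tips of the smallest clade containing a focal taxon
#'
#' For an unrooted tree, roots at the leaf farthest (by path length) from
#' the focal taxon, then returns the tip labels descending from the focal
#' tip's parent node — the focal taxon's smallest containing clade.
#'
#' @param tree An [ape::phylo] tree.
#' @param taxon Focal tip label.
#' @return Character vector of tip labels (includes `taxon`).
#' @export
smallest_clade_tips <- function(tree, taxon) {
  stopifnot(taxon %in% tree$tip.label)
  dm <- ape::cophenetic.phylo(tree)
  far <- names(which.max(dm[taxon, setdiff(colnames(dm), taxon)]))
  rooted <- ape::root(tree, outgroup = far, resolve.root = TRUE)
  tip <- which(rooted$tip.label == taxon)
  parent <- rooted$edge[rooted$edge[, 2] == tip, 1]
  sub <- ape::extract.clade(rooted, parent)
  sub$tip.label
}
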