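# One fixed codon per amino acid, used when writing planted features.
AA_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

# Amino-acid sequences written for planted RdRP motifs (X positions filled
# with standard residues).
MOTIF_PLANT <- c(A = "DIVSLD", B = "GAVTSKAN", C = "GDD")

# Strongly hydrophilic residues used for transmembrane island shoulders.
HYDROPHILIC <- c("R", "K", "D", "E", "N", "Q")

#' Configuration for a synthetic viral genome
#'
#' Describes a positive-sense genome with planted major ORFs, optional
#' RdRP motifs in a designated ORF, optional transmembrane islands
#' (alanine stretches with enforced hydrophilic 9-residue shoulders, so a
#' 19-residue / 1.6-threshold hydropathy scan recovers the configured
#' interval exactly), and an optional poly(A) tail.
#'
#' @param length Core genome length in nt (poly(A) excluded).
#' @param gc GC fraction of the background (default 0.5).
#' @param orfs List of `c(start, end)` 1-based inclusive nt intervals;
#'   frames follow from the starts; `end` is the last base of the stop.
#' @param motif_order `"C-A-B"`, `"A-B-C"` or `"none"`.
#' @param motif_orf Index (into `orfs`) of the ORF carrying the motifs.
#' @param motif_positions Named integer vector (`A`, `B`, `C`) of 1-based
#'   start residues of each motif in the motif ORF's protein; `NULL`
#'   auto-places them around 3/4 of the protein, 50 residues apart, in the
#'   configured order.
#' @param tm_orf Index of the ORF carrying transmembrane islands.
#' @param tm_islands List of `c(start, end)` 1-based residue intervals.
#' @param polya_len Poly(A) tail length appended after `length` nt.
#' @param suppress_min_codons ORF-length threshold (codons) above which
#'   non-planted ORFs are mutated away (default 150, the annotation
#'   default).
#' @param seed RNG seed; generation is deterministic per seed.
#' @return A list of class `genome_config`.
#' @export
genome_config <- function(length = 8945L, gc = 0.5,
                          orfs = list(c(45L, 6908L)),
                          motif_order = c("none", "C-A-B", "A-B-C"),
                          motif_orf = 1L, motif_positions = NULL,
                          tm_orf = base::length(orfs), tm_islands = list(),
                          polya_len = 0L, suppress_min_codons = 150L,
                          seed = 1L) {
  motif_order <- match.arg(motif_order)
  length <- as.integer(length)
  stopifnot(length >= 100L, gc > 0, gc < 1, base::length(orfs) >= 1L)
  orfs <- do.call(rbind, lapply(orfs, function(o) {
    stopifnot(base::length(o) == 2L, o[1] >= 1L, o[2] <= length,
              (o[2] - o[1] + 1L) %% 3L == 0L, o[2] - o[1] + 1L >= 9L)
    data.frame(start = as.integer(o[1]), end = as.integer(o[2]))
  }))
  stopifnot(!is.unsorted(orfs$start, strictly = TRUE))
  orfs$frame <- (orfs$start - 1L) %% 3L + 1L
  orfs$plen <- (orfs$end - orfs$start + 1L) %/% 3L - 1L
  if (motif_order != "none") {
    stopifnot(motif_orf >= 1L, motif_orf <= nrow(orfs))
    plen <- orfs$plen[motif_orf]
    if (is.null(motif_positions)) {
      anchor <- as.integer(plen * 0.75)
      ord <- strsplit(motif_order, "-", fixed = TRUE)[[1]]
      motif_positions <- stats::setNames(anchor + 50L * (seq_along(ord) - 1L),
                                         ord)
    }
    stopifnot(all(c("A", "B", "C") %in% names(motif_positions)))
    ends <- motif_positions + nchar(MOTIF_PLANT[names(motif_positions)]) - 1L
    stopifnot(all(motif_positions >= 1L), all(ends <= plen))
    if (any(motif_positions <= plen %/% 2L)) {
      warning("planted motifs outside the C-terminal half; the default ",
              "classification region will not see them")
    }
    ord_by_pos <- paste(names(sort(motif_positions)), collapse = "-")
    if (ord_by_pos != motif_order) {
      stop("config error: motif_positions imply order ", ord_by_pos,
           " but motif_order is ", motif_order)
    }
    gaps <- diff(sort(motif_positions)) -
      nchar(MOTIF_PLANT[names(sort(motif_positions))])[-3L]
    if (any(gaps < 5L) || any(gaps > 300L)) {
      stop("config error: planted motif gaps must lie in [5, 300] residues")
    }
  }
  if (base::length(tm_islands) > 0L) {
    stopifnot(tm_orf >= 1L, tm_orf <= nrow(orfs))
    plen <- orfs$plen[tm_orf]
    tm <- do.call(rbind, lapply(tm_islands, function(x) {
      data.frame(start = as.integer(x[1]), end = as.integer(x[2]))
    }))
    tm <- tm[order(tm$start), , drop = FALSE]
    stopifnot(all(tm$end - tm$start + 1L >= 19L),
              all(tm$start >= 11L), all(tm$end <= plen - 10L))
    if (nrow(tm) > 1L && any(tm$start[-1L] - tm$end[-nrow(tm)] - 1L < 10L)) {
      stop("config error: transmembrane islands must be separated by >= 10 aa")
    }
    tm_islands <- lapply(seq_len(nrow(tm)), function(i) {
      c(tm$start[i], tm$end[i])
    })
  }
  # planted features must not reach into another ORF: writing their codons
  # there would clobber that ORF's frame (e.g. a TM island overwriting the
  # upstream ORF's stop codon inside an overlap)
  aa_span_nt <- function(orf_i, aa_lo, aa_hi) {
    c(orfs$start[orf_i] + 3L * (aa_lo - 1L),
      orfs$start[orf_i] + 3L * (aa_hi - 1L) + 2L)
  }
  check_clear <- function(owner, aa_lo, aa_hi, what) {
    span <- aa_span_nt(owner, aa_lo, aa_hi)
    for (j in seq_len(nrow(orfs))) {
      if (j == owner) next
      if (span[1] <= orfs$end[j] && span[2] >= orfs$start[j]) {
        stop("config error: ", what, " (nt ", span[1], "-", span[2],
             ") overlaps ORF", j, "; move it clear of the overlap region")
      }
    }
  }
  if (motif_order != "none") {
    for (m in names(motif_positions)) {
      check_clear(motif_orf, motif_positions[[m]],
                  motif_positions[[m]] + nchar(MOTIF_PLANT[[m]]) - 1L,
                  paste("planted motif", m))
    }
  }
  for (isl in tm_islands) {
    check_clear(tm_orf, max(2L, isl[1] - 9L),
                min(orfs$plen[tm_orf], isl[2] + 9L),
                "planted transmembrane island (with shoulders)")
  }
  structure(list(length = length, gc = gc, orfs = orfs,
                 motif_order = motif_order, motif_orf = as.integer(motif_orf),
                 motif_positions = motif_positions,
                 tm_orf = as.integer(tm_orf), tm_islands = tm_islands,
                 polya_len = as.integer(polya_len),
                 suppress_min_codons = as.integer(suppress_min_codons),
                 seed = as.integer(seed)),
            class = "genome_config")
}

#' Genome configuration mirroring the INLV1 organization
#'
#' A 8945-nt positive-sense genome with three partially overlapping major
#' ORFs (ORF1 45-6908 nt, 2287-aa polyprotein; ORF2 overlapping ORF1 by
#' 263 nt in a different frame; ORF3 ending at 8847 nt so the 3' UTR spans
#' 8848-8945), permuted C-A-B RdRP motifs planted in the C-terminal region
#' of the ORF1 product, and four transmembrane islands at residues 68-87,
#' 107-126, 138-157 and 177-196 of the ORF3 product. Spurious ORFs are
#' suppressed down to 50 codons so annotation of the generated genome is
#' insensitive to the ORF-length threshold over its useful range.
#'
#' @param seed RNG seed.
#' @return A [genome_config()].
#' @export
inlv1_like_config <- function(seed = 1L) {
  genome_config(
    length = 8945L, gc = 0.5,
    orfs = list(c(45L, 6908L), c(6646L, 8187L), c(8197L, 8847L)),
    motif_order = "C-A-B", motif_orf = 1L,
    motif_positions = c(C = 1900L, A = 1950L, B = 2000L),
    tm_orf = 3L,
    tm_islands = list(c(68L, 87L), c(107L, 126L), c(138L, 157L),
                      c(177L, 196L)),
    polya_len = 0L, suppress_min_codons = 50L, seed = seed)
}

#' Generate a synthetic genome with known ground truth
#'
#' Samples background nucleotides at the configured GC, writes ATG starts
#' and TAA stops for every configured ORF, plants motifs and
#' transmembrane islands at their residue positions, then iterates a
#' repair loop until the construction is self-consistent: internal stops
#' inside planted ORFs are recoded; plus-strand ORFs of at least
#' `suppress_min_codons` codons other than the planted ones are mutated
#' away (start codon broken, or an early in-frame stop inserted when the
#' start is protected); spurious motif hits inside the classification
#' region of the motif ORF and spurious hydrophobic windows in the
#' transmembrane ORF are scrubbed. Planted positions are never touched.
#' Deterministic per `cfg$seed`.
#'
#' @param cfg A [genome_config()].
#' @param id Sequence id for the generated record.
#' @return A list: `genome` (a [genome_record()], poly(A) appended) and
#'   `truth` (configured coordinates, UTR lengths, motif and island
#'   positions, and the planted proteins).
#' @export
gen_genome <- function(cfg, id = "synthetic_genome") {
  stopifnot(inherits(cfg, "genome_config"))
  set.seed(cfg$seed)
  L <- cfg$length
  orfs <- cfg$orfs
  g <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
              prob = c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2,
                       (1 - cfg$gc) / 2))
  protected <- logical(L)

  orf_nt <- function(orf_i, aa_start) orfs$start[orf_i] + 3L * (aa_start - 1L)
  write_codons <- function(orf_i, aa_start, aa_str, protect = TRUE) {
    res <- strsplit(aa_str, "")[[1]]
    for (k in seq_along(res)) {
      p <- orf_nt(orf_i, aa_start + k - 1L)
      g[p:(p + 2L)] <<- strsplit(AA_CODON[[res[k]]], "")[[1]]
      if (protect) protected[p:(p + 2L)] <<- TRUE
    }
  }
  for (i in seq_len(nrow(orfs))) {
    g[orfs$start[i]:(orfs$start[i] + 2L)] <- c("A", "T", "G")
    g[(orfs$end[i] - 2L):orfs$end[i]] <- c("T", "A", "A")
    protected[orfs$start[i]:(orfs$start[i] + 2L)] <- TRUE
    protected[(orfs$end[i] - 2L):orfs$end[i]] <- TRUE
  }
  if (cfg$motif_order != "none") {
    for (m in names(cfg$motif_positions)) {
      write_codons(cfg$motif_orf, cfg$motif_positions[[m]], MOTIF_PLANT[[m]])
    }
  }
  if (length(cfg$tm_islands) > 0L) {
    plen <- orfs$plen[cfg$tm_orf]
    for (isl in cfg$tm_islands) {
      write_codons(cfg$tm_orf, isl[1], strrep("A", isl[2] - isl[1] + 1L))
      sh_left <- max(1L, isl[1] - 9L):(isl[1] - 1L)
      sh_right <- (isl[2] + 1L):min(plen, isl[2] + 9L)
      for (p in c(sh_left, sh_right)) {
        write_codons(cfg$tm_orf, p,
                     sample(HYDROPHILIC, 1L))
      }
    }
  }

  # --- repair machinery ---------------------------------------------------
  codon_of <- function(orf_i, pos) {
    # start of the codon (in orf_i's frame) containing genome position pos
    orfs$start[orf_i] + ((pos - orfs$start[orf_i]) %/% 3L) * 3L
  }
  makes_forbidden_stop <- function(pos) {
    # would the current base at pos leave a stop codon inside any planted
    # ORF (terminal stop codons are protected and never reach here)?
    for (i in seq_len(nrow(orfs))) {
      if (pos >= orfs$start[i] && pos <= orfs$end[i] - 3L) {
        cs <- codon_of(i, pos)
        if (paste(g[cs:(cs + 2L)], collapse = "") %in% STOP_CODONS) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  try_set <- function(pos, base) {
    # set g[pos] <- base unless protected or it creates an internal stop
    if (protected[pos] || g[pos] == base) return(FALSE)
    old <- g[pos]
    g[pos] <<- base
    if (makes_forbidden_stop(pos)) {
      g[pos] <<- old
      return(FALSE)
    }
    TRUE
  }
  gc_table <- Biostrings::GENETIC_CODE
  synonyms <- split(names(gc_table), unname(gc_table))
  covering_codons <- function(pos) {
    # planted-ORF codons (orf index, codon start) containing position pos
    out <- list()
    for (i in seq_len(nrow(orfs))) {
      if (pos >= orfs$start[i] && pos <= orfs$end[i]) {
        out[[length(out) + 1L]] <- c(i, codon_of(i, pos))
      }
    }
    out
  }
  try_syn_recode <- function(pos, goal_ok) {
    # recode the planted codon owning `pos` synonymously (amino acid kept,
    # so planted features are untouched) until goal_ok() holds; positions
    # covered by two planted ORFs at once are left alone
    cov <- covering_codons(pos)
    if (length(cov) != 1L) return(FALSE)
    cs <- cov[[1L]][2L]
    cur <- paste(g[cs:(cs + 2L)], collapse = "")
    aa <- gc_table[[cur]]
    for (alt in setdiff(synonyms[[aa]], cur)) {
      old <- g[cs:(cs + 2L)]
      g[cs:(cs + 2L)] <<- strsplit(alt, "")[[1]]
      ok <- goal_ok()
      if (ok) {
        for (q in cs:(cs + 2L)) if (makes_forbidden_stop(q)) ok <- FALSE
      }
      if (ok) return(TRUE)
      g[cs:(cs + 2L)] <<- old
    }
    FALSE
  }
  break_codon <- function(cstart, avoid) {
    # change one base so that the codon at cstart is no longer `avoid`
    for (off in c(0L, 1L, 2L)) {
      p <- cstart + off
      for (b in setdiff(c("A", "C", "G", "T"), g[p])) {
        old <- g[p]
        if (try_set(p, b)) {
          if (paste(g[cstart:(cstart + 2L)], collapse = "") != avoid) {
            return(TRUE)
          }
          g[p] <<- old
        }
      }
    }
    # all three positions protected: a synonymous recode of the planted
    # codon that owns one of them may still break the target codon
    still_avoid <- function() {
      paste(g[cstart:(cstart + 2L)], collapse = "") != avoid
    }
    for (off in c(0L, 1L, 2L)) {
      if (try_syn_recode(cstart + off, still_avoid)) return(TRUE)
    }
    FALSE
  }
  write_codon_checked <- function(orf_i, aa_pos, res) {
    # rewrite one codon of orf_i to residue `res`; revert on violation
    p <- orf_nt(orf_i, aa_pos)
    if (any(protected[p:(p + 2L)])) return(FALSE)
    old <- g[p:(p + 2L)]
    g[p:(p + 2L)] <<- strsplit(AA_CODON[[res]], "")[[1]]
    for (q in p:(p + 2L)) {
      if (makes_forbidden_stop(q)) {
        g[p:(p + 2L)] <<- old
        return(FALSE)
      }
    }
    TRUE
  }
  translate_orf <- function(orf_i) {
    sub("\\*$", "",
        translate_dna(paste(g[orfs$start[orf_i]:orfs$end[orf_i]],
                            collapse = "")))
  }
  planted_key <- paste(orfs$start, orfs$end)

  motif_protect_aa <- if (cfg$motif_order != "none") {
    unlist(lapply(names(cfg$motif_positions), function(m) {
      cfg$motif_positions[[m]] +
        seq_len(nchar(MOTIF_PLANT[[m]])) - 1L
    }))
  } else integer()
  tm_protect_aa <- if (length(cfg$tm_islands) > 0L) {
    unlist(lapply(cfg$tm_islands, function(isl) {
      max(1L, isl[1] - 9L):min(orfs$plen[cfg$tm_orf], isl[2] + 9L)
    }))
  } else integer()

  for (iter in seq_len(80L)) {
    changed <- FALSE
    # 1. recode internal stops within planted ORFs
    for (i in seq_len(nrow(orfs))) {
      cods <- seq(orfs$start[i], orfs$end[i] - 3L, by = 3L)
      for (cs in cods) {
        cod <- paste(g[cs:(cs + 2L)], collapse = "")
        if (cod %in% STOP_CODONS) {
          if (!break_codon(cs, cod)) {
            stop("config error: cannot recode internal stop at nt ", cs)
          }
          changed <- TRUE
        }
      }
    }
    if (changed) next
    # 2. suppress spurious long ORFs (including upstream in-frame ATG
    #    extensions of planted ORFs)
    rec <- genome_record(id, paste(g, collapse = ""))
    fo <- find_orfs(rec, min_len_codons = cfg$suppress_min_codons)
    spurious <- fo[!(paste(fo$start, fo$end) %in% planted_key), ,
                   drop = FALSE]
    for (k in seq_len(nrow(spurious))) {
      s <- spurious$start[k]
      if (break_codon(s, "ATG")) {
        changed <- TRUE
      } else {
        # start codon protected: plant an early in-frame stop instead
        done <- FALSE
        for (cs in seq(s, spurious$end[k] - 3L, by = 3L)) {
          old <- g[cs:(cs + 2L)]
          if (!any(protected[cs:(cs + 2L)])) {
            ok <- TRUE
            g[cs:(cs + 2L)] <- c("T", "A", "A")
            for (q in cs:(cs + 2L)) if (makes_forbidden_stop(q)) ok <- FALSE
            if (ok) { done <- TRUE; changed <- TRUE; break }
            g[cs:(cs + 2L)] <- old
          }
        }
        if (!done) stop("config error: cannot suppress spurious ORF at nt ",
                        s)
      }
    }
    if (changed) next
    # 3. scrub spurious motif hits in the classification region
    if (cfg$motif_order != "none") {
      prot <- translate_orf(cfg$motif_orf)
      plen <- nchar(prot)
      region <- c(plen %/% 2L + 1L, plen)
      for (m in c("A", "B", "C")) {
        hits <- scan_motif(substr(prot, region[1], region[2]), m)
        if (nrow(hits) == 0L) next
        hits$start <- hits$start + region[1] - 1L
        hits$end <- hits$end + region[1] - 1L
        pm <- cfg$motif_positions[[m]]
        pk <- paste(pm, pm + nchar(MOTIF_PLANT[[m]]) - 1L)
        for (h in seq_len(nrow(hits))) {
          if (paste(hits$start[h], hits$end[h]) == pk) next
          w <- hits$end[h] - hits$start[h] + 1L
          # mutating a fixed-match position is what breaks the pattern
          fixed_off <- switch(m, A = c(1L, w), B = c(1L, w - 4L, w),
                              C = 1:3)
          for (off in fixed_off) {
            aa <- hits$start[h] + off - 1L
            if (aa %in% motif_protect_aa) next
            res <- if (substr(prot, aa, aa) == "R") "E" else "R"
            if (write_codon_checked(cfg$motif_orf, aa, res)) {
              prot <- translate_orf(cfg$motif_orf)
              changed <- TRUE
              break
            }
          }
        }
      }
    }
    if (changed) next
    # 4. scrub spurious hydrophobic windows in the transmembrane ORF
    if (length(cfg$tm_islands) > 0L) {
      prot <- translate_orf(cfg$tm_orf)
      pr <- hydropathy_profile(prot, window = 19L)
      island_centers <- unlist(lapply(cfg$tm_islands, function(isl) {
        (isl[1] + 9L):(isl[2] - 9L)
      }))
      bad <- pr$center[pr$value >= 1.6 & !(pr$center %in% island_centers)]
      for (c0 in bad) {
        for (aa in max(1L, c0 - 9L):min(nchar(prot), c0 + 9L)) {
          if (aa %in% tm_protect_aa) next
          if (substr(prot, aa, aa) %in% HYDROPHILIC) next
          if (write_codon_checked(cfg$tm_orf, aa, "R")) {
            prot <- translate_orf(cfg$tm_orf)
            changed <- TRUE
            break
          }
        }
      }
    }
    if (!changed) break
  }
  if (changed) stop("config error: genome construction did not converge")

  core <- paste(g, collapse = "")
  seq_full <- if (cfg$polya_len > 0L) {
    paste0(core, strrep("A", cfg$polya_len))
  } else core
  genome <- genome_record(id, seq_full, "synthetic nege-like genome")
  truth <- list(
    core_length = L,
    orfs = orfs,
    utr5_len = orfs$start[1L] - 1L,
    utr3_len = L - orfs$end[nrow(orfs)],
    motif_order = cfg$motif_order,
    motif_orf = cfg$motif_orf,
    motif_positions = cfg$motif_positions,
    tm_orf = cfg$tm_orf,
    tm_islands = cfg$tm_islands,
    polya_len = cfg$polya_len,
    proteins = vapply(seq_len(nrow(orfs)), function(i) translate_orf(i),
                      character(1)))
  list(genome = genome, truth = truth)
}

#' Configuration for a synthetic small-RNA library
#'
#' Default parameters emulate the vsiRNA structure typical of an actively
#' replicating insect virus: a 22-nt modal length carrying 69% of the
#' reads, balanced strands, 80% 5'-terminal A/U, and a 4:1 background of
#' non-viral reads.
#'
#' @param n_viral Number of genome-derived reads (default 20000).
#' @param n_background Number of non-viral reads (default 80000), random
#'   sequences verified absent from both genome strands.
#' @param length_dist Named probability vector over read lengths 18-30 nt
#'   (must sum to 1); the default puts 0.69 on 22 nt.
#' @param strand_prob Probability a viral read derives from the plus
#'   strand (default 0.5).
#' @param five_prime_au_prob Target probability that a viral read's
#'   5'-terminal nucleotide is A or U (default 0.8), met by rejection
#'   sampling of start positions.
#' @param hotspot Optional `list(start =, end =, weight =)`: genomic
#'   interval whose positions are `weight` times more likely to seed a
#'   read's 5' end.
#' @param seed RNG seed.
#' @return A list of class `read_config`.
#' @export
read_config <- function(n_viral = 20000L, n_background = 80000L,
                        length_dist = NULL, strand_prob = 0.5,
                        five_prime_au_prob = 0.8, hotspot = NULL,
                        seed = 1L) {
  if (is.null(length_dist)) {
    length_dist <- c(`18` = 0.01, `19` = 0.02, `20` = 0.04, `21` = 0.10,
                     `22` = 0.69, `23` = 0.08, `24` = 0.03, `25` = 0.01,
                     `26` = 0.005, `27` = 0.005, `28` = 0.005,
                     `29` = 0.0025, `30` = 0.0025)
  }
  stopifnot(abs(sum(length_dist) - 1) < 1e-9,
            all(as.integer(names(length_dist)) >= 18L),
            all(as.integer(names(length_dist)) <= 30L),
            strand_prob >= 0, strand_prob <= 1,
            five_prime_au_prob >= 0, five_prime_au_prob <= 1)
  if (!is.null(hotspot)) {
    stopifnot(is.list(hotspot), all(c("start", "end", "weight") %in%
                                      names(hotspot)),
              hotspot$weight > 0)
  }
  structure(list(n_viral = as.integer(n_viral),
                 n_background = as.integer(n_background),
                 length_dist = length_dist, strand_prob = strand_prob,
                 five_prime_au_prob = five_prime_au_prob,
                 hotspot = hotspot, seed = as.integer(seed)),
            class = "read_config")
}

#' Generate a synthetic small-RNA library with per-read truth
#'
#' Viral reads are exact substrings of the genome (plus strand) or of its
#' reverse complement (minus strand), with lengths drawn from
#' `length_dist`, strands Bernoulli(`strand_prob`), 5'-end positions
#' uniform (or hotspot-weighted), rejection-sampled so the realized
#' 5'-terminal A/U frequency follows `five_prime_au_prob`. Background
#' reads are random sequences verified to match neither genome strand.
#'
#' @param genome A [genome_record()].
#' @param cfg A [read_config()].
#' @return A list: `reads` (a `read_set`, see [read_reads()]) and `truth`
#'   (data.frame per input read: `id`, `seq`, `length`, `origin`,
#'   `strand`, `start`, `end` in plus-strand coordinates, `NA` for
#'   background).
#' @export
gen_reads <- function(genome, cfg) {
  stopifnot(inherits(genome, "genome_record"), inherits(cfg, "read_config"))
  set.seed(cfg$seed)
  L <- nchar(genome$seq)
  lens_avail <- as.integer(names(cfg$length_dist))
  if (L <= max(lens_avail)) stop("genome shorter than maximum read length")
  gchars <- strsplit(genome$seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  pos_weight <- rep(1, L)
  if (!is.null(cfg$hotspot)) {
    pos_weight[cfg$hotspot$start:cfg$hotspot$end] <- cfg$hotspot$weight
  }
  n <- cfg$n_viral
  viral <- NULL
  if (n > 0L) {
    len <- sample(lens_avail, n, replace = TRUE, prob = cfg$length_dist)
    plus <- stats::runif(n) < cfg$strand_prob
    want_au <- stats::runif(n) < cfg$five_prime_au_prob
    start <- integer(n)
    unfilled <- seq_len(n)
    draw_starts <- function(idx) {
      # vectorized by read length; weighted when a hotspot is configured
      out <- integer(length(idx))
      for (l in unique(len[idx])) {
        grp <- which(len[idx] == l)
        lim <- L - l + 1L
        out[grp] <- if (is.null(cfg$hotspot)) {
          sample.int(lim, length(grp), replace = TRUE)
        } else {
          sample.int(lim, length(grp), replace = TRUE,
                     prob = pos_weight[seq_len(lim)])
        }
      }
      out
    }
    for (round in seq_len(60L)) {
      if (length(unfilled) == 0L) break
      cand <- draw_starts(unfilled)
      # 5' nucleotide: genome base at the left end for plus reads, the
      # complement of the base at the right end for minus reads
      nt5 <- ifelse(plus[unfilled], gchars[cand],
                    comp[gchars[cand + len[unfilled] - 1L]])
      ok <- (nt5 %in% c("A", "T")) == want_au[unfilled]
      start[unfilled[ok]] <- cand[ok]
      unfilled <- unfilled[!ok]
    }
    if (length(unfilled) > 0L) {
      stop("config error: could not satisfy the 5' A/U target by ",
           "rejection sampling")
    }
    end <- start + len - 1L
    seqs <- substring(genome$seq, start, end)
    seqs[!plus] <- revcomp(seqs[!plus])
    viral <- data.frame(
      id = sprintf("viral_%06d", seq_len(n)), seq = seqs, length = len,
      origin = "viral", strand = ifelse(plus, "+", "-"),
      start = start, end = end, stringsAsFactors = FALSE)
  }
  bg <- NULL
  if (cfg$n_background > 0L) {
    nb <- cfg$n_background
    blen <- sample(lens_avail, nb, replace = TRUE, prob = cfg$length_dist)
    bseq <- character(nb)
    todo <- seq_len(nb)
    rc_genome <- revcomp(genome$seq)
    for (round in seq_len(100L)) {
      if (length(todo) == 0L) break
      cand <- vapply(blen[todo], function(l) {
        paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
              collapse = "")
      }, character(1))
      in_genome <- stringi::stri_detect_fixed(genome$seq, cand) |
        stringi::stri_detect_fixed(rc_genome, cand)
      bseq[todo[!in_genome]] <- cand[!in_genome]
      todo <- todo[in_genome]
    }
    if (length(todo) > 0L) {
      stop("config error: could not generate non-matching background reads")
    }
    bg <- data.frame(
      id = sprintf("background_%06d", seq_len(nb)), seq = bseq,
      length = blen, origin = "background", strand = NA_character_,
      start = NA_integer_, end = NA_integer_, stringsAsFactors = FALSE)
  }
  truth <- rbind(viral, bg)
  if (is.null(truth)) stop("config error: zero reads requested")
  rs <- read_set(truth$id, truth$seq)
  list(reads = rs, truth = truth)
}
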