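test_that("reads map to constructed positions on both strands", {
  set.seed(43)
  gseq <- random_dna(400)
  g <- genome_record("g", gseq)
  r_plus <- substr(gseq, 11, 32)
  r_minus <- oracle_revcomp(substr(gseq, 51, 72))
  r_none <- strrep("T", 22)  # may occur by chance: regenerate if so
  while (grepl(r_none, gseq) || grepl(oracle_revcomp(r_none), gseq)) {
    r_none <- random_dna(22)
  }
  rs <- read_set(c("p", "m", "n"), c(r_plus, r_minus, r_none))
  hits <- map_reads(rs, g)
  hp <- hits[hits$seq == r_plus, ]
  expect_true(any(hp$strand == "+" & hp$pos5 == 11 & hp$end == 32))
  hm <- hits[hits$seq == r_minus, ]
  expect_true(any(hm$strand == "-" & hm$start == 51 & hm$pos5 == 72))
  expect_false(r_none %in% hits$seq)
  # zero-mismatch guarantee on every hit
  spans <- substring(gseq, hits$start, hits$end)
  expect_true(all(ifelse(hits$strand == "+", spans == hits$seq,
                         spans == revcomp(hits$seq))))
})

test_that("mapping agrees with the brute-force offset-scan oracle", {
  set.seed(47)
  for (i in 1:100) {
    L <- sample(200:2000, 1)
    gseq <- random_dna(L)
    g <- genome_record("g", gseq)
    # mixture of planted plus, planted minus and random reads
    reads <- character(0)
    for (j in 1:4) {
      w <- sample(18:30, 1)
      s <- sample(L - w + 1, 1)
      reads <- c(reads, substr(gseq, s, s + w - 1))
    }
    for (j in 1:4) {
      w <- sample(18:30, 1)
      s <- sample(L - w + 1, 1)
      reads <- c(reads, oracle_revcomp(substr(gseq, s, s + w - 1)))
    }
    reads <- c(reads, vapply(1:4, function(j) random_dna(sample(18:30, 1)),
                             ""))
    rs <- read_set(paste0("r", seq_along(reads)), reads)
    hits <- map_reads(rs, g)
    expected <- do.call(rbind, lapply(rs$reads$seq, oracle_map,
                                      genome_seq = gseq))
    got <- hits[, c("seq", "strand", "start", "end")]
    key <- function(df) {
      if (is.null(df)) return(character(0))
      sort(paste(df$seq, df$strand, df$start, df$end))
    }
    expect_identical(key(got), key(expected), info = paste("iter", i))
  }
})

test_that("profiles count totals, strands and 5' nucleotides correctly", {
  set.seed(53)
  gseq <- random_dna(500)
  g <- genome_record("g", gseq)
  starts_p <- seq(10, 190, by = 36)[1:6]
  starts_m <- seq(250, 400, by = 50)[1:4]
  reads <- c(substring(gseq, starts_p, starts_p + 21),
             vapply(starts_m, function(s) {
               oracle_revcomp(substr(gseq, s, s + 21))
             }, ""))
  stopifnot(length(unique(reads)) == 10)
  rs <- read_set(paste0("r", 1:10), reads)
  prof <- sirna_profile(map_reads(rs, g), rs, nchar(gseq))
  expect_equal(prof$n_total_mapped, 10)
  sd22 <- prof$size_dist[prof$size_dist$length == 22, ]
  expect_equal(sum(sd22$total), 10)
  expect_equal(sd22$total[sd22$strand == "+"], 6)
  expect_equal(sd22$total[sd22$strand == "-"], 4)
  expect_equal(prof$frac_total, 1.0)
  # 5' nucleotide is reported in the RNA alphabet
  expect_setequal(prof$five_prime$nt, c("A", "C", "G", "U"))
  plus5 <- chartr("T", "U", substr(reads[1:6], 1, 1))
  for (nt in c("A", "C", "G", "U")) {
    expect_equal(prof$five_prime$count[prof$five_prime$nt == nt &
                                         prof$five_prime$strand == "+"],
                 sum(plus5 == nt))
  }
  expect_true(validate_profile(prof, mapped_nt = 10 * 22))
})

test_that("an unmapped library yields an all-zero profile", {
  g <- genome_record("g", strrep("C", 300))
  rs <- read_set("r1", strrep("A", 22))
  prof <- sirna_profile(map_reads(rs, g), rs, 300L)
  expect_equal(prof$n_total_mapped, 0L)
  expect_equal(prof$frac_total, 0)
  expect_equal(sum(prof$size_dist$total), 0)
  expect_equal(sum(prof$coverage), 0)
})

test_that("multi-locus reads are counted once with split coverage weight", {
  unit <- "ACGTTGCAACGTTGCAACGTCA"  # 22 nt
  gseq <- paste0(strrep("C", 50), unit, strrep("C", 50), unit,
                 strrep("C", 50))
  g <- genome_record("g", gseq)
  rs <- read_set(c("a", "b", "c"), c(unit, unit, unit))
  hits <- map_reads(rs, g)
  expect_equal(nrow(hits), 2L)
  prof <- sirna_profile(hits, rs, nchar(gseq))
  expect_equal(prof$n_total_mapped, 3)
  expect_equal(prof$n_unique_mapped, 1L)
  # 3 counts split over 2 loci: 1.5 per position of each locus
  expect_equal(max(prof$coverage["+", ]), 1.5)
  expect_equal(sum(prof$coverage), 3 * 22)
  expect_true(validate_profile(prof, mapped_nt = 3 * 22))
})

test_that("palindromic reads are assigned to plus and flagged", {
  pal <- "ACGCGT"
  pal22 <- paste0("ACG", pal, revcomp(paste0("ACG", pal)))  # 18 nt palindrome
  expect_identical(revcomp(pal22), pal22)
  gseq <- paste0(strrep("C", 40), pal22, strrep("C", 40))
  g <- genome_record("g", gseq)
  rs <- read_set("p", pal22)
  hits <- map_reads(rs, g)
  expect_setequal(hits$strand, c("+", "-"))
  prof <- sirna_profile(hits, rs, nchar(gseq))
  expect_equal(prof$n_ambiguous_strand, 1L)
  expect_equal(sum(prof$size_dist$total[prof$size_dist$strand == "+"]), 1)
})

test_that("profiles round-trip through their TSV/JSON panels", {
  set.seed(59)
  out <- gen_genome(small_config(seed = 6))
  lib <- gen_reads(out$genome, read_config(n_viral = 200,
                                           n_background = 300, seed = 6))
  prof <- sirna_profile(map_reads(lib$reads, out$genome), lib$reads,
                        nchar(out$genome$seq))
  prefix <- file.path(tempdir(), "prof_rt")
  paths <- write_profile(prof, prefix)
  expect_true(all(file.exists(paths)))
  back <- read_profile(prefix)
  expect_equal(back$n_total_mapped, prof$n_total_mapped)
  expect_equal(back$frac_total, prof$frac_total)
  expect_equal(back$size_dist$total, prof$size_dist$total)
  expect_equal(back$five_prime$count, prof$five_prime$count)
  expect_equal(back$coverage, prof$coverage)
  expect_true(validate_profile(back))
})

test_that("a 3' hotspot elevates coverage inside the hotspot", {
  set.seed(61)
  out <- gen_genome(small_config(seed = 8))
  L <- nchar(out$genome$seq)
  hot <- list(start = 2400L, end = 2900L, weight = 8)
  lib <- gen_reads(out$genome,
                   read_config(n_viral = 2000, n_background = 0,
                               hotspot = hot, seed = 8))
  prof <- sirna_profile(map_reads(lib$reads, out$genome), lib$reads, L)
  cov <- colSums(prof$coverage)
  inside <- mean(cov[hot$start:hot$end])
  outside <- mean(cov[setdiff(seq_len(L), hot$start:hot$end)])
  expect_gt(inside, outside)
})
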