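test_that("generated genomes are deterministic per seed", {
  a <- gen_genome(small_config(seed = 4))
  b <- gen_genome(small_config(seed = 4))
  c <- gen_genome(small_config(seed = 5))
  expect_identical(a$genome$seq, b$genome$seq)
  expect_false(identical(a$genome$seq, c$genome$seq))
  pa <- tempfile(fileext = ".fasta")
  pb <- tempfile(fileext = ".fasta")
  write_fasta(a$genome, pa)
  write_fasta(b$genome, pb)
  expect_identical(readLines(pa), readLines(pb))
})

test_that("planted ORFs, motifs and islands survive construction", {
  for (seed in c(1, 2)) {
    for (ord in c("A-B-C", "C-A-B")) {
      out <- gen_genome(small_config(seed = seed, motif_order = ord))
      ann <- annotate_genome(out$genome, min_len_codons = 150L)
      expect_equal(ann$orfs$start, out$truth$orfs$start)
      expect_equal(ann$orfs$end, out$truth$orfs$end)
      res <- classify_order(ann$orfs$protein[1])
      expect_equal(res$order, ord)
      expect_equal(res$hits$start[res$hits$motif == "A"],
                   unname(out$truth$motif_positions["A"]))
      seg <- predict_tm(ann$orfs$protein[2])
      expect_equal(seg$start, 60L)
      expect_equal(seg$end, 79L)
    }
  }
})

test_that("configuration validation rejects inconsistent plants", {
  expect_error(genome_config(length = 3000, orfs = list(c(21, 2121))),
               "is not TRUE")  # span not a codon multiple
  expect_error(
    genome_config(length = 3000, orfs = list(c(21, 2120)),
                  motif_order = "A-B-C",
                  motif_positions = c(C = 420L, A = 470L, B = 520L)),
    "imply order")
  expect_error(
    genome_config(length = 3000, orfs = list(c(21, 2120)),
                  motif_order = "A-B-C",
                  motif_positions = c(A = 420L, B = 427L, C = 520L)),
    "gaps")
  expect_error(
    genome_config(length = 3000, orfs = list(c(21, 2120), c(2200, 2841)),
                  tm_orf = 2, tm_islands = list(c(60, 79), c(85, 104))),
    "separated")
})

test_that("viral reads are genome substrings with faithful truth records", {
  out <- gen_genome(small_config(seed = 10))
  gseq <- out$genome$seq
  cfg <- read_config(n_viral = 400, n_background = 100, seed = 10)
  lib <- gen_reads(out$genome, cfg)
  expect_equal(lib$reads$n_input, 500L)
  expect_equal(lib$reads$n_kept, sum(lib$reads$reads$count))
  v <- lib$truth[lib$truth$origin == "viral", ]
  spans <- substring(gseq, v$start, v$end)
  expect_true(all(ifelse(v$strand == "+", spans == v$seq,
                         spans == revcomp(v$seq))))
  bg <- lib$truth[lib$truth$origin == "background", ]
  rc <- revcomp(gseq)
  expect_false(any(vapply(bg$seq, function(s) {
    grepl(s, gseq, fixed = TRUE) || grepl(s, rc, fixed = TRUE)
  }, logical(1))))
})

test_that("strand_prob = 1 yields plus-strand hits only", {
  out <- gen_genome(small_config(seed = 12))
  lib <- gen_reads(out$genome,
                   read_config(n_viral = 300, n_background = 0,
                               strand_prob = 1, seed = 12))
  prof <- sirna_profile(map_reads(lib$reads, out$genome), lib$reads,
                        nchar(out$genome$seq))
  expect_equal(sum(prof$size_dist$total[prof$size_dist$strand == "-"]), 0)
  expect_equal(prof$frac_total, 1.0)
})

test_that("zero viral reads give a zero mapped fraction", {
  out <- gen_genome(small_config(seed = 14))
  lib <- gen_reads(out$genome,
                   read_config(n_viral = 0, n_background = 200, seed = 14))
  prof <- sirna_profile(map_reads(lib$reads, out$genome), lib$reads,
                        nchar(out$genome$seq))
  expect_equal(prof$frac_total, 0)
})

test_that("realized read lengths track the configured distribution", {
  out <- gen_genome(small_config(seed = 16))
  cfg <- read_config(n_viral = 4000, n_background = 0, seed = 16)
  lib <- gen_reads(out$genome, cfg)
  share <- mean(lib$truth$length == 22)
  p <- cfg$length_dist[["22"]]
  expect_lt(abs(share - p), 3 * sqrt(p * (1 - p) / 4000))
})

test_that("a poly(A) tail is appended after the core sequence", {
  cfg <- genome_config(length = 3000, orfs = list(c(21, 2120)),
                       polya_len = 30L, seed = 3)
  out <- gen_genome(cfg)
  expect_equal(nchar(out$genome$seq), 3030L)
  expect_equal(substr(out$genome$seq, 3001, 3030), strrep("A", 30))
  ann <- annotate_genome(out$genome, min_len_codons = 150L,
                         trim_polya = TRUE)
  # trimming removes the whole terminal A run, including any genuine
  # terminal A's of the core sequence
  core_tail <- nchar(regmatches(substr(out$genome$seq, 1, 3000),
                                regexpr("A*$",
                                        substr(out$genome$seq, 1, 3000))))
  expect_equal(ann$genome_length, 3000L - core_tail)
})
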