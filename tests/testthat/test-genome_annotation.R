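test_that("find_orfs locates start-to-stop spans per frame", {
  g <- genome_record("toy", "CCATGAAATAGGG")
  orfs <- find_orfs(g, min_len_codons = 2L)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 3L)
  expect_equal(orfs$end, 11L)
  expect_equal(orfs$protein, "MK")
  expect_equal(find_orfs(genome_record("noatg", "CCCCCCCC"), 2L),
               find_orfs(genome_record("noatg2", "CCCCCCCC"), 2L))
  expect_equal(nrow(find_orfs(genome_record("noatg", "CCCCCCCC"), 2L)), 0L)
  # ORF without a downstream stop is discarded
  expect_equal(nrow(find_orfs(genome_record("nostop", "CCATGAAAAAA"), 2L)),
               0L)
  # first ATG after the previous in-frame stop opens the next ORF
  g2 <- genome_record("two", "ATGAAATAAATGTGCTGCTGA")
  orfs2 <- find_orfs(g2, min_len_codons = 2L)
  expect_equal(orfs2$start, c(1L, 10L))
  expect_equal(orfs2$end, c(9L, 21L))
  expect_equal(orfs2$protein, c("MK", "MCC"))
})

test_that("single-ORF genome annotates with zero-length UTRs", {
  g <- genome_record("solo", paste0("ATG", strrep("GCT", 8), "TAA"))
  ann <- annotate_genome(g, min_len_codons = 2L)
  expect_equal(ann$utr5_len, 0L)
  expect_equal(ann$utr3_len, 0L)
  expect_equal(nrow(ann$relations), 0L)
  expect_error(annotate_genome(g, min_len_codons = 50L), "lowering")
})

test_that("consecutive-ORF relations report overlaps and gaps with frames", {
  out <- gen_genome(small_config(seed = 3))
  ann <- annotate_genome(out$genome, min_len_codons = 150L)
  expect_equal(ann$orfs$start, out$truth$orfs$start)
  expect_equal(ann$orfs$end, out$truth$orfs$end)
  r <- ann$relations
  expect_equal(nrow(r), 1L)
  expect_equal(r$kind, "intergenic")
  expect_equal(r$length, 2200L - 2120L - 1L)
  expect_warning(annotate_genome(out$genome, min_len_codons = 150L,
                                 expected_orfs = 3L), "expected 3")
})

test_that("annotation length-conservation identity holds on random layouts", {
  for (seed in 1:5) {
    out <- gen_genome(small_config(seed = seed))
    ann <- annotate_genome(out$genome, min_len_codons = 150L)
    expect_true(validate_annotation(ann, out$genome))
    ov <- sum(ann$relations$length[ann$relations$kind == "overlap"])
    gap <- sum(ann$relations$length[ann$relations$kind == "intergenic"])
    lhs <- ann$utr5_len + sum(ann$orfs$end - ann$orfs$start + 1L) - ov +
      gap + ann$utr3_len
    expect_equal(lhs, ann$genome_length)
  }
})

test_that("nested ORFs resolve to the longer one", {
  # inner ATG in the same stop-to-stop segment of another frame
  set.seed(42)
  out <- gen_genome(small_config(seed = 9))
  orfs <- find_orfs(out$genome, min_len_codons = 30L)
  ann <- annotate_genome(out$genome, min_len_codons = 30L)
  for (i in seq_len(nrow(ann$orfs))) {
    for (j in seq_len(nrow(ann$orfs))) {
      if (i == j) next
      nested <- ann$orfs$start[i] >= ann$orfs$start[j] &&
        ann$orfs$end[i] <= ann$orfs$end[j]
      expect_false(nested)
    }
  }
})

test_that("terminal poly(A) can be trimmed before annotation", {
  out <- gen_genome(small_config(seed = 5))
  tailed <- genome_record(out$genome$id,
                          paste0(out$genome$seq, strrep("A", 25)))
  ann <- annotate_genome(tailed, min_len_codons = 150L, trim_polya = TRUE)
  expect_equal(ann$genome_length, 3000L)
  expect_equal(ann$utr3_len, 3000L - out$truth$orfs$end[2])
  # short A runs are genuine sequence, not a tail
  short <- genome_record("s", paste0(out$genome$seq, "AAA"))
  expect_equal(trim_polya(short)$seq, short$seq)
})

test_that("annotation reports round-trip through GFF3 and TSV", {
  out <- gen_genome(small_config(seed = 2))
  ann <- annotate_genome(out$genome, min_len_codons = 150L)
  tsv <- tempfile(fileext = ".tsv")
  gff <- tempfile(fileext = ".gff3")
  rep <- report_annotation(ann, tsv_path = tsv, gff3_path = gff)
  tab <- read.delim(tsv)
  expect_equal(tab$start, ann$orfs$start)
  expect_equal(tab$end, ann$orfs$end)
  gr <- rtracklayer::import(gff)
  cds <- gr[gr$type == "CDS"]
  expect_equal(BiocGenerics::start(cds), ann$orfs$start)
  expect_equal(BiocGenerics::end(cds), ann$orfs$end)
  expect_true(all(as.character(BiocGenerics::strand(cds)) == "+"))
  expect_equal(sum(gr$type == "five_prime_UTR"), 1L)
  expect_equal(sum(gr$type == "three_prime_UTR"), 1L)
})
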