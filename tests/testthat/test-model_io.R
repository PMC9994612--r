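test_that("gene vocabulary is closed with 13 PCGs, 22 tRNAs, 2 rRNAs, CR", {
  expect_length(mito_genes(), 38L)
  expect_length(mito_genes("PCG"), 13L)
  expect_length(mito_genes("tRNA"), 22L)
  expect_identical(mito_genes("rRNA"), c("rrnS", "rrnL"))
  expect_identical(mito_genes("CR"), "CR")
  expect_false(anyNA(gene_category(mito_genes())))
})

test_that("gene name normalization maps common aliases and is idempotent", {
  expect_identical(normalize_gene_names(c("12S", "16S", "D-loop", "ND5",
                                          "CYTB", "COI")),
                   c("rrnS", "rrnL", "CR", "nad5", "cob", "cox1"))
  expect_identical(normalize_gene_names("trnL(CUN)"), "trnL1")
  expect_identical(normalize_gene_names("trnS(UCN)"), "trnS2")
  once <- normalize_gene_names(c("nd4l", "ATP6"))
  expect_identical(normalize_gene_names(once), once)
  expect_error(normalize_gene_names("nad99"), "unknown gene symbol")
  expect_identical(normalize_gene_names("nad99", error = FALSE),
                   NA_character_)
})

test_that("annotations sort records, normalize strands, reject duplicates", {
  rec <- data.frame(gene = c("cox2", "cox1"), start = c(50L, 1L),
                    end = c(90L, 45L), strand = c("F", "R"))
  ann <- mito_annotation(rec, genome_length = 100L, taxon = "t")
  expect_identical(ann$records$gene, c("cox1", "cox2"))
  expect_identical(ann$records$strand, c("-", "+"))
  rec2 <- rec; rec2$gene <- c("cox1", "COI")
  expect_error(mito_annotation(rec2, 100L), "duplicate")
  expect_error(mito_annotation(rec[0, ], 100L), "no records")
})

test_that("wrap-around records are circular-only and sequence length is checked", {
  rec <- data.frame(gene = "trnI", start = 95L, end = 10L, strand = "+")
  ann <- mito_annotation(rec, 100L, circular = TRUE)
  expect_identical(ann$records$end, 10L)
  expect_error(mito_annotation(rec, 100L, circular = FALSE), "wrap-around")
  rec2 <- data.frame(gene = "cox1", start = 1L, end = 30L, strand = "+")
  expect_error(mito_annotation(rec2, 100L, sequence = "ACGT"),
               "does not equal genome_length")
})

test_that("coordinate-derived lengths handle the origin wrap", {
  expect_identical(gene_length(5296L, 6966L, 17311L), 1671L)
  expect_identical(gene_length(17300L, 10L, 17311L), 22L)
  expect_error(gene_length(90L, 10L, 100L, circular = FALSE), "wrap-around")
})

test_that("validation reports stated-length mismatches without throwing", {
  expect_identical(nrow(validate_annotation(chishuiense())), 0L)
  v <- validate_annotation(wushanense())
  expect_identical(v$gene, "trnL1")
  expect_identical(v$issue, "length_mismatch")
  expect_match(v$detail, "60")
  expect_match(v$detail, "66")
})

test_that("a truncated stop codon legitimizes a non-multiple-of-3 PCG", {
  # cox2 of the second fixture spans 682 bp with stop T--: not an anomaly
  w <- wushanense()
  expect_false("codon_anomaly" %in% validate_annotation(w)$issue)
  # the same length with a complete stop is flagged
  r <- w$records[w$records$gene == "cox2", c("gene", "start", "end", "strand")]
  r$stop_codon <- "TAA"
  bad <- mito_annotation(r, w$genome_length)
  expect_identical(validate_annotation(bad)$issue, "codon_anomaly")
})

test_that("annotation tables round-trip through write and read", {
  ann <- chishuiense()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(ann, path)
  back <- read_annotation_table(path)
  expect_identical(back$genome_length, ann$genome_length)
  expect_identical(back$taxon, ann$taxon)
  expect_identical(back$records$gene, ann$records$gene)
  expect_identical(back$records$start, ann$records$start)
  expect_identical(back$records$end, ann$records$end)
  expect_identical(back$records$strand, ann$records$strand)
  expect_identical(back$records$start_codon, ann$records$start_codon)
})

test_that("GenBank flat files round-trip, including origin-wrap records", {
  rec <- data.frame(gene = c("cox1", "nad2", "trnK", "CR", "trnI"),
                    start = c(1L, 41L, 71L, 87L, 115L),
                    end = c(30L, 70L, 86L, 114L, 5L),
                    strand = c("+", "-", "+", NA, "+"))
  seq <- paste(rep("ACGT", 30), collapse = "")
  ann <- mito_annotation(rec, 120L, taxon = "round trip", sequence = seq)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(ann, path)
  back <- read_genbank(path)
  expect_identical(back$genome_length, 120L)
  expect_true(back$circular)
  expect_identical(back$records$gene, ann$records$gene)
  expect_identical(back$records$start, ann$records$start)
  expect_identical(back$records$end, ann$records$end)
  expect_identical(back$records$strand, ann$records$strand)
  expect_identical(back$sequence, seq)
})

test_that("GenBank reader rejects an origin-spanning feature on a linear genome", {
  rec <- data.frame(gene = "trnI", start = 115L, end = 5L, strand = "+")
  ann <- mito_annotation(rec, 120L, circular = TRUE)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(ann, path)
  txt <- readLines(path)
  txt <- sub("circular", "linear  ", txt)
  writeLines(txt, path)
  expect_error(read_genbank(path), "linear")
})

test_that("gene-order lists round-trip with signs intact", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_gene_orders(list(ground_pattern()), path)
  back <- read_gene_orders(path)
  expect_length(back, 1L)
  expect_identical(back[[1L]]$genes, ground_pattern()$genes)
  expect_identical(back[[1L]]$signs, ground_pattern()$signs)
  expect_identical(back[[1L]]$taxon, "pancrustacean")
})

test_that("FASTA sequences round-trip", {
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(g1 = "ACGTACGT", g2 = "TTTTAAAA"), path)
  back <- read_fasta(path)
  expect_identical(back, c(g1 = "ACGTACGT", g2 = "TTTTAAAA"))
})
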