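fixture_gb <- system.file("extdata", "synthetic_mitogenome.gb",
                          package = "mitocub")

test_that("packaged GenBank fixture parses with the expected feature inventory", {
  g <- read_genbank(fixture_gb)
  feats <- g$features
  expect_identical(sum(feats$type == "CDS"), 13L)
  expect_identical(sum(feats$type == "CDS" & feats$strand == "-"), 4L)
  expect_true(g$circular)
  expect_true(all(feats$start >= 1 & feats$end <= g$length))
  expect_true(all(grepl("^[ACGTN]+$", g$sequence)))
  # reader reports strand but never reverse-complements the genome sequence
  minus_cds <- feats[feats$type == "CDS" & feats$strand == "-", ][1, ]
  region <- substring(g$sequence, minus_cds$start, minus_cds$end)
  expect_identical(nchar(region), minus_cds$end - minus_cds$start + 1L)
})

test_that("GenBank parsing fails informatively on malformed records", {
  no_origin <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp DNA circular", "FEATURES", "//"),
             no_origin)
  expect_error(read_genbank(no_origin), "ORIGIN")
  bad_loc <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 12 bp DNA linear",
               "FEATURES             Location/Qualifiers",
               "     CDS             frob..12",
               '                     /gene="broken"',
               "ORIGIN",
               "        1 atgaaatAAa tt", "//"), bad_loc)
  expect_error(read_genbank(bad_loc), "location")
})

test_that("CDS extraction handles strand, frame and incomplete stops", {
  cds <- make_coding_sequence("ATGAAATAA", gene = "t1", code = code5)
  expect_identical(cds$start_codon, "ATG")
  expect_identical(cds$stop_codon, "TAA")
  expect_false(cds$stop_completed)

  padded <- make_coding_sequence("ATGAAATA", gene = "t2", code = code5)
  expect_identical(padded$nt, "ATGAAATAA")
  expect_true(padded$stop_completed)
  padded1 <- make_coding_sequence("ATGAAAT", gene = "t3", code = code5)
  expect_identical(padded1$nt, "ATGAAATAA")
  expect_true(padded1$stop_completed)

  # remainder that is not a TAA prefix is a frame error, not silently padded
  expect_error(make_coding_sequence("ATGAAAGG", code = code5), "remainder")
  # internal stop is an annotation error
  expect_error(make_coding_sequence("ATGTAAAAATAA", code = code5),
               "internal stop")
  expect_error(make_coding_sequence("ATGAAAAAA", code = code5),
               "terminal stop")
})

test_that("minus-strand extraction reverse-complements to the identical sense CDS", {
  sense <- "ATGAAATAA"
  emitted <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(sense)))
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    sprintf("LOCUS       T %d bp DNA linear", nchar(sense)),
    "FEATURES             Location/Qualifiers",
    sprintf("     CDS             complement(1..%d)", nchar(sense)),
    '                     /gene="g1"',
    "ORIGIN",
    sprintf("        1 %s", tolower(emitted)), "//"), gb)
  g <- read_genbank(gb)
  got <- extract_cds(g, 1, code5)
  expect_identical(got$nt, sense)
  expect_identical(got$strand, "-")
})

test_that("codon counting excludes the stop, honours flags, and is additive", {
  counts <- count_codons("ATGAAATAA", code5)
  expect_identical(unname(counts["ATG"]), 1L)
  expect_identical(unname(counts["AAA"]), 1L)
  expect_identical(sum(counts), 2L)

  no_start <- count_codons("ATGAAATAA", code5, include_start = FALSE)
  expect_identical(sum(no_start), 1L)
  expect_identical(unname(no_start["ATG"]), 0L)

  with_n <- make_coding_sequence("ATGANAAAATAA", code = code5)
  counted <- count_codons(with_n, code5)
  expect_identical(sum(counted), 2L)  # ANA dropped

  g <- read_genbank(fixture_gb)
  cds <- extract_all_cds(g, code5)
  per_gene <- lapply(cds, count_codons, code = code5)
  pooled <- pool_codon_counts(per_gene)
  concat <- Reduce(`+`, lapply(per_gene, unclass))
  expect_equal(unclass(pooled)[names(concat)], concat, ignore_attr = TRUE)
})

test_that("every fixture CDS translates with one terminal and no internal stop", {
  g <- read_genbank(fixture_gb)
  cds <- extract_all_cds(g, code5)
  expect_length(cds, 13)
  gcmap <- Biostrings::getGeneticCode("5")
  for (x in cds) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(x$nt),
                                             genetic.code = gcmap))
    expect_identical(substring(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substring(aa, 1, nchar(aa) - 1)))
  }
  expect_identical(sum(vapply(cds, `[[`, TRUE, "stop_completed")), 3L)
})

test_that("reverse complement is an involution and FASTA round-trips byte-identically", {
  set.seed(401)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(3:90, 1), replace = TRUE),
               collapse = "")
    expect_identical(mitocub:::dna_revcomp(mitocub:::dna_revcomp(s)), s)
  }
  g <- read_genbank(fixture_gb)
  cds <- extract_all_cds(g, code5)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_cds_fasta(cds, f1)
  back <- read_cds_fasta(f1, code5)
  expect_identical(vapply(back, `[[`, "", "nt"), vapply(cds, `[[`, "", "nt"))
  write_cds_fasta(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})
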