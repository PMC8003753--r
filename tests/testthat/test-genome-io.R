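test_that("FASTA parsing validates records and preserves order", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACGT"), fa)
  rec <- read_fasta(fa, "dna")
  expect_equal(rec$id, "g1")
  expect_equal(rec$length, 4L)

  writeLines(c(">p1", "MKT", ">p2", "MKV"), fa)
  prots <- read_fasta(fa, "protein")
  expect_equal(prots$id, c("p1", "p2"))
  expect_equal(prots$length, c(3L, 3L))

  writeLines(c(">g1", "ACGT", ">g1", "AC"), fa)
  expect_error(read_fasta(fa, "dna"), "duplicate.*g1")

  writeLines(c(">g1", "ACXT"), fa)
  expect_error(read_fasta(fa, "dna"), "position 3")

  writeLines(c(">g1", "acgtn"), fa)
  expect_equal(read_fasta(fa, "dna")$sequence, "ACGTN")
})

test_that("FASTA round-trips exactly", {
  recs <- tibble::tibble(id = c("a", "b"),
                         sequence = c(strrep("ACGT", 40), "TTTNGG"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, fa)
  back <- read_fasta(fa, "dna")
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
})

test_that("GFF reading validates coordinates and sorts features", {
  genomes <- tibble::tibble(id = "g1", sequence = strrep("A", 10),
                            length = 10L)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "g1\t.\tCDS\t7\t9\t.\t-\t0\tID=b",
               "g1\t.\tCDS\t1\t6\t.\t+\t0\tID=a"), gff)
  feats <- read_gff(gff, genomes)
  expect_equal(feats$gene_id, c("a", "b"))
  expect_equal(feats$start, c(1L, 7L))
  expect_equal(feats$strand, c("+", "-"))

  writeLines(c("##gff-version 3", "g1\t.\tCDS\t1\t20\t.\t+\t0\tID=a"), gff)
  expect_error(read_gff(gff, genomes), "beyond its genome")

  writeLines(c("##gff-version 3", "gX\t.\tCDS\t1\t6\t.\t+\t0\tID=a"), gff)
  expect_error(read_gff(gff, genomes), "unknown genome")

  writeLines(c("##gff-version 3",
               "g1\t.\tCDS\t1\t6\t.\t+\t0\tID=a",
               "g1\t.\tgene\t1\t6\t.\t+\t.\tID=ga"), gff)
  expect_message(read_gff(gff, genomes), "1 non-CDS")
})

test_that("GFF writing round-trips through the reader", {
  sv <- survey_fixture()
  g <- sv$genomes$Camm
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff(g$features, gff)
  back <- suppressMessages(read_gff(gff, g$genome |>
                                      dplyr::rename(id = "id")))
  expect_equal(back$start, g$features$start)
  expect_equal(back$end, g$features$end)
  expect_equal(back$strand, g$features$strand)
  expect_equal(back$locus_tag, g$features$locus_tag)
})

test_that("translation follows the bacterial code on both strands", {
  genome <- tibble::tibble(id = "g", sequence = "ATGAAAACCTAA",
                           length = 12L)
  feats <- tibble::tibble(gene_id = "x", genome_id = "g", start = 1L,
                          end = 12L, strand = "+", product = NA,
                          locus_tag = "x")
  expect_equal(extract_proteome(genome, feats)$sequence, "MKT")

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAAACCTAA")))
  genome2 <- tibble::tibble(id = "g", sequence = rc, length = 12L)
  feats$strand <- "-"
  expect_equal(extract_proteome(genome2, feats)$sequence, "MKT")

  genome3 <- tibble::tibble(id = "g", sequence = "ATGTAAAAATAA",
                            length = 12L)
  feats$strand <- "+"
  expect_error(extract_proteome(genome3, feats), "internal stop.*x")

  # ambiguous codon translates to X
  genome4 <- tibble::tibble(id = "g", sequence = "ATGANATAA", length = 9L)
  feats4 <- feats; feats4$end <- 9L
  expect_equal(extract_proteome(genome4, feats4)$sequence, "MX")
})

test_that("a synthetic genome yields exactly the planted proteins", {
  sv <- survey_fixture()
  g <- sv$genomes$Ccas
  proteome <- extract_proteome(g$genome, g$features)
  expect_equal(proteome$id, g$proteins$locus_tag)
  expect_equal(proteome$sequence, g$proteins$sequence)
})
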