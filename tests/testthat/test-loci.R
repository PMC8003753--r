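mk_genes <- function(roles, starts, widths = 900L, genome_id = "g") {
  n <- length(roles)
  widths <- rep_len(widths, n)
  tibble::tibble(
    gene_id = paste0("gene", seq_len(n)), genome_id = genome_id,
    start = as.integer(starts), end = as.integer(starts + widths - 1L),
    strand = "+", product = NA_character_,
    locus_tag = paste0("tag", seq_len(n)), role = roles)
}

test_that("adjacent role genes form one locus, distant ones split", {
  g <- mk_genes(c("RR", "HK", "NBD", "permease", "NSR_peptidase"),
                starts = c(1, 1001, 2001, 3001, 4001), widths = 900L)
  loci <- assemble_loci(g)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$n_members, 5L)
  expect_equal(loci$start, 1L)
  expect_equal(loci$end, 4900L)

  far <- mk_genes(c("NBD", "NSR_peptidase"), starts = c(1, 12000))
  expect_equal(nrow(assemble_loci(far)), 2L)

  # two role-less genes in between exceed the default tolerance
  mix <- mk_genes(c("NBD", "none", "none", "permease"),
                  starts = c(1, 1001, 2001, 3001))
  expect_equal(nrow(assemble_loci(mix)), 2L)
  # ... but a single intervening role-less gene is bridged
  mix1 <- mk_genes(c("NBD", "none", "permease"),
                   starts = c(1, 1001, 2001))
  expect_equal(nrow(assemble_loci(mix1)), 1L)
})

test_that("clustering is order-independent and role-less genes never seed", {
  g <- mk_genes(c("none", "NBD", "permease", "none", "HK", "RR"),
                starts = c(1, 1001, 2001, 3001, 4001, 5001))
  base <- assemble_loci(g)
  withr::with_seed(7, {
    shuffled <- g[sample(nrow(g)), ]
  })
  expect_equal(assemble_loci(shuffled), base)
  expect_false(any(grepl("none", base$roles)))
})

test_that("architecture labels combine the present role groups", {
  expect_equal(classify_architecture(c("NBD", "permease", "NSR_peptidase")),
               "ABC_NSR")
  expect_equal(classify_architecture(c("NBD", "permease", "HK", "RR")),
               "ABC_TCS")
  expect_equal(classify_architecture(c("RR", "HK", "NBD", "permease",
                                       "NSR_peptidase")), "ABC_TCS_NSR")
  expect_equal(classify_architecture(c("NBD", "permease")), "ABC_only")
  expect_equal(classify_architecture("NSR_peptidase"), "NSR_only")
  expect_error(classify_architecture("HK"), "complete no architecture")
  expect_error(classify_architecture("none"), "no recognized role")
})

test_that("stored architecture labels survive recomputation from roles", {
  pip <- pipeline_fixture()
  for (d in pip$details) {
    loci <- d$loci[d$loci$architecture != "fragmented_NSR", , drop = FALSE]
    for (i in seq_len(nrow(loci))) {
      expect_equal(classify_architecture(loci[i, ]), loci$architecture[i])
    }
  }
})

test_that("fragment detection uses span overlap and joint coverage", {
  hits <- tibble::tibble(subject_id = c("A", "B"),
                         query_start = c(5L, 210L),
                         query_end = c(200L, 410L))
  expect_true(detect_fragmented(hits, query_length = 420L))

  paralogs <- tibble::tibble(subject_id = c("A", "B"),
                             query_start = c(1L, 1L),
                             query_end = c(200L, 200L))
  expect_false(detect_fragmented(paralogs, query_length = 420L))

  single <- tibble::tibble(subject_id = "A", query_start = 10L,
                           query_end = 390L)
  expect_false(detect_fragmented(single, query_length = 420L))
})

test_that("planted architectures are recovered exactly, decoys give none", {
  pip <- pipeline_fixture()
  sv <- survey_fixture()
  for (gid in names(sv$genomes)) {
    truth <- sv$genomes[[gid]]$truth
    planted_ops <- truth[truth$kind %in% c("operon", "fragmented_nsr"), ]
    got <- pip$details[[gid]]$loci
    expect_equal(nrow(got), nrow(planted_ops))
    if (nrow(planted_ops) > 0) {
      expect_setequal(got$architecture,
                      sub("fragmented_nsr", "fragmented_NSR",
                          planted_ops$label))
    }
  }
})
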