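test_that("protein mutation hits the identity target and locks motifs", {
  reg <- query_registry()
  nsr <- reg[reg$name == "NSR_Saga", ]
  seedp <- prot("nsr", nsr$sequence)

  expect_equal(mutate_protein(seedp, 1.0, seed = 1)$sequence,
               nsr$sequence)

  mut <- mutate_protein(seedp, 0.5, seed = 2, protected = nsr$motifs[[1]])
  ident <- global_identity(prot("a", nsr$sequence),
                           prot("b", mut$sequence))
  expect_gte(ident, 0.47)
  expect_lte(ident, 0.53)
  # the locked catalytic box still fires
  hit <- find_catalytic_motif(mut)
  expect_equal(nrow(hit), 1L)
  expect_true(hit$serine_conserved)

  # a tiny protein that is almost all motif cannot reach 30% identity
  tiny <- prot("t", "TASSAEMAA")
  expect_error(mutate_protein(tiny, 0.3, seed = 3,
                              protected = tibble::tibble(start = 1L,
                                                         end = 7L)),
               "unreachable")
})

test_that("genome building is seed-deterministic", {
  plants <- list(list(kind = "operon", layout = "nsrRKFPX",
                      identity = 0.5))
  g1 <- build_genome(plants, seed = 77, genome_id = "gA")
  g2 <- build_genome(plants, seed = 77, genome_id = "gA")
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  expect_identical(g1$features, g2$features)
  g3 <- build_genome(plants, seed = 78, genome_id = "gA")
  expect_false(identical(g1$genome$sequence, g3$genome$sequence))
})

test_that("planted truth metadata scores end-to-end recovery", {
  g <- build_genome(list(list(kind = "operon", layout = "nsrRKFPX",
                              identity = 0.5)),
                    seed = 55, genome_id = "gT")
  expect_equal(g$truth$label, "ABC_TCS_NSR")
  res <- suppressMessages(run_pipeline(list(g)))
  loci <- res$details$gT$loci
  expect_equal(loci$architecture, "ABC_TCS_NSR")
  # recovered at the planted span
  expect_equal(loci$start, g$truth$start)
  expect_equal(loci$end, g$truth$end)
})

test_that("membrane-protein construction validates its ECD request", {
  expect_error(build_membrane_protein(10, rep(12, 10)), "loop lengths")
  expect_error(build_membrane_protein(10, rep(12, 11),
                                      ecd_between = c(7, 9),
                                      ecd_length = 100), "consecutive")
  expect_error(build_membrane_protein(10, rep(12, 11),
                                      ecd_between = c(7, 8)), "ecd_length")
  # zero helices yields a soluble protein, read as a cytoplasmic kinase
  sol <- build_membrane_protein(0, 250, seed = 5)
  expect_equal(classify_kinase(predict_tmh(sol$record)), "cytoplasmic")
})

test_that("assay and alignment generators are deterministic", {
  a1 <- simulate_assay(2.5, noise_sd = 0.05, seed = 9)
  a2 <- simulate_assay(2.5, noise_sd = 0.05, seed = 9)
  expect_identical(a1$od_t24, a2$od_t24)

  tr <- random_tree(6, seed = 4)
  e1 <- evolve_alignment(tr, 300, seed = 8)
  e2 <- evolve_alignment(tr, 300, seed = 8)
  expect_identical(e1$sequence, e2$sequence)

  # a zero-length tree evolves identical rows
  tr0 <- tr; tr0$edge.length[] <- 0
  e0 <- evolve_alignment(tr0, 200, seed = 2)
  expect_equal(length(unique(e0$sequence)), 1L)
})

test_that("simulated trees are recovered from evolved alignments", {
  ok <- 0; n <- 25
  for (s in seq_len(n)) {
    tr <- random_tree(8, seed = s)
    aln <- evolve_alignment(tr, 2000, seed = s + 1000)
    rec <- nj_tree(jc69_distance(aln))
    if (ape::dist.topo(ape::unroot(tr), rec) == 0) ok <- ok + 1
  }
  expect_gte(ok / n, 0.95)
})
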