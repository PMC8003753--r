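test_that("local alignment matches hand-checkable self-alignment", {
  hit <- local_align(prot("q", "MKT"), prot("s", "MKT"))
  expect_equal(hit$raw_score, 15)  # BLOSUM62 diagonal M+K+T = 5+5+5
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$aligned_length, 3L)
  expect_error(local_align(prot("q", ""), prot("s", "MKT")), "empty")
})

test_that("local and global scores match the brute-force DP oracle", {
  mat <- oracle_submat()
  scheme <- scoring_scheme()
  withr::with_seed(11, {
    for (k in 1:30) {
      a <- random_peptide(sample(5:30, 1))
      b <- random_peptide(sample(5:30, 1))
      hit <- local_align(prot("a", a), prot("b", b), scheme)
      expect_equal(hit$raw_score, oracle_local_score(a, b, mat))
      # score symmetry
      expect_equal(local_align(prot("b", b), prot("a", a),
                               scheme)$raw_score, hit$raw_score)
    }
  })
  # the dissimilar-pair edge case: clamped at 0 when the oracle finds no
  # positive-scoring cell
  expect_equal(local_align(prot("a", "MKT"), prot("b", "WWWW"))$raw_score,
               oracle_local_score("MKT", "WWWW", mat))
})

test_that("global identity counts gap columns in the denominator", {
  expect_equal(global_identity(prot("a", "MKTW"), prot("b", "MKTW")), 1.0)
  expect_equal(global_identity(prot("a", "MKT"), prot("b", "MKV")), 2 / 3)
  # disjoint residue alphabets of equal length: gapless alignment is
  # optimal (a gap pair costs more than any mismatch), identity 0
  expect_equal(global_identity(prot("a", "MKTW"), prot("b", "GPSD")), 0)
})

test_that("Karlin-Altschul E-values follow the closed form", {
  sch <- scoring_scheme()
  # S chosen so K*m*n*exp(-lambda*S) = 1 algebraically
  s1 <- log(sch$K * 200 * 300) / sch$lambda
  expect_equal(evalue_ka(s1, 200, 300, sch), 1.0)
  expect_equal(evalue_ka(50, 400, 300, sch),
               2 * evalue_ka(50, 200, 300, sch))
  expect_equal(evalue_ka(100, 300, 300, sch),
               0.041 * 300 * 300 * exp(-0.267 * 100))
  # strictly decreasing in score
  ev <- evalue_ka(seq(10, 200, by = 10), 300, 300, sch)
  expect_true(all(diff(ev) < 0))
})

test_that("proteome search keeps one best hit per pair and sorts by E", {
  q <- prot("q1", random_peptide(200, seed = 3))
  proteome <- dplyr::bind_rows(q, prot("other", random_peptide(200,
                                                               seed = 4)))
  hits <- search_proteome(q, proteome)
  expect_equal(hits$subject_id[1], "q1")  # self-hit ranked first
  expect_equal(hits$identity[1], 1.0)

  # dedup is per query: two queries hitting the same subject
  q2 <- dplyr::bind_rows(q, prot("q2", q$sequence))
  hits2 <- search_proteome(q2, proteome)
  expect_equal(sum(hits2$subject_id == "q1"), 2L)
})

test_that("lowering the cutoff never adds hits", {
  reg <- query_registry()
  lysx <- reg[reg$name == "LysX", ]
  proteome <- dplyr::bind_rows(
    prot("homolog", mutate_protein(prot("h", lysx$sequence), 0.5,
                                   seed = 5)$sequence),
    purrr::map_dfr(1:10, function(i) prot(paste0("d", i),
                                          random_peptide(300, seed = i))))
  loose <- search_proteome(lysx, proteome, search_config(1e-5))
  strict <- search_proteome(lysx, proteome, search_config(1e-30))
  expect_true(all(strict$subject_id %in% loose$subject_id))
})

test_that("planted homologs are recovered and decoys rejected", {
  reg <- query_registry()
  queries <- reg[reg$name %in% c("LysX", "casei_NBD", "NSR_Saga"), ]
  withr::with_seed(21, {
    decoys <- purrr::map_dfr(1:50, function(i) {
      prot(paste0("decoy", i), random_peptide(sample(150:400, 1)))
    })
    for (ident in c(0.3, 0.5, 0.7)) {
      homs <- purrr::map_dfr(seq_len(nrow(queries)), function(i) {
        q <- queries[i, ]
        prot(paste0("hom_", q$name),
             mutate_protein(prot(q$name, q$sequence), ident,
                            protected = q$motifs[[1]])$sequence)
      })
      hits <- search_proteome(queries, dplyr::bind_rows(homs, decoys))
      # recall 1: each query finds its planted homolog
      for (qn in queries$name) {
        expect_true(paste0("hom_", qn) %in%
                      hits$subject_id[hits$query_id == qn])
      }
      # no decoy passes the 1e-10 filter
      expect_false(any(grepl("^decoy", hits$subject_id)))
    }
  })
})
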