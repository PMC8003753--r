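test_that("single hydrophobic stretch yields one helix that tiles", {
  seq <- paste0(strrep("K", 20), strrep("L", 25), strrep("K", 20))
  pred <- predict_tmh(prot("x", seq))
  expect_equal(pred$n_tmh, 1L)
  expect_equal(nrow(pred$loops), 2L)
  # helices plus loops tile the protein
  iv <- dplyr::arrange(dplyr::bind_rows(pred$tmh,
                                        pred$loops[, c("start", "end")]),
                       start)
  expect_equal(iv$start[1], 1L)
  expect_equal(iv$end[nrow(iv)], nchar(seq))
  expect_true(all(iv$start[-1] == iv$end[-nrow(iv)] + 1L))

  expect_equal(predict_tmh(prot("k", strrep("K", 100)))$n_tmh, 0L)
  expect_error(predict_tmh(prot("s", "MKT")), "shorter than")
})

test_that("ten poly-LIV helices with KRKE-rich loops give ten helices", {
  loop <- "TSKRKEKRKEKRKST"  # 15 aa, KRKE-rich core
  helix <- paste(rep(c("L", "I", "V"), 7), collapse = "")  # 21 aa
  seq <- paste0(loop, paste(rep(paste0(helix, loop), 10), collapse = ""))
  pred <- predict_tmh(prot("deca", seq))
  expect_equal(pred$n_tmh, 10L)
  expect_equal(pred$n_term_side, "in")
  expect_true(all(pred$loops$side == rep(c("in", "out"),
                                         length.out = nrow(pred$loops))))
})

test_that("predictions are invariant under a hydropathy scale shift", {
  seq <- paste0(strrep("E", 25), strrep("I", 21), strrep("K", 12),
                strrep("L", 21), strrep("D", 25))
  base <- predict_tmh(prot("x", seq))
  cfg <- topology_config(tmh_threshold = 1.6 + 2,
                         scale = kyte_doolittle() + 2)
  shifted <- predict_tmh(prot("x", seq), cfg)
  expect_equal(shifted$tmh, base$tmh)
  expect_equal(shifted$loops, base$loops)
})

test_that("transporter classification keys on the loop between helices 7/8", {
  with_ecd <- build_membrane_protein(10, c(30, rep(12, 9), 20),
                                     ecd_between = c(7, 8),
                                     ecd_length = 180, seed = 1)
  pred <- predict_tmh(with_ecd$record)
  cls <- classify_transporter(pred)
  expect_equal(cls$label, "BceAB_with_ECD")
  expect_true(cls$ecd$loop_length >= 50)

  without <- build_membrane_protein(10, c(30, rep(12, 9), 20), seed = 2)
  expect_equal(classify_transporter(predict_tmh(without$record))$label,
               "corynebacterium_type_no_ECD")

  six <- build_membrane_protein(6, c(30, rep(12, 5), 20), seed = 3)
  expect_equal(classify_transporter(predict_tmh(six$record))$label,
               "not_pep7e")
})

test_that("kinase classification separates cytoplasmic, BceS- and CprK-like", {
  reg <- query_registry()
  hk <- predict_tmh(prot("hk", reg$sequence[reg$name == "casei_HK"]))
  expect_equal(classify_kinase(hk), "cytoplasmic")

  nsrk <- predict_tmh(prot("nsrk", reg$sequence[reg$name == "NsrK_Saga"]))
  expect_equal(classify_kinase(nsrk), "BceS_like")

  cprk <- build_membrane_protein(2, c(15, 120, 200), ecd_between = c(1, 2),
                                 ecd_length = 120, seed = 4)
  expect_equal(classify_kinase(predict_tmh(cprk$record)), "CprK_like")
})

test_that("planted helix counts are recovered across random constructs", {
  ok <- 0; n <- 60
  withr::with_seed(31, {
    for (k in seq_len(n)) {
      nh <- sample(1:12, 1)
      loops <- c(sample(15:40, 1), rep(12L, max(nh - 1, 0)),
                 sample(15:40, 1))[seq_len(nh + 1)]
      mp <- build_membrane_protein(nh, loops, seed = sample.int(1e6, 1))
      pred <- predict_tmh(mp$record)
      if (pred$n_tmh == nh) ok <- ok + 1
      # sides must alternate in every prediction
      first <- pred$loops$side[1]
      other <- setdiff(c("in", "out"), first)
      expect_equal(pred$loops$side,
                   rep(c(first, other), length.out = nrow(pred$loops)))
    }
  })
  expect_gte(ok / n, 0.95)
})

test_that("the permease stand-ins differ by the planted ECD", {
  reg <- query_registry()
  casei <- prot("c", reg$sequence[reg$name == "casei_permease"])
  nsrp <- prot("n", reg$sequence[reg$name == "NsrP_Saga"])
  expect_equal(length_difference(prot("a", strrep("A", 451)),
                                 prot("b", strrep("A", 651))), 200L)
  expect_equal(length_difference(casei, casei), 0L)
  # the ECD-bearing stand-in is larger by the ECD minus the replaced loop
  expect_equal(length_difference(casei, nsrp), 200L)
})
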