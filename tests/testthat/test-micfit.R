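test_that("relative growth normalizes to the untreated control", {
  assay <- tibble::tibble(
    strain = "s", condition = "uninduced",
    concentration = c(4, 2, 1, 0, 0),
    od_t0 = 0.05,
    od_t24 = c(0.05, 0.55, 1.05, 1.05, 1.05),
    is_untreated = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  rel <- relative_growth(assay)
  expect_equal(rel$rel_growth, c(0, 0.5, 1))

  bad <- assay
  bad$od_t24[bad$is_untreated] <- 0.04
  expect_error(relative_growth(bad), "denominator")
})

test_that("noise-free simulated plates reproduce the generating curve", {
  a <- simulate_assay(1.25, slope = 10, noise_sd = 0, seed = 1)
  rel <- relative_growth(a)
  truth <- attr(a, "truth")
  expect_equal(rel$rel_growth,
               gompertz_response(rel$concentration, 1, truth$true_mic / 2,
                                 truth$slope))
})

test_that("Gompertz fitting recovers exact and noisy parameters", {
  conc <- mic_grid(top = 10, n_steps = 8)
  exact <- tibble::tibble(concentration = conc,
                          rel_growth = gompertz_response(conc, 1, 0.6, 8))
  f <- fit_gompertz(exact)
  expect_equal(f$A, 1, tolerance = 1e-6)
  expect_equal(f$m, 0.6, tolerance = 1e-6)
  expect_equal(f$s, 8, tolerance = 1e-5)
  expect_lt(f$rss, 1e-10)
  expect_false(f$boundary)
  expect_equal(tidy(f)$term, c("A", "m", "s"))
  expect_true(glance(f)$converged)

  ok <- 0
  withr::with_seed(17, {
    for (k in 1:25) {
      pts <- tibble::tibble(
        concentration = rep(conc, 3),
        rel_growth = gompertz_response(rep(conc, 3), 1, 0.6, 8) +
          stats::rnorm(24, 0, 0.05))
      fk <- fit_gompertz(pts)
      if (abs(fk$m - 0.6) / 0.6 < 0.15) ok <- ok + 1
    }
  })
  expect_gte(ok, 24)

  # growth rising with dose violates the model shape
  rising <- tibble::tibble(concentration = sort(conc),
                           rel_growth = seq(0.1, 0.9,
                                            length.out = length(conc)))
  expect_true(tryCatch(fit_gompertz(rising)$boundary,
                       error = function(e) TRUE))
})

test_that("MIC reading requires a contiguous no-growth tail", {
  pts <- tibble::tibble(
    concentration = c(10, 5, 2.5, 1.25, 0.625, 0.3125),
    rel_growth = c(0, 0, 0, 0, 0.6, 0.95))
  expect_equal(extract_mic(pts)$mic, 1.25)
  # row order does not matter
  expect_equal(extract_mic(pts[sample(nrow(pts)), ])$mic, 1.25)

  grown <- pts; grown$rel_growth <- grown$rel_growth + 0.5
  res <- extract_mic(grown)
  expect_true(res$censored)
  expect_match(res$mic_label, ">")

  # an isolated dip with regrowth above is ignored (and logged)
  dip <- tibble::tibble(
    concentration = c(10, 5, 2.5, 1.25, 0.625),
    rel_growth = c(0, 0, 0.4, 0.02, 0.9))
  expect_message(r2 <- extract_mic(dip), "isolated")
  expect_equal(r2$mic, 5)
})

test_that("planted MICs come back exactly over the whole dilution grid", {
  for (m in mic_grid()) {
    rel <- relative_growth(simulate_assay(m, slope = 10, noise_sd = 0,
                                          seed = 3))
    expect_equal(extract_mic(rel)$mic, m)
  }
  beyond <- relative_growth(simulate_assay(2 * mic_grid()[1], slope = 10,
                                           noise_sd = 0, seed = 3))
  expect_true(extract_mic(beyond)$censored)
})

test_that("noisy plates stay within one dilution step of the planted MIC", {
  hit <- 0; n <- 200
  grid <- mic_grid()
  for (s in seq_len(n)) {
    m <- grid[3 + (s %% 7)]
    rel <- relative_growth(simulate_assay(m, slope = 10, noise_sd = 0.05,
                                          seed = s))
    mic <- suppressMessages(extract_mic(rel))$mic
    if (!is.na(mic) && abs(log2(mic / m)) <= 1) hit <- hit + 1
  }
  expect_gte(hit / n, 0.95)
})

test_that("fold changes reproduce the induction arithmetic", {
  fc <- fold_change(tibble::tibble(mic = 5, censored = FALSE),
                    tibble::tibble(mic = 1.25, censored = FALSE))
  expect_equal(fc$fold_change, 4)
  # printed-value arithmetic: 1.25 / 0.63 reads as 2-fold at dilution-step
  # resolution
  fc2 <- fold_change(tibble::tibble(mic = 1.25, censored = FALSE),
                     tibble::tibble(mic = 0.63, censored = FALSE))
  expect_equal(fc2$fold_change, 1.9841, tolerance = 1e-4)
  expect_equal(2^round(log2(fc2$fold_change)), 2)
  expect_equal(fold_change(tibble::tibble(mic = 5, censored = FALSE),
                           tibble::tibble(mic = 5, censored = FALSE))
               $fold_change, 1)
  cens <- fold_change(tibble::tibble(mic = NA_real_, censored = TRUE),
                      tibble::tibble(mic = 5, censored = FALSE))
  expect_true(is.na(cens$fold_change))
  expect_match(cens$reason, "censored")
})

test_that("plate TSVs round-trip through read_plate and mic_table", {
  a1 <- simulate_assay(1.25, seed = 1, strain = "Cglu",
                       condition = "uninduced")
  a2 <- simulate_assay(1.25, seed = 2, strain = "Cglu",
                       condition = "induced")
  plate <- dplyr::bind_rows(a1, a2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(strain = plate$strain, condition = plate$condition,
               concentration_ug_ml = plate$concentration,
               od600_t0 = plate$od_t0, od600_t24 = plate$od_t24,
               is_untreated = plate$is_untreated),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_plate(tsv)
  tab <- mic_table(back)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$mic, c(1.25, 1.25))
  expect_equal(tab$fold_change, c(1, 1))
})
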