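seq_of <- function(...) paste(c(...), collapse = "")

test_that("JC69 distances follow the closed form with site filtering", {
  aln <- tibble::tibble(
    taxon = c("a", "b", "c"),
    sequence = c(strrep("A", 100),
                 paste0(strrep("C", 10), strrep("A", 90)),
                 strrep("A", 100)))
  d <- jc69_distance(aln)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], -0.75 * log(1 - 0.4 / 3))
  expect_true(isSymmetric(d))

  # gap and N columns are excluded per pair
  aln2 <- tibble::tibble(
    taxon = c("a", "b", "c"),
    sequence = c("AAAA-AAANA", "AAAACAAACC", "AAAAAAAAAA"))
  d2 <- jc69_distance(aln2)
  # gap and N columns drop out for a/b: 8 comparable, 1 mismatch
  expect_equal(d2["a", "b"], -0.75 * log(1 - (4 / 3) * (1 / 8)))

  # no comparable columns is an error naming the pair
  aln3 <- tibble::tibble(taxon = c("a", "b", "c"),
                         sequence = c("----AAAA", "AAAA----", "AAAAAAAA"))
  expect_error(jc69_distance(aln3), "no comparable columns.*a.*b")

  # saturation goes to the ceiling with a warning
  aln4 <- tibble::tibble(taxon = c("a", "b", "c"),
                         sequence = c("ACGTACGTACGT", "CGATCGATCGAT",
                                      "ACGTACGTACGT"))
  expect_warning(d4 <- jc69_distance(aln4), "saturated")
  expect_equal(d4["a", "b"], 5)
})

test_that("JC69 distance is monotone in the mismatch fraction", {
  p <- seq(0.01, 0.70, by = 0.01)
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(d) > 0))
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  # closed form: x = (dab + dac - dbc) / 2, etc.
  bl <- stats::setNames(tr$edge.length,
                        c(tr$tip.label, "")[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), 1)
  expect_equal(unname(bl["b"]), 2)
  expect_equal(unname(bl["c"]), 3)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "at least 3 taxa")
})

test_that("NJ reconstructs additive trees exactly", {
  withr::with_seed(13, {
    for (k in 1:20) {
      nt <- sample(5:8, 1)
      tr <- random_tree(nt, seed = sample.int(1e6, 1))
      dm <- ape::cophenetic.phylo(tr)
      rec <- nj_tree(dm)
      expect_equal(ape::dist.topo(ape::unroot(tr), rec), 0,
                   ignore_attr = TRUE)
      # path lengths equal the input distances
      expect_equal(ape::cophenetic.phylo(rec)[rownames(dm), colnames(dm)],
                   dm, tolerance = 1e-8)
    }
  })
})

test_that("branch lengths are clamped at zero and input must be symmetric", {
  dm <- matrix(c(0, 0.1, 0.1, 0.4,
                 0.1, 0, 0.02, 0.4,
                 0.1, 0.02, 0, 0.4,
                 0.4, 0.4, 0.4, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length >= 0))
  bad <- dm; bad[1, 2] <- 9
  expect_error(nj_tree(bad), "symmetric")
})

test_that("bootstrap supports are reproducible and signal-responsive", {
  # two well-separated four-taxon clades
  tr <- ape::read.tree(text = paste0(
    "((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.05,",
    "((e:0.05,f:0.05):0.05,(g:0.05,h:0.05):0.3):0.3);"))
  aln <- evolve_alignment(tr, 1000, seed = 5)
  b1 <- bootstrap_support(aln, replicates = 200, seed = 11)
  b2 <- bootstrap_support(aln, replicates = 200, seed = 11)
  expect_identical(b1$node.label, b2$node.label)
  expect_gte(max(attr(b1, "support"), na.rm = TRUE), 0.95)

  ident <- tibble::tibble(taxon = letters[1:4],
                          sequence = rep(strrep("ACGT", 50), 4))
  expect_warning(star <- bootstrap_support(ident, replicates = 5,
                                           seed = 1), "star tree")
  expect_true(all(star$node.label == "1"))
})

test_that("outgroup rooting is stable and validated", {
  tr <- nj_tree(ape::cophenetic.phylo(random_tree(4, seed = 3)))
  rooted <- root_on(tr, "t4")
  expect_true(ape::is.rooted(rooted))
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1, 2]
  expect_true(which(rooted$tip.label == "t4") %in% kids)
  expect_equal(root_on(rooted, "t4")$tip.label, rooted$tip.label)
  expect_error(root_on(tr, "nope"), "unknown outgroup")
})

test_that("Newick output round-trips topology, lengths and supports", {
  tr <- random_tree(6, seed = 21)
  aln <- evolve_alignment(tr, 500, seed = 22)
  bs <- bootstrap_support(aln, replicates = 50, seed = 23)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(bs, nwk)
  back <- read_newick(nwk)
  expect_equal(ape::dist.topo(back, bs), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(bs$edge.length),
               tolerance = 1e-5)
  expect_setequal(back$node.label, bs$node.label)
})
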