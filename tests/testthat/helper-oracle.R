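# Independent brute-force affine-gap DP oracles, kept deliberately free of
# any code path used by the package (plain triple-loop recursions over the
# three-state matrices). A gap of length k costs gap_open + k * gap_extend.

oracle_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

oracle_local_score <- function(a, b, mat = oracle_submat(), go = 11,
                               ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i, j - 1] - go - ge, X[i, j - 1] - ge)
      Y[i, j] <- max(M[i - 1, j] - go - ge, Y[i - 1, j] - ge)
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + mat[A[i - 1], B[j - 1]])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

oracle_global_score <- function(a, b, mat = oracle_submat(), go = 11,
                                ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) X[1, j] <- -go - (j - 1) * ge
  for (i in 2:(n + 1)) Y[i, 1] <- -go - (i - 1) * ge
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i, j - 1] - go - ge, X[i, j - 1] - ge)
      Y[i, j] <- max(M[i - 1, j] - go - ge, Y[i - 1, j] - ge)
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + mat[A[i - 1], B[j - 1]]
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_peptide <- function(len, seed = NULL) {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  freq <- c(8.3, 5.5, 4.1, 5.5, 1.4, 3.9, 6.8, 7.1, 2.3, 6.0, 9.7, 5.8,
            2.4, 3.9, 4.7, 6.6, 5.3, 1.1, 2.9, 6.9)
  draw <- function() paste(sample(aas, len, TRUE, prob = freq),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

prot <- function(id, seq) tibble::tibble(id = id, sequence = seq)
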