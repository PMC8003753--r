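#' Scoring scheme for protein alignment
#'
#' Bundles the substitution matrix, affine gap costs and gapped
#' Karlin-Altschul parameters used throughout the homology search. Defaults
#' are the classic BLASTP settings (BLOSUM62, gap existence 11, gap
#' extension 1) with the standard published gapped parameters for that
#' combination (lambda = 0.267, K = 0.041). A gap of length k costs
#' `gap_open + k * gap_extend`.
#'
#' @param matrix_name Name of a substitution matrix bundled with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Positive integer gap costs.
#' @param lambda,K Karlin-Altschul parameters for [evalue_ka()].
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, K = 0.041) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 1, lambda > 0, K > 0)
  mat <- .load_submat(matrix_name)
  stopifnot(isSymmetric(unname(mat)))
  structure(
    list(matrix_name = matrix_name, substitution = mat,
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         lambda = lambda, K = K),
    class = "scoring_scheme"
  )
}

.load_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", x$matrix_name, "; gap ", x$gap_open, "/",
      x$gap_extend, "; lambda=", x$lambda, ", K=", x$K, "\n", sep = "")
  invisible(x)
}

#' Search configuration for proteome screening
#'
#' @param evalue_cutoff Retain only hits with E-value strictly below this
#'   (default `1e-10`, the survey's filter).
#' @param scheme A [scoring_scheme()].
#' @param search_space `"pairwise"` (E-value from the two sequence lengths of
#'   each pair) or `"effective"` (n = total proteome length, for sensitivity
#'   analysis).
#' @return An object of class `search_config`.
#' @export
search_config <- function(evalue_cutoff = 1e-10, scheme = scoring_scheme(),
                          search_space = c("pairwise", "effective")) {
  stopifnot(evalue_cutoff > 0, inherits(scheme, "scoring_scheme"))
  structure(list(evalue_cutoff = evalue_cutoff, scheme = scheme,
                 search_space = match.arg(search_space)),
            class = "search_config")
}

# Accept either `id` or `name` as the identifier column of a record table.
.as_record_tbl <- function(x) {
  if (!"id" %in% names(x)) {
    x <- dplyr::rename(x, id = "name")
  }
  x
}

# Identity over the aligned columns of a pairwiseAlignment, gaps counted in
# the denominator.
.aln_identity <- function(pa) {
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  if (length(p) == 0) return(0)
  sum(p == s & p != "-") / length(p)
}

#' Exact local alignment of two proteins
#'
#' Smith-Waterman local alignment with affine gaps -- the deterministic,
#' oracle-checkable stand-in for a heuristic BLASTP hit. Raw scores below
#' zero (possible when no residue pair scores positively) are clamped to 0.
#'
#' @param query,subject Single-row protein record tibbles (or anything with
#'   `id` and `sequence`), or plain named character vectors of length 1.
#' @param scheme A [scoring_scheme()].
#' @return A one-row tibble: `query_id`, `subject_id`, `raw_score`,
#'   `bit_score`, `evalue`, `identity` (in \[0,1\]), `aligned_length`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme()) {
  q <- .as_protein(query); s <- .as_protein(subject)
  if (nchar(q$sequence) == 0 || nchar(s$sequence) == 0) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q$sequence), Biostrings::AAString(s$sequence),
    substitutionMatrix = scheme$substitution,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "local")
  raw <- max(0, Biostrings::score(pa))
  tibble::tibble(
    query_id = q$id, subject_id = s$id,
    raw_score = raw,
    bit_score = (scheme$lambda * raw - log(scheme$K)) / log(2),
    evalue = evalue_ka(raw, nchar(q$sequence), nchar(s$sequence), scheme),
    identity = .aln_identity(pa),
    aligned_length = nchar(as.character(Biostrings::alignedPattern(pa))),
    query_start = Biostrings::start(Biostrings::pattern(pa)),
    query_end = Biostrings::end(Biostrings::pattern(pa)),
    subject_start = Biostrings::start(Biostrings::subject(pa)),
    subject_end = Biostrings::end(Biostrings::subject(pa))
  )
}

.as_protein <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    id <- if ("id" %in% names(x)) x$id else x$name
    list(id = id, sequence = x$sequence)
  } else if (is.character(x) && length(x) == 1) {
    list(id = if (is.null(names(x))) "seq" else names(x),
         sequence = unname(x))
  } else {
    stop("expected a one-row record tibble or a character scalar")
  }
}

#' Global percent identity of two proteins
#'
#' Needleman-Wunsch global alignment under the same scheme; identity is
#' identical columns divided by the full alignment length, gap columns
#' included in the denominator (the conservative reading of "sequence
#' identity").
#'
#' @inheritParams local_align
#' @return A single numeric in \[0, 1\].
#' @export
global_identity <- function(a, b, scheme = scoring_scheme()) {
  x <- .as_protein(a); y <- .as_protein(b)
  if (nchar(x$sequence) == 0 || nchar(y$sequence) == 0) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(x$sequence), Biostrings::AAString(y$sequence),
    substitutionMatrix = scheme$substitution,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "global")
  .aln_identity(pa)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between sequences of lengths `m` and `n`.
#' Strictly decreasing in `S`, linear in `m` and `n`.
#'
#' @param raw_score Alignment raw score `S`.
#' @param m,n Sequence (or search-space) lengths, both >= 1.
#' @param scheme A [scoring_scheme()] supplying `lambda` and `K`.
#' @return Positive numeric E-value (vectorized over `raw_score`).
#' @export
evalue_ka <- function(raw_score, m, n, scheme = scoring_scheme()) {
  stopifnot(m >= 1, n >= 1)
  scheme$K * m * n * exp(-scheme$lambda * raw_score)
}

#' Screen a proteome with a set of query proteins
#'
#' Aligns every query against every subject, keeps the best hit per
#' (query, subject) pair, drops hits at or above the E-value cutoff and
#' returns the survivors sorted by ascending E-value. Deduplication is per
#' query: two queries hitting the same subject yield two hits.
#'
#' @param queries,proteome Protein record tibbles (`id`, `sequence`).
#' @param config A [search_config()].
#' @return A hit tibble in [local_align()] format, with `identity` in
#'   \[0,1\]; use [export_hits()] for the 0-100 tabular convention.
#' @export
search_proteome <- function(queries, proteome, config = search_config()) {
  stopifnot(nrow(queries) > 0, nrow(proteome) > 0)
  queries <- .as_record_tbl(queries)
  proteome <- .as_record_tbl(proteome)
  scheme <- config$scheme
  n_eff <- sum(nchar(proteome$sequence))
  subj_set <- Biostrings::AAStringSet(proteome$sequence)
  hits <- purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    pas <- Biostrings::pairwiseAlignment(
      subj_set, Biostrings::AAString(q$sequence),
      substitutionMatrix = scheme$substitution,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
      type = "local")
    raw <- pmax(0, Biostrings::score(pas))
    n_sp <- if (config$search_space == "effective") n_eff
            else nchar(proteome$sequence)
    ev <- evalue_ka(raw, nchar(q$sequence), n_sp, scheme)
    keep <- which(ev < config$evalue_cutoff)
    if (length(keep) == 0) return(NULL)
    purrr::map_dfr(keep, function(j) {
      pa <- pas[j]
      tibble::tibble(
        query_id = q$id, subject_id = proteome$id[j],
        raw_score = raw[j],
        bit_score = (scheme$lambda * raw[j] - log(scheme$K)) / log(2),
        evalue = ev[j],
        identity = .aln_identity(pa),
        aligned_length = nchar(as.character(Biostrings::alignedPattern(pa))),
        query_start = Biostrings::start(Biostrings::subject(pa)),
        query_end = Biostrings::end(Biostrings::subject(pa)),
        subject_start = Biostrings::start(Biostrings::pattern(pa)),
        subject_end = Biostrings::end(Biostrings::pattern(pa))
      )
    })
  })
  if (is.null(hits) || nrow(hits) == 0) {
    return(tibble::tibble(
      query_id = character(), subject_id = character(), raw_score = numeric(),
      bit_score = numeric(), evalue = numeric(), identity = numeric(),
      aligned_length = integer(), query_start = integer(),
      query_end = integer(), subject_start = integer(),
      subject_end = integer()))
  }
  hits |>
    dplyr::group_by(.data$query_id, .data$subject_id) |>
    dplyr::slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$evalue)
}

#' Write a hit table in the fixed tabular convention
#'
#' Columns: query_id, subject_id, identity (0-100), aligned_length,
#' raw_score, bit_score, evalue.
#'
#' @param hits Hit tibble from [search_proteome()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_hits <- function(hits, path) {
  out <- dplyr::transmute(
    hits, .data$query_id, .data$subject_id,
    identity = round(100 * .data$identity, 2), .data$aligned_length,
    .data$raw_score, bit_score = round(.data$bit_score, 2), .data$evalue)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
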