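# Sequence-signature domain models and role assignment.
#
# Degenerate PROSITE-style patterns stand in for the Pfam domains the locus
# typing needs (FtsX permease, S41 peptidase, HK, RR, ABC NBD). Models are
# shipped as a plain-text file under inst/extdata and parsed at load time.

#' Convert a PROSITE-style pattern to a regular expression
#'
#' Supports fixed residues, `x` wildcards, `[ABC]` alternatives and `(n)`
#' repeats of the preceding element, with positions separated by `-`.
#'
#' @param pattern A PROSITE-style pattern string, e.g.
#'   `"[AG]-x(4)-G-K-[ST]"`.
#' @return A regular expression string.
#' @export
prosite_to_regex <- function(pattern) {
  toks <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  parts <- vapply(toks, function(tok) {
    rep_n <- 1L
    m <- regmatches(tok, regexec("\\((\\d+)\\)$", tok))[[1]]
    if (length(m) == 2) {
      rep_n <- as.integer(m[2])
      tok <- sub("\\(\\d+\\)$", "", tok)
    }
    base <- if (tok == "x") "." else if (grepl("^\\[", tok)) tok
            else if (nchar(tok) == 1) tok
            else stop("bad pattern token: ", tok)
    paste(rep(base, rep_n), collapse = "")
  }, character(1))
  paste(parts, collapse = "")
}

#' Load the bundled domain signature models
#'
#' @param path Optional path to an alternative model file in the documented
#'   plain-text format (see `inst/extdata/domain_models.txt`).
#' @return A tibble with columns `name`, `min_matches`, `patterns`
#'   (list-column of pattern strings), `regex` (list-column) and
#'   `description`.
#' @export
domain_models <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "domain_models.txt", package = "lantiscan")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    name = vapply(fields, `[[`, "", 1),
    min_matches = as.integer(vapply(fields, `[[`, "", 2)),
    patterns = lapply(fields, function(f) strsplit(f[[3]], ";")[[1]]),
    description = vapply(fields, `[[`, "", 4)
  ) |>
    dplyr::mutate(regex = lapply(.data$patterns,
                                 function(p) vapply(p, prosite_to_regex,
                                                    character(1))))
}

#' Scan a protein for domain signature models
#'
#' A call is emitted for every model whose number of matching patterns
#' reaches `min_matches`; its span runs from the first to the last matched
#' pattern occurrence. Calls are sorted by span start.
#'
#' @param protein One-row protein record tibble (or named character scalar).
#' @param models Model tibble from [domain_models()].
#' @return A tibble `protein_id`, `domain`, `start`, `end`,
#'   `matched_patterns` (possibly empty).
#' @export
scan_domains <- function(protein, models = domain_models()) {
  p <- .as_protein(protein)
  stopifnot(nrow(models) > 0)
  calls <- purrr::map_dfr(seq_len(nrow(models)), function(i) {
    spans <- purrr::map_dfr(models$regex[[i]], function(rx) {
      m <- stringr::str_locate(p$sequence, rx)
      if (is.na(m[1, 1])) NULL
      else tibble::tibble(start = m[1, 1], end = m[1, 2])
    })
    if (nrow(spans) < models$min_matches[i]) return(NULL)
    tibble::tibble(protein_id = p$id, domain = models$name[i],
                   start = as.integer(min(spans$start)),
                   end = as.integer(max(spans$end)),
                   matched_patterns = nrow(spans))
  })
  if (nrow(calls) == 0) {
    return(tibble::tibble(protein_id = character(), domain = character(),
                          start = integer(), end = integer(),
                          matched_patterns = integer()))
  }
  dplyr::arrange(calls, .data$start)
}

#' Locate a TASSAEM-like catalytic peptidase motif
#'
#' Scores every 7-residue window against the S41 catalytic box `TASSAEM`
#' (identical positions out of 7) and reports the best window when it
#' reaches `min_identity` identities *and* carries the catalytically
#' required serine at window position 3. Ties go to the smallest start. The
#' rule accepts naturally degenerate boxes such as `TGSSGEA` (4/7 with the
#' serine conserved) while rejecting random 7-mers.
#'
#' @param protein One-row protein record tibble (length >= 7).
#' @param min_identity Minimum identical positions out of 7 (default 4).
#' @return A one-row tibble `protein_id`, `start`, `end`,
#'   `matched_positions`, `serine_conserved`, `window` -- or an empty tibble
#'   when no qualifying window exists.
#' @export
find_catalytic_motif <- function(protein, min_identity = 4L) {
  p <- .as_protein(protein)
  L <- nchar(p$sequence)
  stopifnot(L >= 7)
  ref <- strsplit("TASSAEM", "")[[1]]
  chars <- strsplit(p$sequence, "")[[1]]
  n_win <- L - 6L
  scores <- vapply(seq_len(n_win), function(i) {
    sum(chars[i:(i + 6L)] == ref)
  }, numeric(1))
  ser <- chars[seq_len(n_win) + 2L] == "S"
  ok <- which(scores >= min_identity & ser)
  empty <- tibble::tibble(protein_id = character(), start = integer(),
                          end = integer(), matched_positions = integer(),
                          serine_conserved = logical(), window = character())
  if (length(ok) == 0) return(empty)
  best <- ok[which.max(scores[ok])]  # which.max: smallest index on ties
  tibble::tibble(protein_id = p$id, start = best, end = best + 6L,
                 matched_positions = as.integer(scores[best]),
                 serine_conserved = TRUE,
                 window = substring(p$sequence, best, best + 6L))
}

# Role labels in precedence order; a single deterministic label per gene.
.role_precedence <- c("permease", "NSR_peptidase", "HK", "RR", "NBD")
.domain_to_role <- c(FtsX_permease = "permease", S41_peptidase = "NSR_peptidase",
                     HisKinase = "HK", ResponseRegulator = "RR",
                     ABC_NBD = "NBD")

#' Assign a functional role from domain calls and homology hits
#'
#' Domain calls map directly to roles (FtsX_permease -> permease,
#' S41_peptidase -> NSR_peptidase, HisKinase -> HK, ResponseRegulator -> RR,
#' ABC_NBD -> NBD) with the precedence
#' permease > NSR_peptidase > HK > RR > NBD when several domains co-occur.
#' A protein with no domain call but a retained hit to a LysX/MprF query is
#' `LysX_like`; otherwise `none`.
#'
#' @param calls Domain-call tibble from [scan_domains()] for one protein.
#' @param hits Retained homology hits for the same protein (may be empty);
#'   only `query_id` is inspected.
#' @param lysx_queries Query ids counting as lysyltransferase evidence.
#' @return A single role label string.
#' @export
assign_role <- function(calls, hits = NULL,
                        lysx_queries = c("LysX", "MprF")) {
  roles <- unname(.domain_to_role[calls$domain])
  roles <- roles[!is.na(roles)]
  for (r in .role_precedence) {
    if (r %in% roles) return(r)
  }
  if (!is.null(hits) && nrow(hits) > 0 &&
      any(hits$query_id %in% lysx_queries)) {
    return("LysX_like")
  }
  "none"
}

#' Write domain calls as TSV
#' @param calls Domain-call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_domain_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
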