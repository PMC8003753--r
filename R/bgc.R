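# Rule-transparent bacteriocin gene cluster (BGC) detection and
# Class I/II/III assignment. Precursors are called from explicit
# length/composition rules; Class I additionally needs homology to bundled
# lanthipeptide-modification-enzyme queries.

#' BGC detection configuration
#'
#' @param precursor_min_len,precursor_max_len Length window (aa) for
#'   precursor peptide candidates (default 20-80).
#' @param stc_min Minimum combined Ser+Thr+Cys fraction of a precursor
#'   (default 0.20) -- the residues that become dehydrated/thioether-bridged
#'   in lanthipeptides.
#' @param large_bacteriocin_min Minimum length (aa) of a Class III
#'   bacteriocin candidate (default 90).
#' @param precursor_evalue Relaxed E-value cutoff for short precursor
#'   queries such as nisin (default 1e-3; the survey-wide 1e-10 filter is
#'   uninformative at ~34 aa query length).
#' @param clustering A [cluster_config()] used to gather cluster members
#'   around a precursor.
#' @return A `bgc_config` object.
#' @export
bgc_config <- function(precursor_min_len = 20L, precursor_max_len = 80L,
                       stc_min = 0.20, large_bacteriocin_min = 90L,
                       precursor_evalue = 1e-3,
                       clustering = cluster_config()) {
  stopifnot(precursor_min_len <= precursor_max_len, stc_min >= 0,
            large_bacteriocin_min > 0, precursor_evalue > 0)
  structure(list(precursor_min_len = as.integer(precursor_min_len),
                 precursor_max_len = as.integer(precursor_max_len),
                 stc_min = stc_min,
                 large_bacteriocin_min = as.integer(large_bacteriocin_min),
                 precursor_evalue = precursor_evalue,
                 clustering = clustering),
            class = "bgc_config")
}

#' Find bacteriocin precursor peptide candidates
#'
#' Candidates are proteins inside the configured length window whose
#' combined S+T+C content reaches `stc_min`; sorted by descending S+T+C
#' fraction.
#'
#' @param proteome Protein record tibble (`id`, `sequence`).
#' @param config A [bgc_config()].
#' @return Tibble `orf_id`, `length`, `stc_fraction`.
#' @export
find_precursors <- function(proteome, config = bgc_config()) {
  len <- nchar(proteome$sequence)
  stc <- stringr::str_count(proteome$sequence, "[STC]") / pmax(len, 1L)
  keep <- len >= config$precursor_min_len & len <= config$precursor_max_len &
    stc >= config$stc_min
  tibble::tibble(orf_id = proteome$id[keep], length = len[keep],
                 stc_fraction = stc[keep]) |>
    dplyr::arrange(dplyr::desc(.data$stc_fraction))
}

#' Is a precursor nisin-like?
#'
#' TRUE iff a local alignment of the candidate against the nisin query is
#' retained under the relaxed short-peptide cutoff.
#'
#' @param precursor,nisin_query One-row protein record tibbles.
#' @param config A [bgc_config()] (supplies `precursor_evalue`).
#' @param scheme A [scoring_scheme()].
#' @return Logical scalar.
#' @export
nisin_like <- function(precursor, nisin_query, config = bgc_config(),
                       scheme = scoring_scheme()) {
  hit <- local_align(precursor, nisin_query, scheme)
  hit$evalue < config$precursor_evalue
}

#' Classify one candidate cluster into a bacteriocin class
#'
#' Class I: precursor present and at least one member retains homology to a
#' modification-enzyme query (LanB/LanC/LanM stand-ins). Class II: precursor
#' present, no modification enzyme, and at least one transporter/peptidase
#' member (role NBD, permease or NSR_peptidase). Class III: a member of at
#' least `large_bacteriocin_min` aa with retained homology to the bundled
#' Class III query. Precedence I > II > III; when no rule fires the result
#' is `NA` (no BGC emitted).
#'
#' @param members Annotated gene tibble for the candidate cluster (needs
#'   `locus_tag`, `role`, `length`).
#' @param has_precursor Logical: does the cluster contain a precursor
#'   candidate?
#' @param modification_hits Hit tibble of members vs modification-enzyme
#'   queries (subject_id matched against member locus_tags).
#' @param class3_hits Hit tibble of members vs the Class III query.
#' @param config A [bgc_config()].
#' @return `"I"`, `"II"`, `"III"` or `NA_character_`.
#' @export
classify_bgc <- function(members, has_precursor, modification_hits,
                         class3_hits = NULL, config = bgc_config()) {
  mod <- nrow(modification_hits) > 0 &&
    any(modification_hits$subject_id %in% members$locus_tag)
  transporter <- any(members$role %in% c("NBD", "permease", "NSR_peptidase"))
  large <- !is.null(class3_hits) && nrow(class3_hits) > 0 &&
    any(class3_hits$subject_id %in%
          members$locus_tag[members$length >= config$large_bacteriocin_min])
  if (has_precursor && mod) return("I")
  if (has_precursor && !mod && transporter) return("II")
  if (large) return("III")
  NA_character_
}

#' Detect bacteriocin gene clusters in one annotated genome
#'
#' Calls precursor candidates, gathers the genes around each candidate under
#' the clustering rule, scores members against the modification-enzyme and
#' Class III queries from the registry, and assigns classes with
#' [classify_bgc()]. Large-bacteriocin (Class III) candidates without a
#' precursor are picked up separately.
#'
#' @param genes Annotated gene tibble ([annotate_genes()]): `locus_tag`,
#'   `start`, `end`, `role`, `length`, `sequence`, `genome_id`.
#' @param registry Query registry ([query_registry()]).
#' @param config A [bgc_config()].
#' @param scheme A [scoring_scheme()].
#' @return Tibble of BGC loci: `bgc_id`, `genome_id`, `start`, `end`,
#'   `bgc_class`, `precursor_orf`, `nisin_like`, `member_tags`,
#'   `members` list-column.
#' @export
detect_bgc <- function(genes, registry, config = bgc_config(),
                       scheme = scoring_scheme()) {
  empty <- tibble::tibble(bgc_id = character(), genome_id = character(),
                          start = integer(), end = integer(),
                          bgc_class = character(),
                          precursor_orf = character(),
                          nisin_like = logical(), member_tags = character(),
                          members = list())
  if (nrow(genes) == 0) return(empty)
  proteome <- tibble::tibble(id = genes$locus_tag, sequence = genes$sequence)
  precursors <- find_precursors(proteome, config)
  mod_queries <- registry[registry$purpose == "modification", ]
  class3_query <- registry[registry$role == "class3_bacteriocin", ]
  nisin_query <- registry[registry$role == "nisin_precursor", ]
  search_cfg <- search_config(scheme = scheme)
  mod_hits <- if (nrow(mod_queries) > 0) {
    search_proteome(mod_queries, proteome, search_cfg)
  } else NULL
  c3_hits <- if (nrow(class3_query) > 0) {
    search_proteome(class3_query, proteome, search_cfg)
  } else NULL

  genes <- dplyr::arrange(genes, .data$start)
  # genes that can be cluster members: precursor candidates, role-bearing
  # genes, and homologs of the modification / Class III queries
  in_mod <- if (!is.null(mod_hits) && nrow(mod_hits) > 0) {
    genes$locus_tag %in% mod_hits$subject_id
  } else rep(FALSE, nrow(genes))
  in_c3 <- if (!is.null(c3_hits) && nrow(c3_hits) > 0) {
    genes$locus_tag %in% c3_hits$subject_id
  } else rep(FALSE, nrow(genes))
  interesting <- genes$locus_tag %in% precursors$orf_id |
    genes$role %in% .locus_roles | in_mod | in_c3
  gather_members <- function(anchor_idx) {
    # chain outwards over interesting genes under the same adjacency rule
    # the loci module uses (intergenic distance + intervening gene count)
    idx <- anchor_idx
    ints <- which(interesting)
    repeat {
      grew <- FALSE
      lo <- min(idx); hi <- max(idx)
      prev <- ints[ints < lo]
      if (length(prev) > 0) {
        i <- max(prev)
        gap_bp <- genes$start[lo] - genes$end[i] - 1L
        intervening <- sum(!interesting[seq_len(nrow(genes)) > i &
                                          seq_len(nrow(genes)) < lo])
        if (gap_bp <= config$clustering$max_intergenic_bp &&
            intervening <= config$clustering$max_intervening_genes) {
          idx <- c(i, idx); grew <- TRUE
        }
      }
      nxt <- ints[ints > hi]
      if (length(nxt) > 0) {
        j <- min(nxt)
        gap_bp <- genes$start[j] - genes$end[hi] - 1L
        intervening <- sum(!interesting[seq_len(nrow(genes)) > hi &
                                          seq_len(nrow(genes)) < j])
        if (gap_bp <= config$clustering$max_intergenic_bp &&
            intervening <= config$clustering$max_intervening_genes) {
          idx <- c(idx, j); grew <- TRUE
        }
      }
      if (!grew) break
    }
    sort(unique(idx))
  }

  out <- list()
  used <- rep(FALSE, nrow(genes))
  for (orf in precursors$orf_id) {
    anchor <- which(genes$locus_tag == orf)
    if (length(anchor) == 0 || used[anchor]) next
    idx <- gather_members(anchor)
    members <- genes[idx, , drop = FALSE]
    cls <- classify_bgc(members, TRUE, mod_hits, c3_hits, config)
    if (is.na(cls)) next
    used[idx] <- TRUE
    nl <- if (nrow(nisin_query) == 1) {
      nisin_like(tibble::tibble(id = orf,
                                sequence = genes$sequence[anchor]),
                 nisin_query, config, scheme)
    } else FALSE
    out[[length(out) + 1L]] <- tibble::tibble(
      genome_id = genes$genome_id[1],
      start = min(members$start), end = max(members$end), bgc_class = cls,
      precursor_orf = orf, nisin_like = nl,
      member_tags = paste(members$locus_tag, collapse = ","),
      members = list(members))
  }
  # precursor-less Class III candidates
  if (!is.null(c3_hits) && nrow(c3_hits) > 0) {
    for (tag in unique(c3_hits$subject_id)) {
      anchor <- which(genes$locus_tag == tag)
      if (length(anchor) == 0 || used[anchor]) next
      if (genes$length[anchor] < config$large_bacteriocin_min) next
      idx <- gather_members(anchor)
      members <- genes[idx, , drop = FALSE]
      used[idx] <- TRUE
      out[[length(out) + 1L]] <- tibble::tibble(
        genome_id = genes$genome_id[1],
        start = min(members$start), end = max(members$end),
        bgc_class = "III", precursor_orf = NA_character_,
        nisin_like = FALSE,
        member_tags = paste(members$locus_tag, collapse = ","),
        members = list(members))
    }
  }
  if (length(out) == 0) return(empty)
  bgc <- dplyr::bind_rows(out) |> dplyr::arrange(.data$start)
  bgc$bgc_id <- sprintf("%s_bgc%02d", bgc$genome_id, seq_len(nrow(bgc)))
  dplyr::relocate(bgc, "bgc_id")
}

#' Does a BGC share genes with the resistance-search hits?
#'
#' TRUE iff any member of the cluster also appears as a retained subject in
#' the resistance BLAST-style results (matched by locus_tag) -- the
#' cross-referencing step that found no overlap in the survey.
#'
#' @param bgc One-row BGC tibble from [detect_bgc()].
#' @param resistance_hits Hit tibble from the resistance query search.
#' @return Logical scalar.
#' @export
cross_reference_bgc <- function(bgc, resistance_hits) {
  tags <- strsplit(bgc$member_tags[1], ",")[[1]]
  any(tags %in% resistance_hits$subject_id)
}
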