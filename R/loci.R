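# Distance-based clustering of role-bearing genes into candidate resistance
# loci, operon-architecture classification, and fragmented-peptidase
# detection.

#' Locus clustering configuration
#'
#' "Adjacent" is operationalized as at most `max_intergenic_bp` between
#' consecutive role-bearing genes with at most `max_intervening_genes`
#' role-less genes in between. Strand is ignored for clustering (divergently
#' transcribed pairs are common) and recorded per member for reporting.
#'
#' @param max_intergenic_bp Maximum intergenic distance in bp (default 2000).
#' @param max_intervening_genes Maximum role-less genes allowed between two
#'   clustered genes (default 1).
#' @return A `cluster_config` object.
#' @export
cluster_config <- function(max_intergenic_bp = 2000L,
                           max_intervening_genes = 1L) {
  stopifnot(max_intergenic_bp >= 0, max_intervening_genes >= 0)
  structure(list(max_intergenic_bp = as.integer(max_intergenic_bp),
                 max_intervening_genes = as.integer(max_intervening_genes)),
            class = "cluster_config")
}

# Roles that seed / join resistance loci. LysX_like marks cell-envelope
# modification enzymes, which are reported genome-wide, not clustered.
.locus_roles <- c("permease", "NSR_peptidase", "HK", "RR", "NBD")

#' Cluster annotated genes into candidate resistance loci
#'
#' Takes the per-genome annotated gene table (features plus a `role`
#' column, see [annotate_genes()]) and greedily chains role-bearing genes
#' that satisfy the adjacency rule; loci are maximal under this relation.
#' Role-less genes never seed a locus.
#'
#' @param genes Annotated gene tibble sorted by `(genome_id, start)`, with
#'   columns `gene_id`, `genome_id`, `start`, `end`, `strand`, `locus_tag`,
#'   `role`.
#' @param config A [cluster_config()].
#' @return A tibble of loci: `locus_id`, `genome_id`, `start`, `end`,
#'   `n_members`, `roles` (comma string), `members` (list-column holding the
#'   member gene rows in coordinate order).
#' @export
assemble_loci <- function(genes, config = cluster_config()) {
  genes <- dplyr::arrange(genes, .data$genome_id, .data$start)
  out <- list()
  for (gid in unique(genes$genome_id)) {
    g <- genes[genes$genome_id == gid, , drop = FALSE]
    seed_idx <- which(g$role %in% .locus_roles)
    if (length(seed_idx) == 0) next
    cluster_id <- integer(length(seed_idx))
    current <- 1L
    cluster_id[1] <- current
    if (length(seed_idx) > 1) {
      for (k in 2:length(seed_idx)) {
        i <- seed_idx[k - 1]; j <- seed_idx[k]
        gap_bp <- g$start[j] - g$end[i] - 1L
        intervening <- sum(!g$role[seq_len(nrow(g)) > i &
                                     seq_len(nrow(g)) < j] %in% .locus_roles)
        joined <- gap_bp <= config$max_intergenic_bp &&
          intervening <= config$max_intervening_genes
        if (!joined) current <- current + 1L
        cluster_id[k] <- current
      }
    }
    for (cl in unique(cluster_id)) {
      members <- g[seed_idx[cluster_id == cl], , drop = FALSE]
      out[[length(out) + 1L]] <- tibble::tibble(
        genome_id = gid,
        start = min(members$start), end = max(members$end),
        n_members = nrow(members),
        roles = paste(members$role, collapse = ","),
        members = list(members)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(locus_id = character(), genome_id = character(),
                          start = integer(), end = integer(),
                          n_members = integer(), roles = character(),
                          members = list()))
  }
  loci <- dplyr::bind_rows(out)
  loci$locus_id <- sprintf("%s_locus%02d", loci$genome_id,
                           as.integer(stats::ave(seq_len(nrow(loci)),
                                                 loci$genome_id,
                                                 FUN = seq_along)))
  dplyr::relocate(loci, "locus_id")
}

#' Classify the operon architecture of a resistance locus
#'
#' An ABC transporter counts as present when both an NBD and a permease role
#' occur (in separate genes or one fused gene); a TCS when both HK and RR
#' occur. The label combines the present groups
#' (`ABC_TCS_NSR`, `ABC_TCS`, `ABC_NSR`, `ABC_only`, `NSR_only`,
#' `TCS_only`). A locus whose roles complete none of the groups (e.g. an HK
#' without its RR, or a lone NBD) cannot be classified and raises an error.
#'
#' @param roles Character vector of member roles (or a one-row locus tibble
#'   from [assemble_loci()], whose `roles` string is used).
#' @return An architecture label string.
#' @export
classify_architecture <- function(roles) {
  if (is.data.frame(roles)) roles <- strsplit(roles$roles[1], ",")[[1]]
  roles <- unique(roles)
  if (!any(roles %in% .locus_roles)) {
    stop("locus has no recognized role; cannot classify", call. = FALSE)
  }
  abc <- ("NBD" %in% roles && "permease" %in% roles)
  tcs <- ("HK" %in% roles && "RR" %in% roles)
  nsr <- "NSR_peptidase" %in% roles
  label <- if (abc && tcs && nsr) "ABC_TCS_NSR"
    else if (abc && tcs) "ABC_TCS"
    else if (abc && nsr) "ABC_NSR"
    else if (abc) "ABC_only"
    else if (tcs && nsr) "TCS_NSR"
    else if (tcs) "TCS_only"
    else if (nsr) "NSR_only"
    else NA_character_
  if (is.na(label)) {
    stop("locus roles {", paste(roles, collapse = ","),
         "} complete no architecture group (e.g. HK without RR)",
         call. = FALSE)
  }
  label
}

#' Detect a peptidase split across two neighboring ORFs
#'
#' Two distinct ORFs hitting the same query are called fragments (rather
#' than paralogs) when their query spans overlap by less than
#' `max_overlap` of the shorter span while jointly covering at least
#' `min_union_coverage` of the query. Loci built from such pairs are
#' labelled `fragmented_NSR`.
#'
#' @param hits Hit tibble (from [search_proteome()]) restricted to one query;
#'   needs `subject_id`, `query_start`, `query_end`.
#' @param query_length Length of the query protein in residues.
#' @param max_overlap Maximum span overlap fraction (default 0.2).
#' @param min_union_coverage Minimum joint query coverage (default 0.6).
#' @return `TRUE` when some pair of distinct subjects satisfies the rule.
#' @export
detect_fragmented <- function(hits, query_length, max_overlap = 0.2,
                              min_union_coverage = 0.6) {
  hits <- hits[!duplicated(hits$subject_id), , drop = FALSE]
  if (nrow(hits) < 2) return(FALSE)
  combs <- utils::combn(nrow(hits), 2)
  for (k in seq_len(ncol(combs))) {
    a <- hits[combs[1, k], ]; b <- hits[combs[2, k], ]
    ov <- max(0L, min(a$query_end, b$query_end) -
                max(a$query_start, b$query_start) + 1L)
    shorter <- min(a$query_end - a$query_start,
                   b$query_end - b$query_start) + 1L
    union_cov <- (a$query_end - a$query_start + 1L) +
      (b$query_end - b$query_start + 1L) - ov
    if (ov < max_overlap * shorter &&
        union_cov >= min_union_coverage * query_length) {
      return(TRUE)
    }
  }
  FALSE
}

#' Write a locus report as TSV
#'
#' @param loci Locus tibble from [assemble_loci()] (with an `architecture`
#'   column added by the pipeline).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_loci <- function(loci, path) {
  out <- dplyr::mutate(loci, members = vapply(.data$members, function(m) {
    paste(sprintf("%s:%s", m$locus_tag, m$role), collapse = ",")
  }, character(1)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
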