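# Per-genome orchestration: homology screen, domain calls, role
# assignment, locus assembly/classification, fragment detection, BGC
# detection, topology report, and the aggregated trait matrix.

#' Annotate a proteome with domain calls, homology hits and roles
#'
#' Runs the resistance/immunity query screen and the signature-model scan
#' over every protein of one genome and assigns a single functional role
#' per gene.
#'
#' @param features Feature tibble for one genome ([read_gff()] format).
#' @param proteome Protein tibble (`id` = locus_tag, `sequence`), e.g. from
#'   [extract_proteome()].
#' @param registry Query registry ([query_registry()]).
#' @param models Domain models ([domain_models()]).
#' @param config A [search_config()].
#' @return A list: `genes` (features joined with sequence, role and best
#'   hit), `hits` (retained hits of the resistance screen), `domains`
#'   (all domain calls).
#' @export
annotate_genes <- function(features, proteome, registry = query_registry(),
                           models = domain_models(),
                           config = search_config()) {
  queries <- resistance_queries(registry)
  hits <- search_proteome(queries, proteome, config)
  calls <- purrr::map_dfr(seq_len(nrow(proteome)),
                          function(i) scan_domains(proteome[i, ], models))
  roles <- vapply(proteome$id, function(pid) {
    assign_role(calls[calls$protein_id == pid, , drop = FALSE],
                hits[hits$subject_id == pid, , drop = FALSE])
  }, character(1))
  best <- hits |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(subject_id, best_query = "query_id",
                  best_evalue = "evalue")
  genes <- features |>
    dplyr::left_join(
      tibble::tibble(locus_tag = proteome$id, sequence = proteome$sequence,
                     length = nchar(proteome$sequence),
                     role = unname(roles)),
      by = "locus_tag") |>
    dplyr::left_join(best, by = c(locus_tag = "subject_id")) |>
    dplyr::arrange(.data$start)
  list(genes = genes, hits = hits, domains = calls)
}

#' Build, classify and augment resistance loci for one genome
#'
#' Assembles loci from role-bearing genes, labels each architecture
#' (dropping loci whose roles complete no group, with a message), and adds
#' `fragmented_NSR` loci for neighboring ORF pairs that jointly tile an NSR
#' query (see [detect_fragmented()]).
#'
#' @param genes Annotated gene tibble (`annotate_genes()$genes`).
#' @param hits Retained hit tibble (`annotate_genes()$hits`).
#' @param registry Query registry.
#' @param config A [cluster_config()].
#' @return Locus tibble with an `architecture` column.
#' @export
resistance_loci <- function(genes, hits, registry = query_registry(),
                            config = cluster_config()) {
  loci <- assemble_loci(genes, config)
  if (nrow(loci) > 0) {
    arch <- vapply(seq_len(nrow(loci)), function(i) {
      tryCatch(classify_architecture(loci[i, ]),
               error = function(e) NA_character_)
    }, character(1))
    dropped <- sum(is.na(arch))
    if (dropped > 0) {
      message("resistance_loci: dropping ", dropped,
              " unclassifiable locus/loci (incomplete role groups)")
    }
    loci$architecture <- arch
    loci <- loci[!is.na(loci$architecture), , drop = FALSE]
  } else {
    loci$architecture <- character(0)
  }
  # fragmented NSR: neighboring ORFs that tile an NSR query but are not
  # already members of an NSR-containing locus
  nsr_names <- registry$name[registry$role == "nsr_query"]
  in_locus <- unlist(lapply(loci$members, function(m) {
    m$locus_tag[m$role == "NSR_peptidase"]
  }))
  for (qn in nsr_names) {
    qlen <- registry$length[registry$name == qn]
    qh <- hits[hits$query_id == qn & !hits$subject_id %in% in_locus, ,
               drop = FALSE]
    if (nrow(qh) < 2) next
    # require the candidate ORFs to be neighbors
    sub <- genes[genes$locus_tag %in% qh$subject_id, , drop = FALSE] |>
      dplyr::arrange(.data$start)
    gaps <- sub$start[-1] - sub$end[-nrow(sub)] - 1L
    if (any(gaps > config$max_intergenic_bp)) next
    if (detect_fragmented(qh, qlen)) {
      frag <- tibble::tibble(
        locus_id = sprintf("%s_frag01", genes$genome_id[1]),
        genome_id = genes$genome_id[1],
        start = min(sub$start), end = max(sub$end),
        n_members = nrow(sub),
        roles = paste(rep("NSR_fragment", nrow(sub)), collapse = ","),
        members = list(sub), architecture = "fragmented_NSR")
      loci <- dplyr::bind_rows(loci, frag)
      break
    }
  }
  loci
}

#' Build one row of the resistance trait matrix
#'
#' Trait semantics (column order as in the survey's strain table):
#' `BGC` if any bacteriocin gene cluster was detected; `LanI` if a NisI
#' immunity-protein hit was retained; `CprABC` if hits to both CprB- and
#' CprC-type permease queries were retained; `BceAB` if a locus carries
#' both NBD and permease roles; `NSR` if an NSR peptidase role occurs in a
#' locus, printed `(+)` when the peptidase is split over two ORFs; `HK`/`RR`
#' if those roles occur in a classified resistance locus; `LysX` if a
#' lysyltransferase homolog occurs anywhere in the proteome.
#'
#' @param genome_id,species Identifiers for the row.
#' @param loci Locus tibble from [resistance_loci()].
#' @param bgc BGC tibble from [detect_bgc()].
#' @param hits Retained hit tibble.
#' @param genes Annotated gene tibble.
#' @return A one-row trait tibble.
#' @export
build_trait_row <- function(genome_id, species, loci, bgc, hits, genes) {
  for (nm in c("loci", "bgc", "hits", "genes")) {
    if (is.null(get(nm))) stop("missing stage output: ", nm, call. = FALSE)
  }
  mark <- function(x) if (isTRUE(x)) "+" else "-"
  has_role_in_locus <- function(role) {
    any(vapply(loci$members, function(m) role %in% m$role, logical(1)))
  }
  nsr <- if (has_role_in_locus("NSR_peptidase")) "+"
    else if (any(loci$architecture == "fragmented_NSR")) "(+)"
    else "-"
  tibble::tibble(
    genome_id = genome_id, species = species,
    BGC = mark(nrow(bgc) > 0),
    LanI = mark(any(hits$query_id == "NisI")),
    CprABC = mark(any(hits$query_id == "CprB") &&
                    any(hits$query_id == "CprC")),
    BceAB = mark(any(vapply(loci$members, function(m) {
      all(c("NBD", "permease") %in% m$role)
    }, logical(1)))),
    NSR = nsr,
    HK = mark(has_role_in_locus("HK")),
    RR = mark(has_role_in_locus("RR")),
    LysX = mark(any(genes$role == "LysX_like", na.rm = TRUE))
  )
}

#' Run the full survey pipeline over a set of genomes
#'
#' Per genome: derive/accept the proteome, screen it with the query panel,
#' call domains and roles, assemble and classify resistance loci, detect
#' BGCs, predict membrane topology for permease/HK members and build the
#' trait row. Failures are isolated per genome and reported without
#' aborting the batch.
#'
#' @param genomes Either a list of [build_genome()] results, or a tibble of
#'   genome records combined with `features`.
#' @param features Feature tibble covering all genomes (ignored when
#'   `genomes` is a list of generator results).
#' @param registry Query registry.
#' @param search A [search_config()].
#' @param clustering A [cluster_config()].
#' @param bgc A [bgc_config()].
#' @param topology A [topology_config()].
#' @return A list: `traits` (tibble, one row per successful genome),
#'   `details` (per-genome list of stage outputs), `failures` (tibble of
#'   genome_id + error message).
#' @export
run_pipeline <- function(genomes, features = NULL,
                         registry = query_registry(),
                         search = search_config(),
                         clustering = cluster_config(),
                         bgc = bgc_config(clustering = clustering),
                         topology = topology_config()) {
  units <- .pipeline_units(genomes, features)
  details <- list(); rows <- list(); fails <- list()
  for (u in units) {
    res <- tryCatch(
      .run_one_genome(u, registry, search, clustering, bgc, topology),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <- tibble::tibble(
        genome_id = u$genome$id, error = conditionMessage(res))
    } else {
      details[[u$genome$id]] <- res
      rows[[length(rows) + 1]] <- res$trait_row
    }
  }
  traits <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(genome_id = character(), species = character())
  failures <- if (length(fails) > 0) dplyr::bind_rows(fails) else
    tibble::tibble(genome_id = character(), error = character())
  if (length(units) == 0) warning("empty genome list", call. = FALSE)
  list(traits = traits, details = details, failures = failures)
}

.pipeline_units <- function(genomes, features) {
  if (is.data.frame(genomes)) {
    stopifnot(!is.null(features))
    lapply(seq_len(nrow(genomes)), function(i) {
      g <- genomes[i, ]
      list(genome = tibble::tibble(
             id = g$id,
             species = if ("species" %in% names(g)) g$species else g$id,
             sequence = g$sequence, length = g$length),
           features = features[features$genome_id == g$id, , drop = FALSE])
    })
  } else {
    lapply(genomes, function(g) {
      list(genome = tibble::tibble(id = g$genome$id,
                                   species = g$genome$species,
                                   sequence = g$genome$sequence,
                                   length = g$genome$length),
           features = g$features)
    })
  }
}

.run_one_genome <- function(u, registry, search, clustering, bgc_cfg,
                            topo_cfg) {
  proteome <- extract_proteome(u$genome, u$features)
  ann <- annotate_genes(u$features, proteome, registry,
                        config = search)
  loci <- resistance_loci(ann$genes, ann$hits, registry, clustering)
  bgc <- detect_bgc(ann$genes, registry, bgc_cfg, search$scheme)
  bgc_overlap <- vapply(seq_len(nrow(bgc)), function(i) {
    cross_reference_bgc(bgc[i, ], ann$hits)
  }, logical(1))
  if (nrow(bgc) > 0) bgc$matches_resistance_set <- bgc_overlap
  topo_genes <- ann$genes[ann$genes$role %in% c("permease", "HK") &
                            !is.na(ann$genes$role), , drop = FALSE]
  topo <- purrr::map_dfr(seq_len(nrow(topo_genes)), function(i) {
    g <- topo_genes[i, ]
    pred <- tryCatch(
      predict_tmh(tibble::tibble(id = g$locus_tag, sequence = g$sequence),
                  topo_cfg),
      error = function(e) NULL)
    if (is.null(pred)) return(NULL)
    topology_report(list(pred), topo_cfg) |>
      dplyr::mutate(role = g$role, .after = "protein_id")
  })
  trait_row <- build_trait_row(u$genome$id, u$genome$species, loci, bgc,
                               ann$hits, ann$genes)
  list(proteome = proteome, hits = ann$hits, domains = ann$domains,
       genes = ann$genes, loci = loci, bgc = bgc, topology = topo,
       trait_row = trait_row)
}

#' Write the per-genome pipeline reports as TSV files
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_pipeline <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$traits, file.path(dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (gid in names(result$details)) {
    d <- result$details[[gid]]
    export_hits(d$hits, file.path(dir, paste0(gid, "_hits.tsv")))
    export_loci(d$loci, file.path(dir, paste0(gid, "_loci.tsv")))
    if (nrow(d$topology) > 0) {
      utils::write.table(d$topology,
                         file.path(dir, paste0(gid, "_topology.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    bgc_out <- dplyr::select(d$bgc, -"members")
    utils::write.table(bgc_out, file.path(dir, paste0(gid, "_bgc.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
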