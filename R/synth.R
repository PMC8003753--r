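# Synthetic-data generators. Every generator is seed-deterministic and
# emits truth metadata sufficient to score recovery automatically:
# proteomes/genomes with planted operons and BGCs among decoy genes,
# membrane proteins with prescribed helix counts and loop geometry,
# alignments evolved along known trees, and dose-response plates.

# positive-score BLOSUM62 exchange partners per residue (fallback: best
# non-identical partner when no strictly positive exchange exists, e.g. for
# C, G or P)
.partners_env <- new.env(parent = emptyenv())
.positive_partners <- function() {
  if (!is.null(.partners_env$p)) return(.partners_env$p)
  mat <- .load_submat("BLOSUM62")
  aas <- names(.aa_freqs)
  p <- lapply(stats::setNames(aas, aas), function(a) {
    row <- mat[a, aas]
    row <- row[names(row) != a]
    pos <- names(row)[row > 0]
    if (length(pos) > 0) pos else names(row)[row == max(row)]
  })
  .partners_env$p <- p
  p
}

#' Mutate a protein to a target global identity
#'
#' Substitutes randomly chosen positions (preferring positive-scoring
#' BLOSUM62 exchanges) until the expected gap-free identity to the seed
#' protein equals the target; signature motif spans passed via `protected`
#' are never touched, so domain calls survive arbitrary divergence.
#' No indels are introduced.
#'
#' @param protein One-row protein record tibble (`id`, `sequence`).
#' @param target_identity Target identity in `[0.2, 1]`.
#' @param seed Integer seed, or `NULL` to draw from the current RNG state
#'   (for callers that manage their own seed scope).
#' @param protected Optional tibble/data.frame of 1-based inclusive `start`,
#'   `end` intervals to hold fixed.
#' @return A one-row protein record tibble with the mutated sequence.
#' @export
mutate_protein <- function(protein, target_identity, seed = NULL,
                           protected = NULL) {
  stopifnot(target_identity >= 0.2, target_identity <= 1)
  p <- .as_protein(protein)
  run <- function() {
    chars <- strsplit(p$sequence, "")[[1]]
    L <- length(chars)
    prot_pos <- integer(0)
    if (!is.null(protected) && nrow(protected) > 0) {
      prot_pos <- unlist(mapply(seq, protected$start, protected$end,
                                SIMPLIFY = FALSE))
    }
    free <- setdiff(seq_len(L), prot_pos)
    k <- round((1 - target_identity) * L)
    if (k > length(free)) {
      stop("target identity ", target_identity,
           " unreachable with the protected motifs fixed", call. = FALSE)
    }
    if (k > 0) {
      partners <- .positive_partners()
      idx <- sample(free, k)
      for (i in idx) {
        cand <- partners[[chars[i]]]
        if (is.null(cand)) cand <- setdiff(names(.aa_freqs), chars[i])
        chars[i] <- if (length(cand) == 1) cand else sample(cand, 1)
      }
    }
    tibble::tibble(id = p$id, sequence = paste(chars, collapse = ""),
                   length = L)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# internal: pull a plain sequence (with motif metadata) out of a
# build_membrane_protein() result
.mp_seq <- function(mp) {
  s <- mp$record$sequence
  attr(s, "motifs") <- mp$motifs
  s
}

#' Construct a membrane protein with prescribed topology
#'
#' Builds `n_helices` hydrophobic 21-residue helices (drawn from L/I/V/F,
#' mean Kyte-Doolittle hydropathy >= 2) separated by hydrophilic loops of
#' the given lengths. Loops on the cytoplasmic side are lysine/arginine
#' enriched and periplasmic loops carry no K/R, so the positive-inside rule
#' recovers the intended orientation; when an extracellular domain is
#' requested (`ecd_between`), the orientation is chosen so that loop sits
#' outside.
#'
#' @param n_helices Number of transmembrane helices (0 gives a soluble
#'   protein consisting of the single "loop").
#' @param loop_lengths Integer vector of `n_helices + 1` loop lengths (the
#'   N-terminal tail, the inter-helix loops, the C-terminal tail).
#' @param ecd_between Optional pair `c(i, i + 1)` of consecutive helix
#'   indices; the loop between them becomes an extracellular domain of
#'   length `ecd_length`.
#' @param ecd_length Length of the requested ECD in residues.
#' @param helix_length Helix length (default 21).
#' @param motif Optional `list(loop =, offset =, literal =)` splicing a
#'   signature literal into a loop.
#' @param seed Integer seed or `NULL` to use the current RNG state.
#' @param id Record id.
#' @return A list: `record` (one-row protein tibble), `tmh` and `loops`
#'   (truth interval tibbles), `n_term_side`, `motifs`.
#' @export
build_membrane_protein <- function(n_helices, loop_lengths,
                                   ecd_between = NULL, ecd_length = NULL,
                                   helix_length = 21L, motif = NULL,
                                   seed = NULL, id = "membrane_protein") {
  if (length(loop_lengths) != n_helices + 1) {
    stop("need n_helices + 1 loop lengths", call. = FALSE)
  }
  loop_lengths <- as.integer(loop_lengths)
  ecd_loop <- NA_integer_
  if (!is.null(ecd_between)) {
    if (length(ecd_between) != 2 || ecd_between[2] != ecd_between[1] + 1 ||
        ecd_between[2] > n_helices || is.null(ecd_length)) {
      stop("ecd_between must be consecutive helix indices within range, ",
           "with ecd_length set", call. = FALSE)
    }
    ecd_loop <- ecd_between[1] + 1L
    loop_lengths[ecd_loop] <- as.integer(ecd_length)
  }
  # orientation: loop k is on the N-terminal side for odd k; pick the
  # N-terminal side so a requested ECD lands outside
  n_term_side <- "in"
  if (!is.na(ecd_loop) && ecd_loop %% 2L == 1L) n_term_side <- "out"
  side_of <- function(k) {
    first <- n_term_side
    other <- if (first == "in") "out" else "in"
    if (k %% 2L == 1L) first else other
  }
  run <- function() {
    in_pool <- c(K = 25, R = 20, S = 10, T = 8, N = 8, G = 8, E = 7,
                 D = 7, Q = 4, P = 3)
    out_pool <- c(D = 14, E = 13, S = 14, T = 12, N = 12, Q = 10, G = 12,
                  P = 7, H = 3, Y = 2, W = 1)
    # membrane-interface band: three mildly polar residues at each loop
    # edge (so the charged loop core never drags a flanking helix window
    # below the detection threshold) around a strongly hydrophilic core
    # (so a 19-residue window dips clearly between consecutive helices;
    # connectors of >= 10 residues are reliably resolved, shorter ones are
    # below the physical resolution of a hydropathy window)
    buffer_pool <- c(S = 35, T = 30, G = 25, A = 10)
    in_core <- c(K = 35, R = 25, E = 8, D = 8, N = 6, Q = 6, S = 6, T = 4,
                 G = 2)
    out_core <- c(D = 25, E = 25, N = 20, Q = 20, S = 6, T = 4)
    helix_pool <- c(L = 40, I = 35, V = 25)
    loop_seq <- function(len, side) {
      if (len <= 6) return(.random_aa(len, names(buffer_pool), buffer_pool))
      core_pool <- if (side == "in") in_core else out_core
      paste0(.random_aa(3, names(buffer_pool), buffer_pool),
             .random_aa(len - 6, names(core_pool), core_pool),
             .random_aa(3, names(buffer_pool), buffer_pool))
    }
    segs <- list(); kinds <- character(0); sides <- character(0)
    for (k in seq_len(n_helices + 1)) {
      side <- side_of(k)
      segs[[length(segs) + 1]] <- loop_seq(loop_lengths[k], side)
      kinds <- c(kinds, "loop"); sides <- c(sides, side)
      if (k <= n_helices) {
        segs[[length(segs) + 1]] <- .random_aa(helix_length,
                                               names(helix_pool),
                                               helix_pool)
        kinds <- c(kinds, "helix"); sides <- c(sides, NA)
      }
    }
    lens <- vapply(segs, nchar, integer(1))
    ends <- cumsum(lens); starts <- ends - lens + 1L
    seq <- paste(unlist(segs), collapse = "")
    motifs <- tibble::tibble(motif = character(), start = integer(),
                             end = integer())
    if (!is.null(motif)) {
      loop_idx <- which(kinds == "loop")[motif$loop]
      at <- starts[loop_idx] + motif$offset - 1L
      lit <- motif$literal
      seq <- .place_motif(seq, lit, at)
      motifs <- tibble::tibble(motif = "literal", start = at,
                               end = at + nchar(lit) - 1L)
    }
    tmh <- tibble::tibble(start = starts[kinds == "helix"],
                          end = ends[kinds == "helix"])
    loops <- tibble::tibble(start = starts[kinds == "loop"],
                            end = ends[kinds == "loop"],
                            side = sides[kinds == "loop"])
    list(record = tibble::tibble(id = id, sequence = seq,
                                 length = nchar(seq)),
         tmh = tmh, loops = loops, n_term_side = n_term_side,
         ecd_loop = ecd_loop, motifs = motifs)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# bacterial genetic code helpers ----------------------------------------

.codon_env <- new.env(parent = emptyenv())
.codons_by_aa <- function() {
  if (is.null(.codon_env$tab)) {
    gc11 <- .genetic_code_11()
    .codon_env$tab <- split(names(gc11), unname(gc11))
  }
  .codon_env$tab
}

# back-translate a protein with uniform synonymous codon choice and a
# random stop codon appended
.back_translate <- function(aa_seq) {
  tab <- .codons_by_aa()
  chars <- strsplit(aa_seq, "")[[1]]
  codons <- vapply(chars, function(a) {
    cand <- tab[[a]]
    if (length(cand) == 1) cand else sample(cand, 1)
  }, character(1))
  stop_codon <- sample(tab[["*"]], 1)
  paste(c(codons, stop_codon), collapse = "")
}

# decoy protein with no signature-pattern matches
.decoy_protein <- function(len, veto_regex) {
  repeat {
    s <- .random_aa(len)
    if (!any(stringr::str_detect(s, veto_regex))) return(s)
  }
}

# operon layouts mirroring the characterized nsr-like loci: member roles in
# gene order -> template registry entries
.operon_layouts <- list(
  nsrFPX = c(NBD = "casei_NBD", permease = "casei_permease",
             NSR_peptidase = "NSR_Saga"),
  nsrRKFPX = c(RR = "casei_RR", HK = "casei_HK", NBD = "casei_NBD",
               permease = "casei_permease", NSR_peptidase = "NSR_Saga"),
  nsrPFKR = c(permease = "casei_permease", NBD = "casei_NBD",
              HK = "casei_HK", RR = "casei_RR")
)
.layout_architecture <- c(nsrFPX = "ABC_NSR", nsrRKFPX = "ABC_TCS_NSR",
                          nsrPFKR = "ABC_TCS")

.template_protein <- function(registry, name, identity) {
  row <- registry[registry$name == name, ]
  stopifnot(nrow(row) == 1)
  mutate_protein(tibble::tibble(id = name, sequence = row$sequence),
                 target_identity = identity, seed = NULL,
                 protected = row$motifs[[1]])
}

# build the member proteins for one plant; returns tibble
# (role, template, sequence, truth_kind)
.plant_members <- function(plant, registry) {
  identity <- plant$identity %||% 0.5
  if (plant$kind == "operon") {
    tpl <- .operon_layouts[[plant$layout]]
    purrr::map_dfr(seq_along(tpl), function(i) {
      mut <- .template_protein(registry, tpl[[i]], identity)
      tibble::tibble(role = names(tpl)[i], template = tpl[[i]],
                     sequence = mut$sequence)
    })
  } else if (plant$kind == "gene") {
    mut <- .template_protein(registry, plant$template, identity)
    tibble::tibble(role = plant$role %||% "LysX_like",
                   template = plant$template, sequence = mut$sequence)
  } else if (plant$kind == "fragmented_nsr") {
    row <- registry[registry$name == "NSR_Saga", ]
    mut <- .template_protein(registry, "NSR_Saga", identity)
    cut <- 209L
    tibble::tibble(
      role = c("NSR_fragment", "NSR_fragment"),
      template = "NSR_Saga",
      sequence = c(substring(mut$sequence, 1, cut),
                   substring(mut$sequence, cut + 1, nchar(mut$sequence))))
  } else if (plant$kind == "bgc") {
    cls <- plant$class %||% "I"
    if (cls == "I") {
      prec <- .template_protein(registry, "nisin_Z", max(identity, 0.6))
      lan <- .template_protein(registry, "LanM", identity)
      tra <- .template_protein(registry, "NisT", identity)
      tibble::tibble(role = c("precursor", "modification", "transporter"),
                     template = c("nisin_Z", "LanM", "NisT"),
                     sequence = c(prec$sequence, lan$sequence,
                                  tra$sequence))
    } else if (cls == "II") {
      stc_pool <- c(S = 20, T = 20, C = 10, G = 10, A = 10, K = 8, L = 8,
                    P = 7, N = 7)
      prec <- .random_aa(40, names(stc_pool), stc_pool)
      tra <- .template_protein(registry, "NisT", identity)
      tibble::tibble(role = c("precursor", "transporter"),
                     template = c("de_novo", "NisT"),
                     sequence = c(prec, tra$sequence))
    } else {
      big <- .template_protein(registry, "ClassIII_query", identity)
      tibble::tibble(role = "large_bacteriocin", template = "ClassIII_query",
                     sequence = big$sequence)
    }
  } else {
    stop("unknown plant kind: ", plant$kind, call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a synthetic annotated genome with planted elements
#'
#' Plants operons (nsrFPX / nsrRKFPX / nsrPFKR layouts), bacteriocin gene
#' clusters (Class I/II/III), single genes (e.g. a LysX homolog) or a
#' fragmented NSR pair among composition-matched decoy genes. Member
#' proteins are diverged from the registry templates to the requested
#' identity (signature motifs locked), back-translated with uniform
#' synonymous codons, and laid out with short intra-plant intergenic gaps;
#' plants are insulated from each other by decoy genes so distance
#' clustering cannot bridge them. Deterministic per seed.
#'
#' @param plants List of plant specs, e.g.
#'   `list(list(kind = "operon", layout = "nsrRKFPX", identity = 0.5),`
#'   `list(kind = "bgc", class = "I"))`. Kinds: `operon`, `bgc`, `gene`
#'   (needs `template`, optional `role`), `fragmented_nsr`.
#' @param n_decoys Number of decoy genes (default 24).
#' @param seed Integer seed.
#' @param genome_id,species Genome identifiers.
#' @param registry Query registry used for templates.
#' @return A list: `genome` (one-row tibble `id`, `species`, `sequence`,
#'   `length`), `features` (GFF-style tibble), `proteins` (planted protein
#'   truth), `truth` (tibble of planted elements with coordinates).
#' @export
build_genome <- function(plants = list(), n_decoys = 24L, seed = 1L,
                         genome_id = "synth1", species = genome_id,
                         registry = query_registry()) {
  withr::with_seed(seed, {
    veto <- unlist(domain_models()$regex)
    plant_tbls <- lapply(plants, .plant_members, registry = registry)
    n_blocks <- length(plants) + 1L
    per_block <- max(2L, ceiling(n_decoys / n_blocks))

    genes <- list()   # each: list(role, template, sequence, kind, plant_id)
    for (b in seq_len(n_blocks)) {
      for (d in seq_len(per_block)) {
        genes[[length(genes) + 1]] <- list(
          role = "none", template = NA_character_,
          sequence = .decoy_protein(sample(150:300, 1), veto),
          kind = "decoy", plant_id = NA_integer_)
      }
      if (b <= length(plants)) {
        tbl <- plant_tbls[[b]]
        for (i in seq_len(nrow(tbl))) {
          genes[[length(genes) + 1]] <- list(
            role = tbl$role[i], template = tbl$template[i],
            sequence = tbl$sequence[i], kind = plants[[b]]$kind,
            plant_id = b)
        }
      }
    }

    seq_parts <- character(0)
    pos <- 0L
    feats <- list(); prots <- list()
    prev_plant <- NA_integer_
    for (gi in seq_along(genes)) {
      g <- genes[[gi]]
      same_plant <- !is.na(g$plant_id) && identical(g$plant_id, prev_plant)
      gap <- if (same_plant) sample(60:140, 1) else sample(250:450, 1)
      spacer <- .random_aa(gap, c("A", "C", "G", "T"),
                           c(A = 30, C = 20, G = 20, T = 30))
      cds <- .back_translate(g$sequence)
      strand <- if (g$kind == "decoy") sample(c("+", "-"), 1) else "+"
      placed <- if (strand == "-") {
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds)))
      } else cds
      start <- pos + gap + 1L
      end <- start + nchar(cds) - 1L
      tag <- sprintf("%s_%04d", genome_id, gi * 5L)
      seq_parts <- c(seq_parts, spacer, placed)
      pos <- end
      feats[[gi]] <- tibble::tibble(
        gene_id = tag, genome_id = genome_id, start = start, end = end,
        strand = strand,
        product = if (g$kind == "decoy") "hypothetical protein"
                  else paste0(g$kind, ":", g$role),
        locus_tag = tag)
      prots[[gi]] <- tibble::tibble(
        locus_tag = tag, role = g$role, template = g$template,
        kind = g$kind, plant_id = g$plant_id, sequence = g$sequence,
        start = start, end = end)
    }
    tail_spacer <- .random_aa(sample(250:450, 1), c("A", "C", "G", "T"),
                              c(A = 30, C = 20, G = 20, T = 30))
    genome_seq <- paste(c(seq_parts, tail_spacer), collapse = "")
    features <- dplyr::bind_rows(feats)
    proteins <- dplyr::bind_rows(prots)

    empty_truth <- tibble::tibble(
      kind = character(), label = character(), identity = numeric(),
      locus_tags = character(), roles = character(), start = integer(),
      end = integer())
    truth <- purrr::map_dfr(seq_along(plants), function(b) {
      mem <- proteins[!is.na(proteins$plant_id) & proteins$plant_id == b, ]
      p <- plants[[b]]
      label <- switch(p$kind,
        operon = .layout_architecture[[p$layout]],
        bgc = paste0("BGC_", p$class %||% "I"),
        gene = p$template,
        fragmented_nsr = "fragmented_NSR")
      tibble::tibble(kind = p$kind, label = label,
                     identity = p$identity %||% 0.5,
                     locus_tags = paste(mem$locus_tag, collapse = ","),
                     roles = paste(mem$role, collapse = ","),
                     start = min(mem$start), end = max(mem$end))
    })
    if (nrow(truth) == 0) truth <- empty_truth
    list(
      genome = tibble::tibble(id = genome_id, species = species,
                              sequence = genome_seq,
                              length = nchar(genome_seq)),
      features = features, proteins = proteins, truth = truth)
  })
}

#' Synthesize the six-strain survey panel
#'
#' Builds six synthetic genomes whose planted resistance traits mirror the
#' characterized strain panel: a trait-free sensitive strain, an
#' ABC+NSR operon strain, an ABC+TCS operon strain with a LysX homolog and
#' a Class I BGC, a strain with only a fragmented NSR pair, a full
#' ABC+TCS+NSR operon strain with a Class I BGC, and a BGC-only strain.
#'
#' @param seed Integer seed.
#' @param identity Plant identity to the query templates (default 0.5).
#' @param n_decoys Decoy genes per genome.
#' @param registry Query registry.
#' @return A list with `genomes` (list of [build_genome()] results, named
#'   by genome id) and `expected_traits` (the planted trait matrix, in
#'   survey column order).
#' @export
synthesize_survey <- function(seed = 1L, identity = 0.5, n_decoys = 12L,
                              registry = query_registry()) {
  panel <- list(
    Cglu = list(species = "C. glutamicum ATCC 13032", plants = list()),
    Camm = list(species = "C. ammoniagenes DSM 20306",
                plants = list(list(kind = "operon", layout = "nsrFPX",
                                   identity = identity))),
    Clac = list(species = "C. lactis RW3-42",
                plants = list(
                  list(kind = "operon", layout = "nsrPFKR",
                       identity = identity),
                  list(kind = "gene", template = "LysX",
                       role = "LysX_like", identity = identity),
                  list(kind = "bgc", class = "I", identity = identity))),
    Ceff = list(species = "C. efficiens DSM 44549",
                plants = list(list(kind = "fragmented_nsr",
                                   identity = max(identity, 0.6)))),
    Ccas = list(species = "C. casei DSM 44701",
                plants = list(
                  list(kind = "operon", layout = "nsrRKFPX",
                       identity = identity),
                  list(kind = "bgc", class = "I", identity = identity))),
    Ccan = list(species = "C. canis DSM 45402",
                plants = list(list(kind = "bgc", class = "I",
                                   identity = identity)))
  )
  genomes <- purrr::imap(panel, function(spec, gid) {
    build_genome(spec$plants, n_decoys = n_decoys,
                 seed = seed + match(gid, names(panel)),
                 genome_id = gid, species = spec$species,
                 registry = registry)
  })
  expected <- tibble::tribble(
    ~genome_id, ~BGC, ~LanI, ~CprABC, ~BceAB, ~NSR, ~HK, ~RR, ~LysX,
    "Cglu", "-", "-", "-", "-", "-", "-", "-", "-",
    "Camm", "-", "-", "-", "+", "+", "-", "-", "-",
    "Clac", "+", "-", "-", "+", "-", "+", "+", "+",
    "Ceff", "-", "-", "-", "-", "(+)", "-", "-", "-",
    "Ccas", "+", "-", "-", "+", "+", "+", "+", "-",
    "Ccan", "+", "-", "-", "-", "-", "-", "-", "-")
  list(genomes = genomes, expected_traits = expected)
}

# dose-response simulation ----------------------------------------------

#' Two-fold dilution grid
#'
#' @param top Highest concentration (ug/mL).
#' @param n_steps Number of concentrations.
#' @return Descending numeric vector `top / 2^(0:(n_steps-1))`.
#' @export
mic_grid <- function(top = 40, n_steps = 12L) {
  top / 2^(0:(n_steps - 1L))
}

#' Simulate a microdilution assay plate
#'
#' Relative growth follows the decreasing Gompertz curve with inflection
#' `m = true_mic / 2`, so with a slope of 8 or more the no-growth threshold
#' (tau = 0.05) is crossed exactly between the planted MIC and the next
#' lower concentration: at noise 0 the MIC reading returns the planted
#' value. Readings are converted to OD600 with a starting OD of
#' `baseline_od`; noise is signal-proportional Gaussian
#' (`sd = noise_sd * signal + 0.005` OD when `noise_sd > 0`), reflecting
#' that near-empty wells read far more quietly than dense ones.
#'
#' @param true_mic Planted MIC; must lie on `grid` or above its maximum
#'   (then the plate reads as censored).
#' @param slope Gompertz slope (default 10).
#' @param noise_sd Relative noise level (0 = exact).
#' @param seed Integer seed.
#' @param grid Concentration series from [mic_grid()].
#' @param strain,condition Labels carried into the plate table.
#' @param replicates Wells per concentration.
#' @param baseline_od,growth_od Starting OD and untreated growth increment.
#' @return A tidy plate tibble (see [relative_growth()]) with the truth in
#'   `attr(, "truth")`.
#' @export
simulate_assay <- function(true_mic, slope = 10, noise_sd = 0, seed = 1L,
                           grid = mic_grid(), strain = "strain1",
                           condition = "uninduced", replicates = 1L,
                           baseline_od = 0.05, growth_od = 1.0) {
  on_grid <- any(abs(grid - true_mic) / true_mic < 1e-6)
  if (!on_grid && true_mic <= max(grid)) {
    stop("true_mic must lie on the dilution grid or above its maximum",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    conc <- rep(sort(grid, decreasing = TRUE), each = replicates)
    rel <- gompertz_response(conc, A = 1, m = true_mic / 2, s = slope)
    noise <- function(signal) {
      if (noise_sd == 0) return(rep(0, length(signal)))
      stats::rnorm(length(signal), 0, noise_sd * signal + 0.005)
    }
    wells <- tibble::tibble(
      strain = strain, condition = condition, concentration = conc,
      od_t0 = baseline_od,
      od_t24 = baseline_od + growth_od * rel + noise(growth_od * rel),
      is_untreated = FALSE)
    untreated <- tibble::tibble(
      strain = strain, condition = condition, concentration = 0,
      od_t0 = baseline_od,
      od_t24 = baseline_od + growth_od + noise(rep(growth_od, 3L)),
      is_untreated = TRUE)
    out <- dplyr::bind_rows(wells, untreated)
    attr(out, "truth") <- list(true_mic = true_mic, slope = slope,
                               noise_sd = noise_sd, grid = grid,
                               censored = !on_grid)
    out
  })
}

# phylogeny simulation ---------------------------------------------------

#' Random phylogeny with uniform branch lengths
#'
#' @param n_taxa Number of taxa.
#' @param seed Integer seed.
#' @param min_bl,max_bl Branch-length range (expected substitutions/site).
#' @return An unrooted `phylo` tree with tip labels `t1..tn`.
#' @export
random_tree <- function(n_taxa, seed = 1L, min_bl = 0.05, max_bl = 0.3) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE,
                     tip.label = paste0("t", seq_len(n_taxa)))
    tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
    tr
  })
}

#' Evolve an alignment along a known tree
#'
#' Sites evolve independently under Jukes-Cantor dynamics along the tree
#' (branch lengths in expected substitutions per site, scaled by `rate`);
#' no indels. The generating tree is recorded as an attribute.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param n_sites Number of alignment columns.
#' @param rate Rate multiplier applied to branch lengths.
#' @param seed Integer seed.
#' @return Alignment tibble (`taxon`, `sequence`) with `attr(, "tree")`.
#' @export
evolve_alignment <- function(tree, n_sites, rate = 1, seed = 1L) {
  stopifnot(!is.null(tree$edge.length))
  withr::with_seed(seed, {
    sim <- phangorn::simSeq(tree, l = n_sites, type = "DNA", rate = rate)
    mat <- toupper(as.character(sim))
    aln <- tibble::tibble(taxon = rownames(mat),
                          sequence = apply(mat, 1, paste, collapse = ""))
    attr(aln, "tree") <- tree
    aln
  })
}
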