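# Bundled query registry.
#
# The survey screens proteomes with a fixed panel of query proteins (cell
# envelope modification enzymes, NSR-type peptidases, BceAB/CprABC-type
# transporter subunits, nisin biosynthesis/immunity proteins). The bundled
# sequences are synthetic stand-ins constructed deterministically in code:
# they carry the documented signature content (Walker boxes, S41 catalytic
# box, FtsX-like motif, kinase H/G boxes, transmembrane architecture,
# realistic lengths) but are not the copyrighted UniProt records. Users can
# swap in real sequences by replacing the `sequence` column, keyed by the
# UniProt accession recorded per entry.

# motif literals used across stand-ins (each matches its signature pattern)
.motifs <- list(
  walkerA = "GPSGSGKS", walkerB = "ILLLDE",
  hbox = "AHELKTPL", gbox = "GTGLGLAI",
  rec1 = "ILVDDQ", rec2 = "GLSKPF",
  ftsx = "LDVFSNQV",
  s41_cat = "TASSAEM", s41_anchor = "GQSDLNPW"
)

# approximate natural amino-acid frequencies (percent scale)
.aa_freqs <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9,
               E = 6.8, G = 7.1, H = 2.3, I = 6.0, L = 9.7, K = 5.8,
               M = 2.4, F = 3.9, P = 4.7, S = 6.6, T = 5.3, W = 1.1,
               Y = 2.9, V = 6.9)

.random_aa <- function(n, pool = names(.aa_freqs), prob = .aa_freqs) {
  paste(sample(pool, n, replace = TRUE, prob = prob[pool]), collapse = "")
}

# replace a substring at a fixed position
.place_motif <- function(seq, literal, at) {
  stopifnot(at >= 1, at + nchar(literal) - 1 <= nchar(seq))
  paste0(substring(seq, 1, at - 1), literal,
         substring(seq, at + nchar(literal), nchar(seq)))
}

# soluble scaffold with motifs placed at fixed positions; motif table
# returned as an attribute for mutation locking
.soluble_with_motifs <- function(len, motif_at) {
  seq <- .random_aa(len)
  mot <- tibble::tibble(motif = names(motif_at),
                        start = unname(motif_at),
                        end = unname(motif_at) +
                          nchar(unlist(.motifs[names(motif_at)])) - 1L)
  for (i in seq_len(nrow(mot))) {
    seq <- .place_motif(seq, .motifs[[mot$motif[i]]], mot$start[i])
  }
  attr(seq, "motifs") <- mot
  seq
}

.registry_env <- new.env(parent = emptyenv())

#' The bundled query registry
#'
#' Returns the panel of query proteins used by the resistance survey, the
#' BGC analysis and the synthetic-genome generator, as a tibble with
#' columns `name`, `uniprot` (the accession of the real protein each entry
#' stands in for), `role`, `purpose` (`resistance`, `immunity`,
#' `modification`, `bgc_aux` or `template`), `sequence`, `length` and
#' `motifs` (list-column of locked signature spans, used by
#' [mutate_protein()]).
#'
#' Construction is deterministic: the same `seed` always yields byte-equal
#' sequences.
#'
#' @param seed Integer seed for the deterministic construction.
#' @return The registry tibble.
#' @export
query_registry <- function(seed = 19032021L) {
  key <- as.character(seed)
  if (!is.null(.registry_env[[key]])) return(.registry_env[[key]])
  reg <- withr::with_seed(seed, .build_registry())
  .registry_env[[key]] <- reg
  reg
}

.build_registry <- function() {
  entry <- function(name, uniprot, role, purpose, seq) {
    mot <- attr(seq, "motifs")
    if (is.null(mot)) {
      mot <- tibble::tibble(motif = character(), start = integer(),
                            end = integer())
    }
    tibble::tibble(name = name, uniprot = uniprot, role = role,
                   purpose = purpose, sequence = as.character(seq),
                   length = nchar(seq), motifs = list(mot))
  }

  # cell-envelope modification queries (soluble, no signature motifs)
  dltA <- entry("DltA", "P68876", "dltA_query", "resistance",
                .random_aa(503))
  mprF <- entry("MprF", "C0H3X7", "lysx_query", "resistance",
                .random_aa(563))
  lysX <- entry("LysX", "P9WFU7", "lysx_query", "resistance",
                .random_aa(581))

  # NSR-type S41 peptidases: N-terminal membrane anchor, then the soluble
  # peptidase domain with the anchor box and the TASSAEM catalytic box
  # (catalytic serine near position 236, as in the S. agalactiae protein)
  nsr_seq <- local({
    n_tail <- .random_aa(20, c("K", "R", "S", "T", "N", "G", "E", "D"),
                         c(K = 3, R = 3, S = 1, T = 1, N = 1, G = 1,
                           E = 1, D = 1))
    helix <- .random_aa(23, c("L", "I", "V", "F"),
                        c(L = 35, I = 30, V = 25, F = 10))
    body <- .random_aa(322)
    seq <- paste0(n_tail, helix, body)
    mot <- tibble::tibble(
      motif = c("s41_anchor", "s41_cat"),
      start = c(60L, 233L),
      end = c(60L + nchar(.motifs$s41_anchor) - 1L,
              233L + nchar(.motifs$s41_cat) - 1L))
    seq <- .place_motif(seq, .motifs$s41_anchor, 60L)
    seq <- .place_motif(seq, .motifs$s41_cat, 233L)
    attr(seq, "motifs") <- mot
    seq
  })
  nsr_aga <- entry("NSR_Saga", "A0A656FZQ8", "nsr_query", "resistance",
                   nsr_seq)

  # ABC transporter NBDs (Walker A + Walker B)
  nbd_seq <- function(len, a_at, b_at) {
    .soluble_with_motifs(len, c(walkerA = a_at, walkerB = b_at))
  }
  casei_nbd <- entry("casei_NBD", "W5XY46", "nbd_query", "resistance",
                     nbd_seq(242, 38L, 150L))
  nsrF <- entry("NsrF_Saga", "X5KGL2", "nbd_query", "resistance",
                nbd_seq(233, 41L, 147L))
  nisF <- entry("NisF", "Q48635", "nbd_query", "resistance",
                nbd_seq(225, 35L, 142L))
  cprA <- entry("CprA", "Q18BL2", "nbd_query", "resistance",
                nbd_seq(231, 39L, 155L))
  vraD <- entry("VraD", "A0A4U0CTB1", "nbd_query", "resistance",
                nbd_seq(240, 42L, 151L))

  # Pep7E permease subunits. The Corynebacterium-type subunit lacks the
  # large extracellular domain between helices 7 and 8; the S. agalactiae
  # NsrP stand-in carries a 180 aa ECD there (hence ~200 aa larger).
  casei_perm_seq <- build_membrane_protein(
    n_helices = 10, loop_lengths = c(40L, rep(18L, 9), 25L),
    motif = list(loop = 1L, offset = 9L, literal = .motifs$ftsx),
    id = "casei_permease")
  nsrp_seq <- build_membrane_protein(
    n_helices = 10, loop_lengths = c(40L, rep(18L, 6), 218L, 18L, 18L, 25L),
    motif = list(loop = 1L, offset = 9L, literal = .motifs$ftsx),
    id = "NsrP_Saga")
  casei_perm <- entry("casei_permease", "W5XR13", "permease_query",
                      "resistance", .mp_seq(casei_perm_seq))
  nsrP <- entry("NsrP_Saga", "A0A0E1EH51", "permease_query", "resistance",
                .mp_seq(nsrp_seq))

  # permease queries with no homolog anywhere in the genus (soluble
  # scaffolds; the survey retains no hits for them)
  nisE <- entry("NisE", "Q48636", "permease_query", "resistance",
                .random_aa(602))
  nisG <- entry("NisG", "Q48637", "permease_query", "resistance",
                .random_aa(598))
  cprB <- entry("CprB", "Q18BL7", "permease_query", "resistance",
                .random_aa(611))
  cprC <- entry("CprC", "Q18BL6", "permease_query", "resistance",
                .random_aa(605))
  vraE <- entry("VraE", "A0A5C8XC28", "permease_query", "resistance",
                .random_aa(620))

  # two-component system templates (identified via domain signatures, and
  # used by the generator as operon member templates)
  casei_hk <- entry("casei_HK", "W5XQB7", "hk_template", "template",
                    .soluble_with_motifs(352, c(hbox = 110L, gbox = 262L)))
  nsrk_seq <- local({
    # BceS-like intramembrane kinase: two helices, short outside connector,
    # cytoplasmic catalytic domain
    mp <- build_membrane_protein(n_helices = 2,
                                 loop_lengths = c(15L, 12L, 288L),
                                 id = "NsrK_Saga")
    seq <- .mp_seq(mp)
    h_at <- 160L; g_at <- 290L
    seq <- .place_motif(seq, .motifs$hbox, h_at)
    seq <- .place_motif(seq, .motifs$gbox, g_at)
    attr(seq, "motifs") <- tibble::tibble(
      motif = c("hbox", "gbox"), start = c(h_at, g_at),
      end = c(h_at + 7L, g_at + 7L))
    seq
  })
  nsrK <- entry("NsrK_Saga", "Q8DZW8", "hk_template", "template", nsrk_seq)
  casei_rr <- entry("casei_RR", "synthetic", "rr_template", "template",
                    .soluble_with_motifs(226, c(rec1 = 9L, rec2 = 104L)))

  # nisin biosynthesis / immunity panel
  nisT <- entry("NisT", "Q03203", "bgc_transporter_query", "bgc_aux",
                .soluble_with_motifs(600, c(walkerA = 380L, walkerB = 492L)))
  nisI <- entry("NisI", "P42708", "immunity_query", "immunity",
                .random_aa(245))
  # nisin Z precursor stand-in: 34 aa lanthipeptide precursor with the
  # characteristic high Ser/Thr/Cys content (ring-forming residues)
  nisZ <- entry("nisin_Z", "P29559", "nisin_precursor", "bgc_aux",
                "MKTSCSLCTPGCKTGSLMTCPLKTATCGCHITGK")
  lanM <- entry("LanM", "synthetic", "modification_enzyme", "modification",
                .random_aa(641))
  lanC <- entry("LanC", "synthetic", "modification_enzyme", "modification",
                .random_aa(423))
  class3 <- entry("ClassIII_query", "synthetic", "class3_bacteriocin",
                  "bgc_aux", .random_aa(358))

  dplyr::bind_rows(dltA, mprF, lysX, nsr_aga, .nsr_lactis_entry(nsr_aga),
                   casei_nbd, nsrF, nisF, cprA, vraD,
                   casei_perm, nsrP, nisE, nisG, cprB, cprC, vraE,
                   casei_hk, nsrK, casei_rr,
                   nisT, nisI, nisZ, lanM, lanC, class3)
}

# the L. lactis NSR exemplar: a diverged paralog of the S. agalactiae
# stand-in with the signature boxes conserved
.nsr_lactis_entry <- function(nsr_aga) {
  mut <- mutate_protein(
    tibble::tibble(id = "NSR_Llac", sequence = nsr_aga$sequence),
    target_identity = 0.55, seed = NULL,
    protected = nsr_aga$motifs[[1]])
  tibble::tibble(name = "NSR_Llac", uniprot = "P23648", role = "nsr_query",
                 purpose = "resistance", sequence = mut$sequence,
                 length = nchar(mut$sequence), motifs = nsr_aga$motifs)
}

# registry subsets -------------------------------------------------------

#' Subset the registry to the resistance search panel
#' @param registry A [query_registry()] tibble.
#' @return Tibble of queries used for the genome-wide resistance/immunity
#'   screen.
#' @export
resistance_queries <- function(registry = query_registry()) {
  registry[registry$purpose %in% c("resistance", "immunity"), ]
}
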