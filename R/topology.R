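# Transmembrane topology from sliding-window hydropathy, and the structural
# rules separating ECD-bearing BceAB-type permeases from the ECD-less
# Corynebacterium-type systems.

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 amino acids (X scores 0).
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)
}

#' Topology prediction configuration
#'
#' @param window Odd sliding-window width in residues (default 19).
#' @param tmh_threshold Mean window hydropathy required for a helix call
#'   (default 1.6).
#' @param min_tmh_len Minimum helix run length kept (default 15).
#' @param min_loop_len Runs separated by fewer residues are merged
#'   (default 3).
#' @param ecd_min_len Minimum length (aa) for an outside loop to count as an
#'   extracellular domain (default 50).
#' @param scale Hydropathy scale, a named numeric vector.
#' @return A `topology_config` object.
#' @export
topology_config <- function(window = 19L, tmh_threshold = 1.6,
                            min_tmh_len = 15L, min_loop_len = 3L,
                            ecd_min_len = 50L, scale = kyte_doolittle()) {
  stopifnot(window %% 2 == 1, window >= 7, is.finite(tmh_threshold),
            min_tmh_len >= 1, min_loop_len >= 1, ecd_min_len >= 1)
  structure(list(window = as.integer(window), tmh_threshold = tmh_threshold,
                 min_tmh_len = as.integer(min_tmh_len),
                 min_loop_len = as.integer(min_loop_len),
                 ecd_min_len = as.integer(ecd_min_len), scale = scale),
            class = "topology_config")
}

# Runs of TRUE as (start, end) rows.
.runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Predict transmembrane helices and sided loops
#'
#' Classic hydropathy-plot prediction: a candidate helix is a maximal run of
#' positions whose centered window mean reaches the threshold; runs closer
#' than `min_loop_len` are merged, runs shorter than `min_tmh_len`
#' discarded. Loops are the complement, so helices and loops tile the
#' protein. Orientation follows the positive-inside rule: the N-terminal
#' side is chosen to maximize the lysine+arginine count over inside loops
#' (tie: N-terminus inside).
#'
#' @param protein One-row protein record tibble (or named character scalar).
#' @param config A [topology_config()].
#' @return A `topology_prediction` object: list with `protein_id`, `length`,
#'   `tmh` (tibble start/end), `loops` (tibble start/end/side/loop_length),
#'   `n_tmh`, `n_term_side`, and the per-residue `profile` tibble.
#' @export
predict_tmh <- function(protein, config = topology_config()) {
  p <- .as_protein(protein)
  L <- nchar(p$sequence)
  if (L < config$window) {
    stop("protein '", p$id, "' is shorter than the hydropathy window",
         call. = FALSE)
  }
  h <- unname(config$scale[strsplit(p$sequence, "")[[1]]])
  h[is.na(h)] <- 0
  w <- config$window
  half <- (w - 1L) %/% 2L
  means <- stats::filter(h, rep(1 / w, w), sides = 2)
  means <- as.numeric(means)  # NA at the truncated flanks
  mask <- !is.na(means) & means >= config$tmh_threshold
  runs <- .runs(mask)
  # merge runs separated by short gaps
  if (nrow(runs) > 1) {
    merged <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      prev <- merged[[length(merged)]]
      if (runs[i, "start"] - prev["end"] - 1L < config$min_loop_len) {
        prev["end"] <- runs[i, "end"]
        merged[[length(merged)]] <- prev
      } else {
        merged[[length(merged) + 1L]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, merged)
  }
  if (nrow(runs) > 0) {
    runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= config$min_tmh_len,
                 , drop = FALSE]
  }
  tmh <- tibble::tibble(start = as.integer(runs[, "start"]),
                        end = as.integer(runs[, "end"]))
  loops <- .complement_intervals(tmh, L)
  # positive-inside orientation
  chars <- strsplit(p$sequence, "")[[1]]
  kr_per_loop <- vapply(seq_len(nrow(loops)), function(i) {
    sum(chars[loops$start[i]:loops$end[i]] %in% c("K", "R"))
  }, numeric(1))
  odd <- seq_len(nrow(loops)) %% 2L == 1L
  kr_in_first <- sum(kr_per_loop[odd])
  kr_out_first <- sum(kr_per_loop[!odd])
  n_term_side <- if (kr_in_first >= kr_out_first) "in" else "out"
  sides <- rep(c("in", "out"), length.out = nrow(loops))
  if (n_term_side == "out") sides <- rep(c("out", "in"),
                                         length.out = nrow(loops))
  loops$side <- sides
  loops$loop_length <- loops$end - loops$start + 1L
  structure(list(
    protein_id = p$id, length = L, tmh = tmh, loops = loops,
    n_tmh = nrow(tmh), n_term_side = n_term_side,
    profile = tibble::tibble(position = seq_len(L), hydropathy = h,
                             window_mean = means)
  ), class = "topology_prediction")
}

.complement_intervals <- function(iv, L) {
  if (nrow(iv) == 0) {
    return(tibble::tibble(start = 1L, end = as.integer(L)))
  }
  starts <- c(1L, iv$end + 1L)
  ends <- c(iv$start - 1L, as.integer(L))
  keep <- starts <= ends
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' @export
print.topology_prediction <- function(x, ...) {
  cat("<topology_prediction> ", x$protein_id, ": ", x$n_tmh,
      " TMH, N-terminus ", x$n_term_side, "\n", sep = "")
  invisible(x)
}

#' Classify a permease topology as BceAB-type or Corynebacterium-type
#'
#' Pep7E-family permeases carry exactly 10 transmembrane helices; anything
#' else is `not_pep7e`. Among 10-TMH predictions, an outside loop of at
#' least `ecd_min_len` residues strictly between helices 7 and 8 marks the
#' classical BceAB architecture (`BceAB_with_ECD`); its absence marks the
#' unusual ECD-less type described for Corynebacterium
#' (`corynebacterium_type_no_ECD`).
#'
#' @param pred A `topology_prediction`.
#' @param config A [topology_config()] (supplies `ecd_min_len`).
#' @return A list `label` plus, for ECD-bearing calls, the `ecd` loop row.
#' @export
classify_transporter <- function(pred, config = topology_config()) {
  stopifnot(inherits(pred, "topology_prediction"))
  if (pred$n_tmh != 10L) {
    return(list(label = "not_pep7e", ecd = NULL))
  }
  between <- dplyr::filter(pred$loops,
                           .data$start > pred$tmh$end[7],
                           .data$end < pred$tmh$start[8])
  ecd <- dplyr::filter(between, .data$side == "out",
                       .data$loop_length >= config$ecd_min_len)
  if (nrow(ecd) > 0) {
    list(label = "BceAB_with_ECD", ecd = ecd[1, ])
  } else {
    list(label = "corynebacterium_type_no_ECD", ecd = NULL)
  }
}

#' Classify a histidine-kinase topology
#'
#' 0 TMH: cytoplasmic (the unusual Corynebacterium arrangement); 2 TMH with
#' a short connecting outside loop: BceS-like intramembrane sensing; 2 TMH
#' with an outside loop of at least `ecd_min_len`: CprK-like extracellular
#' sensing; anything else: other.
#'
#' @inheritParams classify_transporter
#' @return A label string.
#' @export
classify_kinase <- function(pred, config = topology_config()) {
  stopifnot(inherits(pred, "topology_prediction"))
  if (pred$n_tmh == 0L) return("cytoplasmic")
  if (pred$n_tmh != 2L) return("other")
  between <- dplyr::filter(pred$loops,
                           .data$start > pred$tmh$end[1],
                           .data$end < pred$tmh$start[2],
                           .data$side == "out")
  if (nrow(between) == 0) return("other")
  if (max(between$loop_length) >= config$ecd_min_len) "CprK_like"
  else "BceS_like"
}

#' Signed length difference between two proteins
#'
#' Returns `length(b) - length(a)` in residues, e.g. how much larger an
#' ECD-bearing permease is than its ECD-less counterpart.
#'
#' @param a,b One-row protein record tibbles or character scalars.
#' @return Signed integer.
#' @export
length_difference <- function(a, b) {
  nchar(.as_protein(b)$sequence) - nchar(.as_protein(a)$sequence)
}

#' Tabulate topology predictions for a report
#'
#' @param preds A list of `topology_prediction` objects.
#' @param config A [topology_config()] used for the class labels.
#' @return Tibble: protein_id, n_tmh, n_term_side, transporter_class,
#'   kinase_class, helix and loop summaries.
#' @export
topology_report <- function(preds, config = topology_config()) {
  purrr::map_dfr(preds, function(pr) {
    tibble::tibble(
      protein_id = pr$protein_id, n_tmh = pr$n_tmh,
      n_term_side = pr$n_term_side,
      transporter_class = classify_transporter(pr, config)$label,
      kinase_class = classify_kinase(pr, config),
      helices = paste(sprintf("%d-%d", pr$tmh$start, pr$tmh$end),
                      collapse = ","),
      loops = paste(sprintf("%d-%d(%s)", pr$loops$start, pr$loops$end,
                            pr$loops$side), collapse = ",")
    )
  })
}
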