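# Microdilution dose-response analysis: relative growth normalization,
# Gompertz curve fitting, the serial-dilution MIC reading rule, and
# induction fold-changes.

#' Decreasing Gompertz dose-response curve
#'
#' `G(d) = A * exp(-exp(s * log(d / m)))`: amplitude `A` as `d -> 0`, zero
#' growth as `d -> Inf`, inflection at dose `m`, dimensionless slope `s`.
#'
#' @param dose Dose vector (same units as `m`, conventionally ug/mL).
#' @param A Amplitude (relative growth of the untreated control, ~1).
#' @param m Inflection dose.
#' @param s Slope, > 0.
#' @return Relative growth values.
#' @export
gompertz_response <- function(dose, A, m, s) {
  A * exp(-exp(s * log(dose / m)))
}

.validate_assay <- function(assay) {
  need <- c("strain", "condition", "concentration", "od_t0", "od_t24",
            "is_untreated")
  stopifnot(all(need %in% names(assay)))
  if (!any(assay$is_untreated)) {
    stop("assay has no untreated control wells", call. = FALSE)
  }
  # each (strain, condition) series must be a two-fold dilution ladder
  series <- split(assay[!assay$is_untreated, ],
                  paste(assay$strain, assay$condition)[!assay$is_untreated])
  for (s in series) {
    conc <- sort(unique(s$concentration), decreasing = TRUE)
    if (length(conc) > 1) {
      ratios <- conc[-length(conc)] / conc[-1]
      if (any(abs(ratios - 2) > 0.15)) {
        stop("concentrations of ", s$strain[1], "/", s$condition[1],
             " are not a two-fold dilution series", call. = FALSE)
      }
    }
  }
  invisible(assay)
}

#' Relative growth of a dilution assay
#'
#' Per well, the background (`od_t0`) is subtracted from the 24 h reading
#' and the difference normalized to the mean growth of the untreated
#' control wells (100% growth).
#'
#' @param assay Tidy plate tibble with columns `strain`, `condition`,
#'   `concentration` (ug/mL), `od_t0`, `od_t24`, `is_untreated` (see
#'   [read_plate()] / [simulate_assay()]).
#' @return Tibble `strain`, `condition`, `concentration`, `rel_growth`
#'   (untreated wells excluded; replicate wells averaged).
#' @export
relative_growth <- function(assay) {
  .validate_assay(assay)
  one_series <- function(df, key) {
    untreated <- df[df$is_untreated, , drop = FALSE]
    denom <- mean(untreated$od_t24 - untreated$od_t0)
    if (!is.finite(denom) || denom <= 0) {
      stop("untreated control of ", paste(unlist(key), collapse = "/"),
           " shows no growth (denominator <= 0)", call. = FALSE)
    }
    df[!df$is_untreated, , drop = FALSE] |>
      dplyr::mutate(rel_growth = (.data$od_t24 - .data$od_t0) / denom) |>
      dplyr::group_by(.data$concentration) |>
      dplyr::summarise(rel_growth = mean(.data$rel_growth),
                       .groups = "drop")
  }
  assay |>
    dplyr::group_by(.data$strain, .data$condition) |>
    dplyr::group_modify(one_series) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$strain, .data$condition,
                   dplyr::desc(.data$concentration))
}

#' Fit a Gompertz dose-response curve
#'
#' Bounded Levenberg-Marquardt least squares of [gompertz_response()] to
#' (concentration, relative growth) points. Initialization: `A` at the
#' maximum observed growth, `m` at the geometric mean of the two
#' concentrations bracketing half-maximal growth, `s = 4`. Bounds:
#' `A` in (0, 1.5], `m` within the tested range times \[1/4, 4\],
#' `s` in (0.1, 50\].
#'
#' @param points Tibble with `concentration` and `rel_growth` (at least 4
#'   points spanning both sides of the transition).
#' @return A `gompertz_fit` object (supports [generics::tidy()],
#'   [generics::glance()], `predict()` and `ggplot2::autoplot()`).
#' @export
fit_gompertz <- function(points) {
  stopifnot(nrow(points) >= 4)
  pts <- dplyr::arrange(points, .data$concentration)
  A0 <- max(pts$rel_growth)
  if (A0 <= 0) stop("no growth anywhere: cannot fit a dose response",
                    call. = FALSE)
  half <- A0 / 2
  below <- pts$concentration[pts$rel_growth <= half]
  above <- pts$concentration[pts$rel_growth > half]
  m0 <- if (length(below) > 0 && length(above) > 0) {
    sqrt(min(below) * max(above))
  } else {
    exp(mean(log(range(pts$concentration))))
  }
  rng <- range(pts$concentration)
  lower <- c(A = 1e-6, m = rng[1] / 4, s = 0.1)
  upper <- c(A = 1.5, m = rng[2] * 4, s = 50)
  start <- c(A = min(max(A0, 0.05), 1.5), m = m0, s = 4)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rel_growth ~ gompertz_response(concentration, A, m, s),
      data = pts, start = as.list(start),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
  } else {
    # a steep transition can leave (m, s) unidentifiable for a
    # derivative-based step; fall back to direct search on log-parameters
    obj <- function(lp) {
      p <- pmin(pmax(exp(lp), lower), upper)
      sum((pts$rel_growth -
             gompertz_response(pts$concentration, p[1], p[2], p[3]))^2)
    }
    opt <- stats::optim(log(start), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    est <- pmin(pmax(exp(opt$par), lower), upper)
    names(est) <- c("A", "m", "s")
    rss <- opt$value
  }
  at_bound <- est[["m"]] <= lower[["m"]] * 1.001 ||
    est[["m"]] >= upper[["m"]] * 0.999 || est[["s"]] <= 0.101
  structure(list(
    A = est[["A"]], m = est[["m"]], s = est[["s"]],
    rss = rss, nls = fit, points = pts,
    boundary = at_bound
  ), class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf("<gompertz_fit> A=%.3f, m=%.4g ug/mL, s=%.3g, rss=%.3g%s\n",
              x$A, x$m, x$s, x$rss,
              if (x$boundary) " [boundary fit]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.gompertz_fit <- function(x, ...) {
  if (!is.null(x$nls)) {
    s <- summary(x$nls)$coefficients
    tibble::tibble(term = rownames(s), estimate = s[, "Estimate"],
                   std.error = s[, "Std. Error"])
  } else {
    tibble::tibble(term = c("A", "m", "s"), estimate = c(x$A, x$m, x$s),
                   std.error = NA_real_)
  }
}

#' @export
glance.gompertz_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$points),
                 boundary = x$boundary,
                 converged = if (!is.null(x$nls)) x$nls$convInfo$isConv
                             else TRUE)
}

#' @export
predict.gompertz_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$points$concentration
       else newdata$concentration
  gompertz_response(d, object$A, object$m, object$s)
}

#' Read the MIC from a relative-growth table
#'
#' The MIC is the lowest tested concentration showing no growth
#' (relative growth at or below `tau`) such that every higher tested
#' concentration also shows no growth -- the standard reading of a serial
#' dilution plate. Isolated no-growth dips with regrowth above them are
#' ignored (and reported via a message). When even the highest tested
#' concentration permits growth the MIC is right-censored.
#'
#' @param points Tibble with `concentration` and `rel_growth` (any row
#'   order).
#' @param tau No-growth threshold on relative growth (default 0.05, the
#'   plate-reader noise floor).
#' @return One-row tibble: `mic` (ug/mL, `NA` when censored), `censored`,
#'   `mic_label` (the printed value, `">MAX"` style when censored).
#' @export
extract_mic <- function(points, tau = 0.05) {
  pts <- dplyr::arrange(points, dplyr::desc(.data$concentration))
  dead <- pts$rel_growth <= tau
  # longest no-growth tail from the top concentration downwards
  tail_len <- if (all(dead)) length(dead) else (which(!dead)[1] - 1L)
  n_dips <- sum(dead) - tail_len
  if (n_dips > 0) {
    message("extract_mic: ignoring ", n_dips,
            " isolated no-growth well(s) with regrowth above")
  }
  if (tail_len == 0) {
    return(tibble::tibble(mic = NA_real_, censored = TRUE,
                          mic_label = paste0(">",
                                             format(max(pts$concentration)))))
  }
  mic <- pts$concentration[tail_len]
  tibble::tibble(mic = mic, censored = FALSE, mic_label = format(mic))
}

#' Induction fold-change between two MIC results
#'
#' Ratio of the test MIC over the reference MIC (e.g. induced over
#' uninduced). Undefined (NA, with a `reason`) when either value is
#' censored.
#'
#' @param test,reference One-row MIC tibbles from [extract_mic()].
#' @return One-row tibble `fold_change`, `reason`.
#' @export
fold_change <- function(test, reference) {
  if (isTRUE(test$censored) || isTRUE(reference$censored)) {
    return(tibble::tibble(fold_change = NA_real_,
                          reason = "censored MIC in comparison"))
  }
  tibble::tibble(fold_change = test$mic / reference$mic, reason = NA_character_)
}

#' Read a plate table from TSV
#'
#' Expected columns: strain, condition, concentration_ug_ml, od600_t0,
#' od600_t24, is_untreated.
#'
#' @param path TSV file path.
#' @return A tidy assay tibble for [relative_growth()].
#' @export
read_plate <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::tibble(strain = df$strain, condition = df$condition,
                 concentration = df$concentration_ug_ml,
                 od_t0 = df$od600_t0, od_t24 = df$od600_t24,
                 is_untreated = as.logical(df$is_untreated))
}

#' Summarise MICs and induction fold-changes for a set of assays
#'
#' @param assays Tidy plate tibble holding one or more (strain, condition)
#'   series.
#' @param tau No-growth threshold for [extract_mic()].
#' @param reference_condition Condition used as the fold-change denominator
#'   (default `"uninduced"`).
#' @return Tibble: strain, condition, mic_label, mic, fold_change vs the
#'   reference condition of the same strain.
#' @export
mic_table <- function(assays, tau = 0.05, reference_condition = "uninduced") {
  rel <- relative_growth(assays)
  res <- rel |>
    dplyr::group_by(.data$strain, .data$condition) |>
    dplyr::group_modify(~ extract_mic(.x, tau)) |>
    dplyr::ungroup()
  ref <- res[res$condition == reference_condition,
             c("strain", "mic", "censored")]
  names(ref) <- c("strain", "ref_mic", "ref_censored")
  dplyr::left_join(res, ref, by = "strain") |>
    dplyr::mutate(fold_change = dplyr::if_else(
      !.data$censored & !.data$ref_censored,
      .data$mic / .data$ref_mic, NA_real_)) |>
    dplyr::select(-"ref_mic", -"ref_censored")
}
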