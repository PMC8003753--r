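# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Hydropathy profile with predicted helices
#'
#' @param object A `topology_prediction` from [predict_tmh()].
#' @param config A [topology_config()] (for the threshold line).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.topology_prediction <- function(object,
                                         config = topology_config(), ...) {
  prof <- object$profile
  helix <- object$tmh
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$position,
                                     y = .data$window_mean)) +
    ggplot2::geom_rect(
      data = helix,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "grey85", inherit.aes = FALSE) +
    ggplot2::geom_hline(yintercept = config$tmh_threshold,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(
      title = paste0(object$protein_id, ": ", object$n_tmh,
                     " predicted TMH (N-terminus ", object$n_term_side, ")"),
      x = "residue", y = "mean window hydropathy") +
    ggplot2::theme_minimal()
}

#' Dose-response curve with the fitted Gompertz model
#'
#' @param object A `gompertz_fit` from [fit_gompertz()].
#' @param ... Unused.
#' @return A ggplot object (log10 dose axis).
#' @export
autoplot.gompertz_fit <- function(object, ...) {
  pts <- object$points
  rng <- range(pts$concentration)
  curve <- tibble::tibble(
    concentration = exp(seq(log(rng[1]), log(rng[2]), length.out = 200)))
  curve$rel_growth <- predict(object, curve)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$concentration,
                                    y = .data$rel_growth)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (µg/mL)",
                  y = "relative growth",
                  title = sprintf("Gompertz fit: A=%.2f, m=%.3g, s=%.2f",
                                  object$A, object$m, object$s)) +
    ggplot2::theme_minimal()
}

#' Trait-matrix tile plot
#'
#' @param traits Trait tibble from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_trait_matrix <- function(traits) {
  long <- traits |>
    tidyr::pivot_longer(dplyr::all_of(c("BGC", "LanI", "CprABC", "BceAB",
                                        "NSR", "HK", "RR", "LysX")),
                        names_to = "trait", values_to = "call") |>
    dplyr::mutate(trait = factor(.data$trait,
                                 levels = c("BGC", "LanI", "CprABC",
                                            "BceAB", "NSR", "HK", "RR",
                                            "LysX")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trait, y = .data$species,
                                     fill = .data$call)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$call), size = 3) +
    ggplot2::scale_fill_manual(values = c("+" = "#7fbf7b",
                                          "(+)" = "#d9f0d3",
                                          "-" = "grey92")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Gene map of a resistance locus
#'
#' @param locus One-row locus tibble from [resistance_loci()].
#' @return A ggplot object with one arrow per member gene, coloured by
#'   role.
#' @export
plot_locus_map <- function(locus) {
  m <- locus$members[[1]]
  m$y <- 1
  ggplot2::ggplot(m) +
    ggplot2::geom_segment(
      ggplot2::aes(x = ifelse(.data$strand == "+", .data$start, .data$end),
                   xend = ifelse(.data$strand == "+", .data$end,
                                 .data$start),
                   y = .data$y, yend = .data$y, colour = .data$role),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.25, "cm")),
      linewidth = 3, lineend = "butt") +
    ggplot2::geom_text(ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = 1.15, label = .data$locus_tag),
                       size = 2.5, angle = 30) +
    ggplot2::ylim(0.5, 1.5) +
    ggplot2::labs(x = paste0(locus$genome_id, " (bp)"), y = NULL,
                  colour = "role",
                  title = paste0(locus$locus_id, ": ",
                                 locus$architecture)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
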