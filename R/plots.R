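#' Manhattan-style plot of a homozygosity scan
#'
#' @param object A `scan_result` (see [roh_scan()]).
#' @param threshold_log10p Genome-wide threshold line (default 8).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scan_result <- function(object, threshold_log10p = 8, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position_bp / 1e6,
                               y = .data$minus_log10_p,
                               colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.6, show.legend = length(unique(object$chromosome)) > 1) +
    ggplot2::geom_hline(yintercept = threshold_log10p, linetype = "dashed",
                        colour = "purple") +
    ggplot2::facet_grid(. ~ chromosome, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = expression(-log[10](p)),
                  title = "Homozygosity association scan") +
    ggplot2::theme_minimal()
}

#' Power curves over the simulation grid
#'
#' Mirrors the power-study panel layout: power against the carrier fraction
#' `delta`, one line per window size `W`, faceted by heterozygous
#' interference `epsilon` and tract length `L`.
#'
#' @param object A `power_grid` (see [power_grid()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$delta, y = .data$power,
                               colour = factor(.data$W),
                               group = factor(.data$W))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$power - 2 * .data$se, 0),
                                        ymax = pmin(.data$power + 2 * .data$se, 1)),
                           width = 0.005) +
    ggplot2::facet_grid(L ~ epsilon,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(delta~"(fraction of cases carrying the ROH)"),
                  y = "power", colour = "W") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Group median intensity along the genome
#'
#' @param object An `intensity_profile` (see [homozygote_intensity()]).
#' @param ... Unused.
#' @return A ggplot of per-group median homozygote intensity by position.
#' @export
autoplot.intensity_profile <- function(object, ...) {
  I <- object$intensity
  phen <- object$phenotype
  df <- dplyr::bind_rows(lapply(c("CASE", "CONTROL"), function(gr) {
    rows <- !is.na(phen) & phen == gr
    if (!any(rows)) return(NULL)
    tibble(position_bp = object$anchors$position_bp,
           chromosome = object$anchors$chromosome,
           median_intensity = cpp_col_medians(I[rows, , drop = FALSE]),
           group = gr)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position_bp / 1e6,
                                   y = .data$median_intensity,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(. ~ chromosome, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "median homozygote intensity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
plot.scan_result <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.power_grid <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.intensity_profile <- function(x, ...) print(autoplot(x, ...))

#' @rdname roh_scan
#' @param x A `scan_result`.
#' @param ... Unused.
#' @export
glance.scan_result <- function(x, ...) {
  tibble(
    n_anchors = nrow(x),
    n_excluded = attr(x, "n_anchors_excluded") %||% sum(is.na(x$minus_log10_p)),
    peak_minus_log10_p = suppressWarnings(max(x$minus_log10_p, na.rm = TRUE)),
    peak_snp = x$snp_id[which.max(x$minus_log10_p)],
    W = attr(x, "W")
  )
}
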