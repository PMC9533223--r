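#' Plot window statistics along the genome
#'
#' Faceted tracks of per-window FST, diversity and Tajima's D.
#'
#' @param object A `win_stats` tibble from [window_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.win_stats <- function(object, ...) {
  long <- object |>
    mutate(pos = (.data$start + .data$end) / 2) |>
    select("contig", "pos", "fst", "pi_a", "pi_b", "tajima_d",
           "z_fst", "log2_pi_ratio") |>
    pivot_longer(-c("contig", "pos"), names_to = "statistic")
  ggplot(long, aes(x = .data$pos / 1e6, y = .data$value)) +
    geom_line(linewidth = 0.3, na.rm = TRUE) +
    facet_grid(rows = vars(.data$statistic), scales = "free_y") +
    labs(x = "position (Mb)", y = NULL) +
    theme_minimal()
}

#' Manhattan-style plot of standardized scan scores
#'
#' @param object A `scan_scores` tibble.
#' @param threshold Horizontal reference line (default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_scores <- function(object, threshold = 2, ...) {
  stat <- object$statistic[1]
  two_sided <- stat %in% c("iHS", "nSL")
  p <- ggplot(object, aes(x = .data$position / 1e6, y = .data$std)) +
    geom_point(size = 0.4, alpha = 0.6, na.rm = TRUE) +
    geom_hline(yintercept = threshold, linetype = "dashed",
               colour = "grey40") +
    labs(x = "position (Mb)", y = sprintf("standardized %s", stat)) +
    theme_minimal()
  if (two_sided) {
    p <- p + geom_hline(yintercept = -threshold, linetype = "dashed",
                        colour = "grey40")
  }
  p
}

#' Plot window proportions of extreme scan scores
#'
#' @param object A `prop_windows` tibble from [proportion_windows()].
#' @param ... Unused.
#' @return A ggplot object showing per-window proportions with the 95/99
#'   percentile tiers highlighted.
#' @export
autoplot.prop_windows <- function(object, ...) {
  ggplot(object, aes(x = (.data$start + .data$end) / 2e6,
                     y = .data$proportion, fill = .data$tier)) +
    geom_col(width = (object$end - object$start) / 1e6 * 0.9) +
    scale_fill_manual(values = c("none" = "grey70", ">=95%" = "orange",
                                 ">=99%" = "firebrick")) +
    labs(x = "position (Mb)",
         y = sprintf("proportion extreme %s", object$statistic[1]),
         fill = "tier") +
    theme_minimal()
}

#' Plot a linkage-disequilibrium decay curve
#'
#' @param object An `ld_decay` tibble from [ld_decay()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ld_decay <- function(object, ...) {
  ggplot(object, aes(x = (.data$bin_start + .data$bin_end) / 2e3,
                     y = .data$mean_r2)) +
    geom_line() +
    geom_point(size = 0.7) +
    labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ylim(0, 1) +
    theme_minimal()
}

#' Plot an EHH decay curve
#'
#' @param object An `ehh_curve` tibble from [ehh_curve()].
#' @param ... Unused.
#' @return A ggplot object of EHH against signed distance from the core.
#' @export
autoplot.ehh_curve <- function(object, ...) {
  core <- attr(object, "core_position")
  ggplot(object, aes(x = (.data$position - core) / 1e3, y = .data$ehh)) +
    geom_step() +
    labs(x = "distance from core (kb)", y = "EHH") +
    ylim(0, 1) +
    theme_minimal()
}
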