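#' Plot an ensemble of simulated trajectories
#'
#' Spaghetti plot of a long-format trajectory tibble as returned by
#' [simulate_sde()], [simulate_population()] or [simulate_learning()].
#'
#' @param traj Tibble with columns `traj`, `time`, and one value column
#'   (`z`, `r` or `w`).
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(traj, alpha = 0.5) {
  value_col <- setdiff(names(traj), c("traj", "time"))[1]
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time,
                                     y = .data[[value_col]],
                                     group = .data$traj)) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.3) +
    ggplot2::labs(x = "time", y = value_col) +
    ggplot2::theme_minimal()
}

#' Plot the effective BCM potential
#'
#' Core potential and, optionally, the stimulus-deformed potential over a
#' weight grid covering the fixed points (the panel used to discuss
#' bistability and barrier lowering).
#'
#' @param params A [bcm_params()].
#' @param c Input rates to display (vector; 0 is always included).
#' @param w_max Upper end of the weight grid (default `1.2 * w_u` when
#'   bistable).
#' @param n Number of grid points.
#' @return A ggplot object.
#' @export
plot_bcm_potential <- function(params, c = 0, w_max = NULL, n = 400L) {
  stopifnot(inherits(params, "bcm_params"))
  bis <- bistability(params)
  if (is.null(w_max)) {
    w_max <- if (bis$bistable) 1.2 * bis$w_u else 1
  }
  grid <- seq(0, w_max, length.out = n)
  cs <- sort(unique(c(0, c)))
  df <- dplyr::bind_rows(lapply(cs, function(ci) bcm_potential(grid, ci, params)))
  df$input <- factor(df$c)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w_bar, y = .data$V,
                                   colour = .data$input)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "mean synaptic weight", y = "effective potential V",
                  colour = "input c (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a probability trajectory of a discrete system
#'
#' One line per state from the long-format output of [evolve_master()].
#'
#' @param traj Tibble with columns `time`, `state`, `p`.
#' @return A ggplot object.
#' @export
plot_prob_trajectory <- function(traj) {
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time, y = .data$p,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "probability") +
    ggplot2::theme_minimal()
}
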