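#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation result
#'
#' Returns the recorded quantity as a tibble: `"weights"` (time-resolved
#' plastic weights), `"spikes"` (spike raster) or `"trace"` (recorded
#' voltages, if any were requested).
#'
#' @param x A `"dendplast_sim"` object.
#' @param what One of `"weights"`, `"spikes"`, `"trace"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dendplast_sim
#' @export
tidy.dendplast_sim <- function(x, what = c("weights", "spikes", "trace"),
                               ...) {
  what <- match.arg(what)
  out <- switch(what,
    weights = x$weights,
    spikes = x$spikes,
    trace = x$trace
  )
  if (is.null(out)) {
    stop("tidy.dendplast_sim: no ", what, " were recorded", call. = FALSE)
  }
  out
}

#' One-row summary of a simulation
#'
#' @param x A `"dendplast_sim"` object.
#' @param ... Unused.
#' @return A tibble with `duration_ms`, `n_spikes`, `n_synapses`,
#'   `n_plastic`, `mean_w_final`.
#' @method glance dendplast_sim
#' @export
glance.dendplast_sim <- function(x, ...) {
  pl <- x$synapses$plastic
  tibble::tibble(
    duration_ms = x$duration_ms,
    n_spikes = nrow(x$spikes),
    n_synapses = nrow(x$synapses),
    n_plastic = sum(pl),
    mean_w_final = if (any(pl)) mean(x$synapses$w[pl]) else NA_real_
  )
}

#' Plot the weight trajectories of a simulation
#'
#' @param object A `"dendplast_sim"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dendplast_sim
#' @export
autoplot.dendplast_sim <- function(object, ...) {
  stopifnot(!is.null(object$weights))
  df <- dplyr::inner_join(
    object$weights,
    dplyr::select(object$synapses, "syn_id", "loc"),
    by = "syn_id"
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      .data$time_ms / 1000, .data$w,
      group = .data$syn_id, colour = .data$loc
    )
  ) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "time (s)", y = "synaptic weight", colour = "placement"
    ) +
    ggplot2::theme_minimal()
}

#' Spike raster plot
#'
#' @param sim A `"dendplast_sim"` object.
#' @return A ggplot.
#' @export
plot_raster <- function(sim) {
  ggplot2::ggplot(
    sim$spikes, ggplot2::aes(.data$time_ms / 1000, .data$neuron)
  ) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Plot a pairing-protocol frequency curve
#'
#' @param pairing Output of [protocol_pairing()].
#' @return A ggplot of normalised weight versus pairing frequency.
#' @export
plot_pairing_curve <- function(pairing) {
  ggplot2::ggplot(
    pairing,
    ggplot2::aes(
      .data$freq_hz, .data$ratio,
      colour = .data$location, linetype = .data$side
    )
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "pairing frequency (Hz)", y = "normalised weight"
    ) +
    ggplot2::theme_minimal()
}

#' Plot block-averaged network weights over time
#'
#' @param object A `"dendplast_memory"` object from
#'   [protocol_feature_network()] or [protocol_two_associations()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dendplast_memory
#' @export
autoplot.dendplast_memory <- function(object, ...) {
  df <- object$blocks |>
    dplyr::mutate(
      kind = ifelse(.data$pre_feature == .data$post_feature,
        "within feature", "between features"
      )
    ) |>
    dplyr::group_by(.data$time_ms, .data$loc, .data$kind) |>
    dplyr::summarise(mean_w = mean(.data$mean_w), .groups = "drop")
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      .data$time_ms / 1000, .data$mean_w,
      colour = .data$loc, linetype = .data$kind
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = "mean plastic weight",
      colour = "placement", linetype = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @method glance dendplast_memory
#' @export
glance.dendplast_memory <- function(x, ...) {
  glance(x$sim)
}

#' Export a recorded voltage trace as delimited text
#'
#' @param sim A `"dendplast_sim"` with a recorded trace.
#' @param path Output file (tab-separated: `time_ms`, `neuron`,
#'   `compartment`, `dend`, `u_mV`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(sim, path) {
  if (is.null(sim$trace)) {
    stop("write_trace: no trace was recorded", call. = FALSE)
  }
  utils::write.table(sim$trace, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
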