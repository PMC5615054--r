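#' Seeded homogeneous Poisson spike train
#'
#' Draws a spike count from `Poisson(rate * duration)` and places the spikes
#' uniformly in `[0, duration)`, snapped to the integration grid. Reproducible
#' given `seed`; with `seed = NULL` the current RNG stream is used (protocol
#' drivers seed once and then generate all their trains from the stream).
#'
#' @param rate Average rate (Hz).
#' @param duration_ms Window length (ms).
#' @param dt Grid step (ms).
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of spike times (ms) on the grid.
#' @export
#' @examples
#' poisson_train(40, 1000, seed = 1)
poisson_train <- function(rate, duration_ms, dt = 0.25, seed = NULL) {
  stopifnot(rate >= 0, duration_ms >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- stats::rpois(1, rate * duration_ms / 1000)
  if (n == 0) {
    return(numeric(0))
  }
  sort(floor(stats::runif(n, 0, duration_ms) / dt) * dt)
}

#' Build the input-spike table for timed activation events
#'
#' Expands a schedule of activation events (each: onset, a set of input
#' sources, a Poisson rate and a duration) into the flat `input_spikes`
#' table consumed by [run_sim()]. Each listed source receives its own
#' independent Poisson train per event.
#'
#' @param events Tibble with columns `onset_ms`, `rate_hz`, `duration_ms`
#'   and a list-column `input_ids`.
#' @param dt Grid step (ms).
#' @return Tibble with columns `time_ms`, `input_id`.
#' @export
schedule_input_spikes <- function(events, dt = 0.25) {
  if (nrow(events) == 0) {
    return(tibble::tibble(time_ms = numeric(0), input_id = integer(0)))
  }
  out <- vector("list", nrow(events))
  for (r in seq_len(nrow(events))) {
    ids <- events$input_ids[[r]]
    trains <- lapply(ids, function(id) {
      poisson_train(events$rate_hz[r], events$duration_ms[r], dt = dt)
    })
    lens <- lengths(trains)
    if (sum(lens)) {
      out[[r]] <- tibble::tibble(
        time_ms = events$onset_ms[r] + unlist(trains, use.names = FALSE),
        input_id = rep(ids, lens)
      )
    }
  }
  dplyr::bind_rows(out)
}
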