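#' Published synapse-to-soma distances for connected layer-5 pairs
#'
#' Distances from the soma (basal and oblique dendrites only) of synapses
#' between thick-tufted layer-5 pyramidal neurons, grouped by whether the
#' neuron pair was connected in one or in both directions. Each row carries a
#' multiplicity: the number of synapses observed at that distance.
#'
#' @return A tibble with columns `distance_um` (numeric), `multiplicity`
#'   (integer) and `class` (`"unidirectional"` or `"bidirectional"`).
#' @export
#' @examples
#' markram_distances()
markram_distances <- function() {
  path <- system.file("extdata", "markram_distances.tsv",
    package = "dendplast", mustWork = TRUE
  )
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$multiplicity <- as.integer(df$multiplicity)
  tibble::as_tibble(df)
}

check_multiplicity_input <- function(x, m) {
  if (length(x) == 0) {
    stop("multiplicity statistics need at least one sample", call. = FALSE)
  }
  if (length(x) != length(m)) {
    stop("`x` and `multiplicity` must have equal length", call. = FALSE)
  }
  if (any(m < 1) || any(m != round(m))) {
    stop("`multiplicity` must be positive integers", call. = FALSE)
  }
}

#' Multiplicity-weighted mean and population standard deviation
#'
#' Equivalent to expanding each value `x[i]` into `multiplicity[i]` repeated
#' observations and taking the plain mean, or the population (N-divisor)
#' standard deviation.
#'
#' @param x Numeric values (e.g. distances in micrometres).
#' @param multiplicity Positive integer counts, one per value.
#' @return A single number.
#' @export
#' @examples
#' multiplicity_mean(c(10, 20), c(3, 1)) # 12.5
multiplicity_mean <- function(x, multiplicity = rep(1L, length(x))) {
  check_multiplicity_input(x, multiplicity)
  sum(x * multiplicity) / sum(multiplicity)
}

#' @rdname multiplicity_mean
#' @export
multiplicity_sd <- function(x, multiplicity = rep(1L, length(x))) {
  check_multiplicity_input(x, multiplicity)
  mu <- sum(x * multiplicity) / sum(multiplicity)
  sqrt(sum(multiplicity * (x - mu)^2) / sum(multiplicity))
}

#' Summarise connection distances per connectivity class
#'
#' Multiplicity-weighted mean and population standard deviation of the
#' synapse-to-soma distance for each connectivity class.
#'
#' @param data A data frame with columns `distance_um`, `multiplicity` and
#'   `class`; defaults to [markram_distances()].
#' @return A tibble with one row per class: `class`, `n_synapses`, `mean_um`,
#'   `sd_um`.
#' @export
#' @examples
#' connection_distance_summary()
connection_distance_summary <- function(data = markram_distances()) {
  stopifnot(all(c("distance_um", "multiplicity", "class") %in% names(data)))
  data |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n_synapses = sum(.data$multiplicity),
      mean_um = multiplicity_mean(.data$distance_um, .data$multiplicity),
      sd_um = multiplicity_sd(.data$distance_um, .data$multiplicity),
      .groups = "drop"
    )
}
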