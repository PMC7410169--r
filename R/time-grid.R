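#' Discrete time grid for the coalescent model
#'
#' The sampler works on a discrete set of coalescence times (in years before
#' present). Migration bands and population divergences are placed at "half
#' time-points" between adjacent coalescence times, computed as arithmetic
#' midpoints. Internally, times are converted to generations using the
#' model's generation time.
#'
#' @param times Numeric vector of coalescence times in years before present,
#'   strictly increasing, starting at 0. At least two times are required.
#' @param generation_time Generation time in years (default 29).
#' @return An object of class `time_grid` with elements `times` (years),
#'   `half` (K-1 half time-points, years), `K`, `generation_time`, and the
#'   generation-scaled versions `times_gen`, `half_gen`.
#' @examples
#' g <- time_grid(c(0, 100e3, 300e3))
#' g$half  # 50e3, 200e3
#' @export
time_grid <- function(times, generation_time = 29) {
  times <- as.numeric(times)
  if (length(times) < 2)
    stop("invalid grid: need at least two time points", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("invalid grid: times must be strictly increasing", call. = FALSE)
  if (times[1] != 0)
    stop("invalid grid: first time must be 0", call. = FALSE)
  if (generation_time <= 0)
    stop("generation_time must be positive", call. = FALSE)
  half <- (times[-length(times)] + times[-1]) / 2
  structure(
    list(
      times = times,
      half = half,
      K = length(times),
      generation_time = generation_time,
      times_gen = times / generation_time,
      half_gen = half / generation_time
    ),
    class = "time_grid"
  )
}

#' The default 20-point hominin time grid
#'
#' Twenty coalescence times spanning 0 to 15 Mya with higher density near the
#' present, suitable for modeling coalescence among modern humans, archaic
#' hominins and a great-ape outgroup. The first half time-points fall at
#' 50, 150, 250 and 350 kya, where hominin migration events are placed.
#'
#' @param generation_time Generation time in years (default 29).
#' @return A [time_grid()].
#' @export
default_time_grid <- function(generation_time = 29) {
  kya <- c(0, 100, 200, 300, 400, 450, 500, 550, 600, 700, 950, 1200,
           1450, 1700, 2000, 3000, 5000, 7000, 13000, 15000)
  time_grid(kya * 1000, generation_time = generation_time)
}

#' @export
print.time_grid <- function(x, ...) {
  cat("<time_grid> K =", x$K, "points,",
      format(max(x$times), big.mark = ","), "years deep\n")
  invisible(x)
}

#' Snap a time to the nearest half time-point
#'
#' Divergence and migration times supplied by the user are rounded to the
#' nearest half time-point of the grid. Ties are broken toward the younger
#' half time-point.
#'
#' @param grid A [time_grid()] (or an object with a `$grid` element, such as
#'   a demographic model).
#' @param time Time in years before present.
#' @return The snapped time in years.
#' @export
snap_to_half_time <- function(grid, time) {
  if (!inherits(grid, "time_grid") && !is.null(grid$grid)) grid <- grid$grid
  stopifnot(inherits(grid, "time_grid"))
  vapply(time, function(t) {
    if (is.na(t) || t < 0 || t > max(grid$times))
      stop("time ", t, " is outside the grid range [0, ",
           max(grid$times), "]", call. = FALSE)
    grid$half[which.min(abs(grid$half - t))]
  }, numeric(1))
}

# Index (1-based into grid$half) of the nearest half time-point.
half_index <- function(grid, time) {
  snapped <- snap_to_half_time(grid, time)
  match(snapped, grid$half)
}

# Nearest grid time index (1-based into grid$times); used for sample ages.
grid_time_index <- function(grid, time) {
  vapply(time, function(t) {
    if (is.na(t) || t < 0 || t > max(grid$times))
      stop("time ", t, " is outside the grid range", call. = FALSE)
    which.min(abs(grid$times - t))
  }, integer(1))
}
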