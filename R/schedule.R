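#' Temperature schedules
#'
#' A temperature schedule is an ordered list of segments, each a duration
#' (ns) at a constant temperature (K).  It encodes the escalating-temperature
#' protocol used to probe metastability: a room-temperature segment followed
#' by rungs at stepwise higher temperatures.
#'
#' @param duration_ns numeric vector of segment durations in ns (> 0).
#' @param temperature_K numeric vector of segment temperatures in K (> 0),
#'   same length as `duration_ns`.
#' @return An object of class `temperature_schedule` with fields
#'   `segments` (data frame `duration_ns`, `temperature_K`) and
#'   `total_ns`.
#' @examples
#' sch <- temperature_schedule(c(32, 12, 12, 20), c(303, 333, 363, 390))
#' temperature_at(sch, 40)  # 333 K
#' @export
temperature_schedule <- function(duration_ns, temperature_K) {
  stopifnot(length(duration_ns) == length(temperature_K),
            length(duration_ns) >= 1L)
  if (any(duration_ns <= 0)) stop("segment durations must be > 0")
  if (any(temperature_K <= 0)) stop("temperatures must be > 0 K")
  structure(list(
    segments = data.frame(duration_ns = as.numeric(duration_ns),
                          temperature_K = as.numeric(temperature_K)),
    total_ns = sum(as.numeric(duration_ns))
  ), class = "temperature_schedule")
}

#' Temperature at a given time
#'
#' Piecewise-constant, right-continuous lookup on `[0, total)`.
#'
#' @param schedule a [temperature_schedule()].
#' @param t_ns time(s) in ns.
#' @return temperature(s) in K.
#' @export
temperature_at <- function(schedule, t_ns) {
  stopifnot(inherits(schedule, "temperature_schedule"))
  if (any(t_ns < 0 | t_ns >= schedule$total_ns))
    stop("time outside schedule domain [0, ", schedule$total_ns, ")")
  edges <- cumsum(schedule$segments$duration_ns)
  idx <- findInterval(t_ns, c(0, edges), rightmost.closed = FALSE)
  schedule$segments$temperature_K[idx]
}

#' Temperature ladder constructor
#'
#' Convenience builder for the stepwise protocol: a base segment at
#' `base_K`, then rungs raised by `step_K` up to `max_K`, each held for
#' `rung_ns` (the final rung may be given its own duration, e.g. 20 ns at
#' the top temperature).
#'
#' @param base_K base temperature (K), default 303.
#' @param base_ns duration of the base segment (ns), default 32.
#' @param step_K ladder increment (K), default 30.
#' @param max_K top temperature (K), default 390 (so the default ladder is
#'   303, 333, 363, 390 K).
#' @param rung_ns duration of each elevated rung (ns), default 12.
#' @param final_rung_ns duration of the top rung (ns), default 20.
#' @return a [temperature_schedule()].
#' @export
ladder_schedule <- function(base_K = 303, base_ns = 32, step_K = 30,
                            max_K = 390, rung_ns = 12, final_rung_ns = 20) {
  temps <- base_K
  t <- base_K + step_K
  while (t <= max_K + 1e-9) { temps <- c(temps, min(t, max_K)); t <- t + step_K }
  if (max(temps) < max_K) temps <- c(temps, max_K)
  durs <- c(base_ns, rep(rung_ns, length(temps) - 1L))
  if (length(durs) > 1L) durs[length(durs)] <- final_rung_ns
  temperature_schedule(durs, temps)
}

#' @export
print.temperature_schedule <- function(x, ...) {
  cat("temperature_schedule:", nrow(x$segments), "segments,",
      x$total_ns, "ns total\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Read/write a schedule config file
#'
#' The on-disk form is a small YAML document with a `segments` list of
#' `(duration_ns, temperature_K)` pairs.
#'
#' @param path file path.
#' @return `read_schedule` returns a [temperature_schedule()];
#'   `write_schedule` returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$segments) || !length(y$segments))
    stop("schedule file has no segments: ", path)
  d <- vapply(y$segments, function(s) as.numeric(s$duration_ns), numeric(1))
  k <- vapply(y$segments, function(s) as.numeric(s$temperature_K), numeric(1))
  temperature_schedule(d, k)
}

#' @rdname read_schedule
#' @param schedule a [temperature_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  segs <- lapply(seq_len(nrow(schedule$segments)), function(i)
    list(duration_ns = schedule$segments$duration_ns[i],
         temperature_K = schedule$segments$temperature_K[i]))
  yaml::write_yaml(list(segments = segs), path)
  invisible(path)
}
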