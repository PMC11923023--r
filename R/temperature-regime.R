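#' Piecewise-constant temperature schedule
#'
#' A schedule maps simulation time to a temperature label (`"25C"` or
#' `"32C"`) through an ordered list of half-open segments
#' `[start, end)` that tile the season `[0, season_length)` exactly. The
#' half-open convention puts a switch day in the *new* temperature, so
#' lookups are deterministic with no double counting.
#'
#' @param segments Data frame with columns `start`, `end`, `temperature`.
#' @param season_length Season duration in days (default 98, a spider mite
#'   development season).
#' @return A `temperature_schedule` object.
#' @export
temperature_schedule <- function(segments, season_length = 98) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "temperature") %in% names(segments)))
  if (!all(segments$temperature %in% c("25C", "32C")))
    stop("temperature labels must be '25C' or '32C'")
  o <- order(segments$start)
  segments <- segments[o, , drop = FALSE]
  if (any(segments$end <= segments$start))
    stop("segments must have end > start")
  if (segments$start[1] != 0 || segments$end[nrow(segments)] != season_length ||
      (nrow(segments) > 1 &&
       any(abs(segments$start[-1] - segments$end[-nrow(segments)]) > 1e-12)))
    stop("segments must tile [0, season_length) contiguously")
  rownames(segments) <- NULL
  structure(list(segments = segments, season_length = season_length),
            class = "temperature_schedule")
}

#' Constant-temperature schedule
#'
#' @param temp `"25C"` or `"32C"`.
#' @param season Season length in days (> 0).
#' @return A [temperature_schedule()] with a single segment.
#' @export
constant_schedule <- function(temp = c("25C", "32C"), season = 98) {
  temp <- match.arg(temp)
  if (season <= 0) stop("season must be > 0")
  temperature_schedule(
    data.frame(start = 0, end = season, temperature = temp),
    season_length = season
  )
}

#' Repeating-heatwave schedule
#'
#' Alternates `base_weeks` weeks at 25C with `wave_weeks` weeks at 32C,
#' starting at 25C, repeating until the season ends (the final cycle is
#' truncated at the season boundary). A "month" is operationalised as the
#' 4-week cycle `base_weeks + wave_weeks`: a one-week monthly heatwave is
#' `(3, 1)`, a two-week monthly heatwave is `(2, 2)`.
#'
#' @param base_weeks Weeks at 25C per cycle (>= 0).
#' @param wave_weeks Weeks at 32C per cycle (>= 0); `base_weeks +
#'   wave_weeks` must be positive.
#' @param season Season length in days.
#' @return A [temperature_schedule()].
#' @examples
#' sched <- heatwave_schedule(2, 2)   # two-week monthly heatwave
#' temperature_at(15, sched)          # "32C"
#' @export
heatwave_schedule <- function(base_weeks, wave_weeks, season = 98) {
  if (base_weeks < 0 || wave_weeks < 0 || base_weeks + wave_weeks <= 0)
    stop("base_weeks + wave_weeks must be positive, neither negative")
  if (season <= 0) stop("season must be > 0")
  base_d <- base_weeks * 7
  wave_d <- wave_weeks * 7
  starts <- numeric(0); ends <- numeric(0); temps <- character(0)
  t0 <- 0
  while (t0 < season) {
    if (base_d > 0) {
      e <- min(t0 + base_d, season)
      starts <- c(starts, t0); ends <- c(ends, e); temps <- c(temps, "25C")
      t0 <- e
      if (t0 >= season) break
    }
    if (wave_d > 0) {
      e <- min(t0 + wave_d, season)
      starts <- c(starts, t0); ends <- c(ends, e); temps <- c(temps, "32C")
      t0 <- e
    }
  }
  temperature_schedule(
    data.frame(start = starts, end = ends, temperature = temps),
    season_length = season
  )
}

#' Build a schedule from a scenario name
#'
#' The four reference scenarios: constant 25C, constant 32C, a one-week
#' monthly heatwave (`"hw1"`, three weeks 25C then one week 32C, repeating)
#' and a two-week monthly heatwave (`"hw2"`, alternating fortnights).
#'
#' @param scenario One of `"constant25"`, `"constant32"`, `"hw1"`, `"hw2"`.
#' @param season Season length in days.
#' @return A [temperature_schedule()].
#' @export
scenario_schedule <- function(scenario = c("constant25", "constant32",
                                           "hw1", "hw2"),
                              season = 98) {
  scenario <- match.arg(scenario)
  switch(scenario,
         constant25 = constant_schedule("25C", season),
         constant32 = constant_schedule("32C", season),
         hw1 = heatwave_schedule(3, 1, season),
         hw2 = heatwave_schedule(2, 2, season))
}

#' Temperature label active at a time point
#'
#' @param t Time in days; must satisfy `0 <= t < season_length`.
#' @param sched A [temperature_schedule()].
#' @return `"25C"` or `"32C"`.
#' @export
temperature_at <- function(t, sched) {
  stopifnot(inherits(sched, "temperature_schedule"))
  if (t < 0 || t >= sched$season_length)
    stop(sprintf("time %g is outside the season [0, %g)", t,
                 sched$season_length))
  seg <- sched$segments
  i <- which(seg$start <= t & t < seg$end)
  seg$temperature[i[1]]
}

#' Model configuration active at a time point
#'
#' Selects the strain parameter sets matching the schedule's temperature at
#' time `t`; the shared `C` and `b` are temperature-independent.
#'
#' @inheritParams temperature_at
#' @param registry Parameter registry (see [mite_params_registry()]).
#' @return A [model_config()].
#' @export
params_at <- function(t, sched, registry = mite_params_registry()) {
  temp <- temperature_at(t, sched)
  model_config(inducer = registry$inducer[[temp]],
               suppressor = registry$suppressor[[temp]],
               shared = registry$shared)
}
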