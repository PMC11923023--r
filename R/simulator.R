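#' Simulate the two-strain competition over a temperature schedule
#'
#' Integrates [mite_rhs()] segment by segment along the schedule: within a
#' segment the parameters are those of the active temperature, and the
#' state is carried over unchanged across switches. The default initial
#' condition places 90 inducers and 10 suppressors, all as adults
#' (infestations start with mated adult females).
#'
#' Integration uses \pkg{deSolve}'s `lsoda` (adaptive, stiff/non-stiff
#' switching) with tight tolerances; `grid_step` only controls the output
#' grid, not accuracy.
#'
#' @param registry Parameter registry (see [mite_params_registry()]).
#' @param sched A [temperature_schedule()] (default: constant 25C over 98
#'   days).
#' @param init Initial state (see [model_state()]).
#' @param grid_step Output grid spacing in days (default 0.1).
#' @param rtol,atol Solver tolerances.
#' @return A `mite_trajectory`: a data frame with columns `time_day`,
#'   `temperature`, `NI1`, `NI2`, `NS1`, `NS2`, `NI_total`, `NS_total`, and
#'   attributes `schedule` and `registry`.
#' @examples
#' traj <- simulate_mites(sched = scenario_schedule("constant32"))
#' crossover_day(traj)
#' @export
simulate_mites <- function(registry = mite_params_registry(),
                           sched = scenario_schedule("constant25"),
                           init = model_state(NI2 = 90, NS2 = 10),
                           grid_step = 0.1, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(sched, "temperature_schedule"))
  if (grid_step <= 0) stop("grid_step must be > 0")
  if (any(init < 0)) stop("initial state must be non-negative")
  seg <- sched$segments
  y <- init
  rows <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    cfg <- params_at(seg$start[i], sched, registry)
    times <- seq(seg$start[i], seg$end[i], by = grid_step)
    if (times[length(times)] < seg$end[i]) times <- c(times, seg$end[i])
    out <- deSolve::ode(y = y, times = times, func = mite_rhs, parms = cfg,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0)
      stop(sprintf("integration failed in segment %d [%g, %g) at %s",
                   i, seg$start[i], seg$end[i], seg$temperature[i]))
    out <- as.data.frame(out)
    names(out) <- c("time_day", "NI1", "NI2", "NS1", "NS2")
    out$temperature <- seg$temperature[i]
    y <- model_state(NI1 = max(out$NI1[nrow(out)], 0),
                     NI2 = max(out$NI2[nrow(out)], 0),
                     NS1 = max(out$NS1[nrow(out)], 0),
                     NS2 = max(out$NS2[nrow(out)], 0))
    # each switch day appears once, labelled with the new temperature
    # (half-open segments); the state itself is continuous across switches
    rows[[i]] <- if (i == nrow(seg)) out else out[-nrow(out), , drop = FALSE]
  }
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  traj$NI_total <- traj$NI1 + traj$NI2
  traj$NS_total <- traj$NS1 + traj$NS2
  traj <- traj[, c("time_day", "temperature", "NI1", "NI2", "NS1", "NS2",
                   "NI_total", "NS_total")]
  structure(traj, class = c("mite_trajectory", "data.frame"),
            schedule = sched, registry = registry, init = init)
}

#' First day suppressors outnumber inducers
#'
#' Finds the first grid time at which total suppressor density strictly
#' exceeds total inducer density, then refines the crossing between the
#' bracketing grid points by bisection on the ODE itself to 0.01-day
#' precision. Returns `NA` if suppressors never overtake within the season.
#'
#' @param traj A trajectory from [simulate_mites()].
#' @param precision Bisection precision in days (default 0.01).
#' @return Crossover day, or `NA_real_` if none.
#' @export
crossover_day <- function(traj, precision = 0.01) {
  stopifnot(inherits(traj, "mite_trajectory"))
  above <- traj$NS_total > traj$NI_total
  if (!any(above)) return(NA_real_)
  k <- which(above)[1]
  if (k == 1) return(traj$time_day[1])
  sched <- attr(traj, "schedule")
  registry <- attr(traj, "registry")
  lo <- traj$time_day[k - 1]
  hi <- traj$time_day[k]
  y_lo <- model_state(NI1 = traj$NI1[k - 1], NI2 = traj$NI2[k - 1],
                      NS1 = traj$NS1[k - 1], NS2 = traj$NS2[k - 1])
  gap_at <- function(tt) {
    # suppressor minus inducer total at time tt, integrating from (lo, y_lo);
    # grid points of one trajectory never straddle a temperature switch
    cfg <- params_at(lo, sched, registry)
    out <- deSolve::ode(y = y_lo, times = c(lo, tt), func = mite_rhs,
                        parms = cfg, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    st <- out[nrow(out), -1]
    (st[3] + st[4]) - (st[1] + st[2])
  }
  while (hi - lo > precision) {
    mid <- (lo + hi) / 2
    if (gap_at(mid) > 0) hi <- mid else lo <- mid
  }
  hi
}

#' End-of-season persistence of each strain
#'
#' A strain persists if its total density at the final time point is at or
#' above the extinction threshold (default 1 individual/plant). The
#' threshold is a reporting rule only; it never feeds back into the
#' dynamics.
#'
#' @param traj A trajectory from [simulate_mites()].
#' @param threshold Extinction threshold (> 0), individuals/plant.
#' @return Named logical vector `c(inducer = , suppressor = )`.
#' @export
persistence <- function(traj, threshold = 1) {
  stopifnot(inherits(traj, "mite_trajectory"))
  if (threshold <= 0) stop("threshold must be > 0")
  n <- nrow(traj)
  c(inducer = traj$NI_total[n] >= threshold,
    suppressor = traj$NS_total[n] >= threshold)
}

#' Summarise a simulation run
#'
#' @inheritParams persistence
#' @return A list with `crossover_day`, final densities, persistence flags
#'   and the day of the inducer density peak.
#' @export
summarize_trajectory <- function(traj, threshold = 1) {
  stopifnot(inherits(traj, "mite_trajectory"))
  n <- nrow(traj)
  per <- persistence(traj, threshold)
  list(
    crossover_day = crossover_day(traj),
    inducer_final = traj$NI_total[n],
    suppressor_final = traj$NS_total[n],
    inducer_persists = unname(per["inducer"]),
    suppressor_persists = unname(per["suppressor"]),
    peak_inducer_day = traj$time_day[which.max(traj$NI_total)]
  )
}

#' Write a trajectory and its summary to disk
#'
#' @param traj A trajectory from [simulate_mites()].
#' @param path CSV path for the trajectory table.
#' @param summary_path Optional JSON path for [summarize_trajectory()]
#'   output.
#' @param threshold Extinction threshold for the summary.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, summary_path = NULL, threshold = 1) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path)) {
    s <- summarize_trajectory(traj, threshold)
    s$crossover_day <- if (is.na(s$crossover_day)) NULL else s$crossover_day
    jsonlite::write_json(s, summary_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Plot strain densities with the temperature trace
#'
#' Base-graphics two-panel figure: the temperature schedule on top, juvenile
#' (dotted) and adult (solid) densities of each strain below, with the
#' extinction threshold as a grey horizontal line.
#'
#' @param traj A trajectory from [simulate_mites()].
#' @param threshold Extinction threshold to draw (default 1).
#' @param log_y Plot densities on a log axis (default TRUE; the threshold
#'   line is visible that way).
#' @return `traj`, invisibly.
#' @export
plot_trajectory <- function(traj, threshold = 1, log_y = TRUE) {
  stopifnot(inherits(traj, "mite_trajectory"))
  op <- graphics::par(mfrow = c(2, 1), mar = c(0.5, 4, 1, 1), oma = c(4, 0, 0, 0))
  on.exit(graphics::par(op), add = TRUE)
  temp_num <- ifelse(traj$temperature == "32C", 32, 25)
  plot(traj$time_day, temp_num, type = "s", ylim = c(24, 33), xaxt = "n",
       ylab = "Temp (°C)", xlab = "")
  graphics::par(mar = c(4, 4, 0.5, 1))
  eps <- if (log_y) 1e-3 else 0
  ylim <- range(pmax(c(traj$NI1, traj$NI2, traj$NS1, traj$NS2, threshold), eps))
  plot(traj$time_day, pmax(traj$NI2, eps), type = "l", col = "blue",
       log = if (log_y) "y" else "", ylim = ylim,
       xlab = "Time (days)", ylab = "Individuals / plant")
  graphics::lines(traj$time_day, pmax(traj$NI1, eps), col = "blue", lty = 3)
  graphics::lines(traj$time_day, pmax(traj$NS2, eps), col = "darkorange")
  graphics::lines(traj$time_day, pmax(traj$NS1, eps), col = "darkorange", lty = 3)
  graphics::abline(h = threshold, col = "grey")
  graphics::legend("bottomright", bty = "n", col = c("blue", "darkorange"),
                   lty = 1, legend = c("inducer", "suppressor"))
  invisible(traj)
}
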