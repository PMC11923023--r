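# Independent oracles used across tests. These re-derive results by brute
# force (fixed-step Euler, day-by-day scans, scalar loops) and never call
# the code paths they check.

# Fixed-step explicit Euler integration of the two-strain system, with the
# right-hand side written out long-hand. Returns the final state and the
# first step time at which suppressor total exceeded inducer total.
euler_oracle <- function(registry, sched, init = c(0, 90, 0, 10),
                         h = 1e-3, t_end = 98) {
  n_steps <- round(t_end / h)
  step_t <- (seq_len(n_steps) - 1) * h
  seg <- sched$segments
  lab <- seg$temperature[findInterval(step_t, seg$start)]
  C <- registry$shared$C
  b <- registry$shared$b
  y <- as.numeric(init)
  crossed <- NA_real_
  for (k in seq_len(n_steps)) {
    I <- registry$inducer[[lab[k]]]
    S <- registry$suppressor[[lab[k]]]
    dd <- max(0, 1 - (y[1] + y[2] + y[3] + y[4]) / C)
    dy <- c(I$r * dd * b * y[2] - I$v * y[1],
            I$e * y[1] - I$mu * y[2],
            S$r * dd * y[4] - S$v * y[3],
            S$e * y[3] - S$mu * y[4])
    y <- y + h * dy
    if (is.na(crossed) && (y[3] + y[4]) > (y[1] + y[2])) crossed <- k * h
  }
  list(final = y, crossover = crossed)
}

# Scalar, loop-based re-computation of the three leaflet metrics.
metrics_by_row_oracle <- function(df) {
  out <- data.frame(survival = numeric(nrow(df)), eggs = numeric(nrow(df)),
                    damage = numeric(nrow(df)))
  for (i in seq_len(nrow(df))) {
    a <- df$alive_females[i]; d <- df$dead_females[i]
    days <- if (is.null(df$assay_days)) 2 else df$assay_days[i]
    out$survival[i] <- 1 - (d / days) / (d + a)
    out$eggs[i] <- (df$total_eggs[i] / (a + d / 2)) / days
    out$damage[i] <- if (is.na(df$damage_area[i])) NA_real_
                     else df$damage_area[i] / (a + d / 2)
  }
  out
}

# A registry with both strains given identical rates, for symmetry checks.
symmetric_registry <- function(b = 1) {
  p <- function(strain) list(
    `25C` = strain_params(strain, "25C", e = 1 / 12, mu = 0.06, v = 0.3, r = 8.5),
    `32C` = strain_params(strain, "32C", e = 1 / 7.5, mu = 0.15, v = 0.4, r = 12)
  )
  list(inducer = p("inducer"), suppressor = p("suppressor"),
       shared = shared_params(C = 1000, b = b))
}
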