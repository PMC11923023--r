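#' Demographic rate set for one strain at one temperature
#'
#' The four rates driving one strain's stage-structured dynamics:
#' development `e` (1/day, juveniles maturing into adults), adult mortality
#' `mu` (1/day), juvenile mortality `v` (1/day) and maximum net reproduction
#' `r` (offspring per adult per day, already corrected for the proportion of
#' female offspring). A strain is viable (admits a positive single-strain
#' equilibrium) iff `r * e > mu * v`.
#'
#' @param strain `"inducer"` or `"suppressor"`.
#' @param temperature `"25C"` or `"32C"`.
#' @param e,mu,v,r Rates as above; all strictly positive.
#' @return A `strain_params` object.
#' @export
strain_params <- function(strain, temperature, e, mu, v, r) {
  strain <- match.arg(strain, c("inducer", "suppressor"))
  temperature <- match.arg(temperature, c("25C", "32C"))
  vals <- c(e = e, mu = mu, v = v, r = r)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rates must be finite and strictly positive")
  structure(list(strain = strain, temperature = temperature,
                 e = e, mu = mu, v = v, r = r),
            class = "strain_params")
}

#' Shared (temperature-independent) model parameters
#'
#' @param C Carrying capacity: total mite density, both strains and both
#'   stages, at which juvenile production falls to zero (individuals/plant).
#' @param b Benefit multiplier (>= 1) boosting inducer reproduction,
#'   representing the common-good effect of defence suppression on the
#'   shared plant.
#' @return A `shared_params` object.
#' @export
shared_params <- function(C = 1000, b = 1.25) {
  if (!is.finite(C) || C <= 0) stop("C must be > 0")
  if (!is.finite(b) || b < 1) stop("b must be >= 1")
  structure(list(C = C, b = b), class = "shared_params")
}

#' Published demographic rates for both strains at both temperatures
#'
#' The built-in registry of empirically derived rates for the
#' defence-inducing and defence-suppressing strains at 25 and 32 degrees C,
#' together with the shared carrying capacity and inducer benefit
#' multiplier. This registry is the parameter source for all reference
#' simulations; the estimation functions ([development_rate()],
#' [adult_mortality()], ...) exist to process raw observations and are
#' never silently substituted for it.
#'
#' @return A list with elements `inducer` and `suppressor` (each a list with
#'   `25C` and `32C` [strain_params()] entries) and `shared`
#'   ([shared_params()]).
#' @examples
#' reg <- mite_params_registry()
#' reg$suppressor$`32C`$r
#' @export
mite_params_registry <- function() {
  list(
    inducer = list(
      `25C` = strain_params("inducer", "25C", e = 1 / 12.262, mu = 0.062,
                            v = 0.309, r = 8.599),
      `32C` = strain_params("inducer", "32C", e = 1 / 7.465, mu = 0.159,
                            v = 0.414, r = 12.263)
    ),
    suppressor = list(
      `25C` = strain_params("suppressor", "25C", e = 1 / 11.857, mu = 0.0419,
                            v = 0.261, r = 8.186),
      `32C` = strain_params("suppressor", "32C", e = 1 / 7.429, mu = 0.075,
                            v = 0.327, r = 15.798)
    ),
    shared = shared_params(C = 1000, b = 1.25)
  )
}

#' Egg-to-adult development rate from leaf-disc timelines
#'
#' Estimates the per-capita development rate as `1 / mean(days to adult)`
#' over discs whose cohort produced at least one adult (mean-then-invert,
#' matching the `1/days` form in which such rates are reported). Each disc
#' contributes the day its first individual reached adulthood.
#'
#' @param discs Data frame of disc timelines with a `day_adult` column
#'   (NA for discs where no individual reached adulthood), e.g. from
#'   [generate_discs()].
#' @return Development rate in 1/day.
#' @export
development_rate <- function(discs) {
  if (is.null(discs$day_adult)) stop("discs must have a 'day_adult' column")
  d <- discs$day_adult[!is.na(discs$day_adult)]
  if (length(d) == 0) stop("no disc cohort reached adulthood")
  1 / mean(d)
}

#' Adult mortality rate from a daily survival proportion
#'
#' Converts a daily survival proportion into a continuous-time mortality
#' rate. The `"log"` convention (`mu = -log(s)`) is the exact inverse of
#' exponential daily survival and is consistent with use in an ODE; the
#' `"linear"` convention (`mu = 1 - s`) is the first-order approximation.
#' The two agree closely at the high survival levels typical of these
#' assays.
#'
#' @param survival_per_day Daily survival proportion in (0, 1\].
#' @param convention `"log"` (default) or `"linear"`.
#' @return Mortality rate in 1/day (0 iff survival is 1).
#' @export
adult_mortality <- function(survival_per_day, convention = c("log", "linear")) {
  convention <- match.arg(convention)
  if (any(survival_per_day <= 0))
    stop("survival of 0 implies an infinite mortality rate")
  if (any(survival_per_day > 1)) stop("survival must be <= 1")
  switch(convention,
         log = -log(survival_per_day),
         linear = 1 - survival_per_day)
}

#' Daily survival implied by a mortality rate
#'
#' Inverse of [adult_mortality()]; useful for round-tripping rates back to
#' the proportion scale.
#'
#' @param mu Mortality rate (1/day), >= 0.
#' @inheritParams adult_mortality
#' @return Daily survival proportion.
#' @export
survival_from_mortality <- function(mu, convention = c("log", "linear")) {
  convention <- match.arg(convention)
  if (any(mu < 0)) stop("mortality rate must be >= 0")
  switch(convention, log = exp(-mu), linear = 1 - mu)
}

#' Juvenile mortality rate from egg-to-adult survival
#'
#' Spreads the overall probability of surviving the juvenile period over the
#' development duration: `v = -log(p)/dev_days` (log convention) or
#' `v = (1 - p)/dev_days` (linear per-day).
#'
#' @param p_survive_to_adult Proportion of eggs surviving to adulthood,
#'   in (0, 1\].
#' @param dev_days Development duration in days (> 0).
#' @param convention `"log"` (default) or `"linear"`.
#' @return Juvenile mortality rate in 1/day.
#' @export
juvenile_mortality <- function(p_survive_to_adult, dev_days,
                               convention = c("log", "linear")) {
  convention <- match.arg(convention)
  if (any(p_survive_to_adult <= 0))
    stop("survival of 0 implies an infinite mortality rate")
  if (any(p_survive_to_adult > 1)) stop("survival must be <= 1")
  if (any(dev_days <= 0)) stop("dev_days must be > 0")
  switch(convention,
         log = -log(p_survive_to_adult) / dev_days,
         linear = (1 - p_survive_to_adult) / dev_days)
}

#' Sex-ratio-corrected net reproduction rate
#'
#' Multiplies daily per-female fecundity by the proportion of female
#' offspring, giving the rate at which adults produce daughters (the `r`
#' entering the competition model).
#'
#' @param fecundity_per_day Eggs per female per day (>= 0).
#' @param prop_female Proportion of female offspring in \[0, 1\].
#' @return Net reproduction in offspring/adult/day.
#' @export
net_reproduction <- function(fecundity_per_day, prop_female) {
  if (any(fecundity_per_day < 0)) stop("fecundity must be >= 0")
  if (any(prop_female < 0 | prop_female > 1))
    stop("prop_female must be in [0, 1]")
  fecundity_per_day * prop_female
}

#' Generation time from disc timelines (descriptive)
#'
#' Mean days from egg to the cohort's first F1 egg. Reported as a
#' descriptive statistic only; the competition model does not use it.
#'
#' @inheritParams development_rate
#' @return Mean generation time in days.
#' @export
generation_time <- function(discs) {
  if (is.null(discs$day_first_egg)) stop("discs must have a 'day_first_egg' column")
  d <- discs$day_first_egg[!is.na(discs$day_first_egg)]
  if (length(d) == 0) stop("no disc cohort reached first oviposition")
  mean(d)
}

#' Estimate a full strain x temperature rate set from raw observations
#'
#' Convenience wrapper chaining the assay metrics and rate conversions:
#' daily survival and fecundity come from the leaflet table, development
#' rate and sex ratio from the disc table.
#'
#' @param leaflets Leaflet data frame (see [compute_leaflet_metrics()]).
#' @param discs Disc data frame (see [development_rate()]); must also carry
#'   `n_females`, `n_males` and `n_eggs`, `n_died` columns.
#' @param strain,temperature Labels for the resulting [strain_params()].
#' @param convention Mortality convention passed to [adult_mortality()] and
#'   [juvenile_mortality()].
#' @return A [strain_params()] object.
#' @export
estimate_strain_params <- function(leaflets, discs, strain, temperature,
                                   convention = c("log", "linear")) {
  convention <- match.arg(convention)
  m <- compute_leaflet_metrics(leaflets)
  s <- mean(m$survival_per_day)
  fec <- mean(m$eggs_per_female_day)
  e <- development_rate(discs)
  p_adult <- 1 - sum(discs$n_died) / sum(discs$n_eggs)
  if (p_adult <= 0) stop("no juveniles survived to adulthood")
  pf <- sum(discs$n_females) / (sum(discs$n_females) + sum(discs$n_males))
  strain_params(strain, temperature,
                e = e,
                mu = adult_mortality(s, convention),
                v = juvenile_mortality(p_adult, 1 / e, convention),
                r = net_reproduction(fec, pf))
}

#' Write / read a parameter registry as YAML
#'
#' Serialises a registry (as returned by [mite_params_registry()] or built
#' from [estimate_strain_params()] results) to a YAML file with per-strain,
#' per-temperature rate blocks plus the shared `C` and `b`, and reads it
#' back.
#'
#' @param registry Registry list (see [mite_params_registry()]).
#' @param path File path.
#' @return `read_params_yaml()` returns a registry list; `write_params_yaml()`
#'   returns `path` invisibly.
#' @export
write_params_yaml <- function(registry, path) {
  as_plain <- function(p) list(e = p$e, mu = p$mu, v = p$v, r = p$r)
  out <- list(
    inducer = lapply(registry$inducer, as_plain),
    suppressor = lapply(registry$suppressor, as_plain),
    shared = list(C = registry$shared$C, b = registry$shared$b)
  )
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(strain) {
    temps <- names(raw[[strain]])
    stats::setNames(lapply(temps, function(tmp) {
      p <- raw[[strain]][[tmp]]
      strain_params(strain, tmp, e = p$e, mu = p$mu, v = p$v, r = p$r)
    }), temps)
  }
  list(inducer = build("inducer"), suppressor = build("suppressor"),
       shared = shared_params(C = raw$shared$C, b = raw$shared$b))
}
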