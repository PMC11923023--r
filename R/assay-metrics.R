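#' Leaflet assay record
#'
#' Bundles the end-of-assay tallies for one infested leaflet: numbers of
#' alive and dead adult females, total eggs laid, and (optionally) the
#' chlorotic damage area. These are the raw quantities entering the
#' mortality-corrected per-capita metrics ([female_survival_per_day()],
#' [eggs_per_alive_female_per_day()], [damage_per_alive_female()]).
#'
#' The metrics credit each dead female with half the assay duration of
#' exposure, on the reasoning that deaths are only observed at the end of
#' the assay and, under constant daily mortality, a female that died was
#' alive for about half the assay on average.
#'
#' @param alive_females Number of females alive at the end of the assay.
#' @param dead_females Number of females found dead at the end of the assay.
#' @param total_eggs Total eggs counted on the leaflet.
#' @param damage_area Chlorotic damage area in mm^2, or `NA` if the leaflet
#'   was not photographed.
#' @param assay_days Assay duration in days (default 2, the standard
#'   infestation window). Must be >= 1.
#' @param block_id,treatment Optional labels (temporal block, strain x
#'   temperature treatment).
#' @return An object of class `leaflet_counts` (a named list).
#' @examples
#' lc <- leaflet_counts(alive_females = 10, dead_females = 4, total_eggs = 60)
#' female_survival_per_day(lc)
#' eggs_per_alive_female_per_day(lc)
#' @export
leaflet_counts <- function(alive_females, dead_females, total_eggs,
                           damage_area = NA_real_, assay_days = 2,
                           block_id = NA_character_, treatment = NA_character_) {
  stopifnot(length(alive_females) == 1, length(dead_females) == 1,
            length(total_eggs) == 1, length(assay_days) == 1)
  if (alive_females < 0 || dead_females < 0 || total_eggs < 0)
    stop("counts must be non-negative")
  if (alive_females + dead_females == 0)
    stop("empty leaflet: alive_females + dead_females must be > 0")
  if (!is.na(damage_area) && damage_area < 0)
    stop("damage_area must be >= 0")
  if (!is.finite(assay_days) || assay_days < 1)
    stop("assay_days must be >= 1 (per-day survival is ill-defined for shorter assays)")
  structure(list(alive_females = alive_females, dead_females = dead_females,
                 total_eggs = total_eggs, damage_area = as.numeric(damage_area),
                 assay_days = assay_days, block_id = block_id,
                 treatment = treatment),
            class = "leaflet_counts")
}

#' Daily female survival, corrected for when deaths occurred
#'
#' Proportion of females surviving per day on one leaflet:
#' `1 - (dead / assay_days) / (dead + alive)`. Spreading the observed deaths
#' evenly over the assay turns an end-point count into a daily rate.
#'
#' @param c A [leaflet_counts()] record.
#' @return Survival proportion per day, in \[0, 1\].
#' @export
female_survival_per_day <- function(c) {
  stopifnot(inherits(c, "leaflet_counts"))
  total <- c$alive_females + c$dead_females
  if (total == 0) stop("empty leaflet: no females observed")
  1 - (c$dead_females / c$assay_days) / total
}

#' Eggs per alive female per day
#'
#' Per-capita daily fecundity with mortality correction: total eggs divided
#' by the effective number of females (`alive + dead/2`, dead females
#' contribute half the assay), divided by the assay duration.
#'
#' @inheritParams female_survival_per_day
#' @return Offspring per female per day (>= 0).
#' @export
eggs_per_alive_female_per_day <- function(c) {
  stopifnot(inherits(c, "leaflet_counts"))
  eff <- c$alive_females + c$dead_females / 2
  if (eff <= 0) stop("effective female count is zero")
  (c$total_eggs / eff) / c$assay_days
}

#' Damage area per alive female
#'
#' Chlorotic feeding damage per female over the whole assay, with the same
#' mortality correction as [eggs_per_alive_female_per_day()]. Note this is
#' per assay, not per day.
#'
#' @inheritParams female_survival_per_day
#' @return Damage area in mm^2 per female.
#' @export
damage_per_alive_female <- function(c) {
  stopifnot(inherits(c, "leaflet_counts"))
  if (is.na(c$damage_area))
    stop("damage_area is missing for this leaflet (only a subset is photographed)")
  eff <- c$alive_females + c$dead_females / 2
  if (eff <= 0) stop("effective female count is zero")
  c$damage_area / eff
}

#' Pixel-to-mm^2 damage calibration
#'
#' Image areas are calibrated by measuring the length of an adult mite in
#' pixels; the physical mite length (abdomen tip to mouth parts) is 0.4 mm.
#'
#' @param mite_length_px Measured mite length in pixels for the image.
#' @param mite_length_mm Physical mite length in mm (default 0.4).
#' @return A `damage_calibration` object.
#' @export
damage_calibration <- function(mite_length_px, mite_length_mm = 0.4) {
  if (!is.finite(mite_length_px) || mite_length_px <= 0 ||
      !is.finite(mite_length_mm) || mite_length_mm <= 0)
    stop("calibration lengths must be strictly positive")
  structure(list(mite_length_px = mite_length_px,
                 mite_length_mm = mite_length_mm),
            class = "damage_calibration")
}

#' Convert a pixel area to mm^2
#'
#' @param area_px Area in pixels^2 (vectorised).
#' @param cal A [damage_calibration()] object.
#' @return Area in mm^2.
#' @examples
#' px_to_mm2(2500, damage_calibration(mite_length_px = 50))  # 0.16
#' @export
px_to_mm2 <- function(area_px, cal) {
  stopifnot(inherits(cal, "damage_calibration"))
  if (any(area_px < 0, na.rm = TRUE)) stop("pixel areas must be >= 0")
  area_px * (cal$mite_length_mm / cal$mite_length_px)^2
}

#' Normalized gene expression from cycle thresholds
#'
#' Delta-Ct normalisation of a qPCR measurement against a housekeeping gene:
#' `base^(ct_housekeeping - ct_target)`. The default base of 2 assumes
#' perfect per-cycle doubling; supply the measured amplification efficiency
#' (e.g. 1.94) to override.
#'
#' @param ct_target,ct_housekeeping Cycle-threshold values (vectorised).
#' @param efficiency_base Amplification base, > 1 (default 2).
#' @return Normalized expression (dimensionless, > 0).
#' @export
normalized_expression <- function(ct_target, ct_housekeeping,
                                  efficiency_base = 2) {
  if (!is.finite(efficiency_base) || efficiency_base <= 1)
    stop("efficiency_base must be > 1")
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_housekeeping)))
    stop("cycle thresholds must be finite")
  if (any(ct_target <= 0) || any(ct_housekeeping <= 0))
    stop("cycle thresholds must be positive")
  efficiency_base^(ct_housekeeping - ct_target)
}

#' Scale expression values per gene to the lowest group mean
#'
#' Within each gene, divides every normalized-expression value by the
#' smallest group mean, so the lowest-expressing group has scaled mean
#' exactly 1 and other groups read as fold changes relative to it.
#'
#' @param values Numeric vector of normalized expression values.
#' @param gene Gene label per value.
#' @param group Experimental group label per value.
#' @return Numeric vector of scaled values, same order as the input.
#' @export
scale_to_lowest_group_mean <- function(values, gene, group) {
  stopifnot(length(values) == length(gene), length(values) == length(group))
  out <- numeric(length(values))
  for (g in unique(gene)) {
    idx <- gene == g
    gm <- tapply(values[idx], group[idx], mean)
    m <- min(gm)
    if (!is.finite(m) || m <= 0)
      stop(sprintf("gene '%s': minimum group mean is not positive", g))
    out[idx] <- values[idx] / m
  }
  out
}

#' Compute the per-capita metrics for a table of leaflets
#'
#' Applies [female_survival_per_day()], [eggs_per_alive_female_per_day()]
#' and [damage_per_alive_female()] to every row of a leaflet table. Rows
#' with a missing `damage_area` get `NA` for `damage_per_female`; the other
#' two metrics are always computed.
#'
#' @param df Data frame with columns `alive_females`, `dead_females`,
#'   `total_eggs`, and optionally `damage_area` (NA allowed) and
#'   `assay_days` (default 2 if absent).
#' @return The input data frame with columns `survival_per_day`,
#'   `eggs_per_female_day` and `damage_per_female` appended.
#' @export
compute_leaflet_metrics <- function(df) {
  req <- c("alive_females", "dead_females", "total_eggs")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(df$assay_days)) df$assay_days <- 2
  if (is.null(df$damage_area)) df$damage_area <- NA_real_
  total <- df$alive_females + df$dead_females
  if (any(total == 0)) stop("empty leaflet row(s): no females observed")
  if (any(df$assay_days < 1)) stop("assay_days must be >= 1 in every row")
  eff <- df$alive_females + df$dead_females / 2
  df$survival_per_day <- 1 - (df$dead_females / df$assay_days) / total
  df$eggs_per_female_day <- (df$total_eggs / eff) / df$assay_days
  df$damage_per_female <- ifelse(is.na(df$damage_area), NA_real_,
                                 df$damage_area / eff)
  df
}

#' Read / write leaflet tables
#'
#' CSV with one row per leaflet and columns `block_id`, `treatment`,
#' `alive_females`, `dead_females`, `total_eggs`, `damage_area` (may be
#' empty), `assay_days`.
#'
#' @param path File path.
#' @return `read_leaflets()` returns a data frame.
#' @export
read_leaflets <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_leaflets
#' @param df Leaflet data frame (typically from [compute_leaflet_metrics()]).
#' @export
write_leaflets <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
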