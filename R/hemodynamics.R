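#' Hydraulic resistance from pressure drop and flow
#'
#' `R = dP / Q` in mmHg.min/mL, the standard clinical definition for
#' oxygenators. Vectorised.
#'
#' @param dp_mmhg Pressure drop across the device, mmHg.
#' @param q_ml_min Flow rate, mL/min; must be positive.
#' @return Resistance in mmHg.min/mL.
#' @examples
#' resistance(1.60, 4.38)
#' @export
resistance <- function(dp_mmhg, q_ml_min) {
  if (any(q_ml_min <= 0)) stop("`q_ml_min` must be positive", call. = FALSE)
  dp_mmhg / q_ml_min
}

#' Natural log of resistance for a series
#'
#' Adds (or recomputes) the `ln_resistance` column of a resistance series,
#' the scale on which resistance trajectories are compared.
#'
#' @param series A data frame with a `resistance` column (all positive).
#' @return The series with `ln_resistance` set.
#' @export
ln_resistance <- function(series) {
  stopifnot(is.data.frame(series), "resistance" %in% names(series))
  if (any(series$resistance <= 0)) {
    stop("resistance must be positive to take logs", call. = FALSE)
  }
  dplyr::mutate(series, ln_resistance = log(.data$resistance))
}

#' Flag time points whose resistance exceeds the clot-free baseline
#'
#' Resistances strictly above the glycerol-water baseline indicate clot
#' formation; the baseline itself is clot-free, so the comparison is
#' strict.
#'
#' @param series A data frame with a `resistance` column.
#' @param r0 Baseline resistance, mmHg.min/mL (positive).
#' @return The series with a logical `above_baseline` column.
#' @export
excess_over_baseline <- function(series, r0) {
  stopifnot(is.data.frame(series), "resistance" %in% names(series), r0 > 0)
  dplyr::mutate(series, above_baseline = .data$resistance > r0)
}

#' Ratio of two resistances
#'
#' @param r_a,r_b Resistances; `r_b` must be positive.
#' @return `r_a / r_b`.
#' @examples
#' baseline_ratio(0.615, 0.365) # 4 cm vs 2 cm path length at 50% packing
#' @export
baseline_ratio <- function(r_a, r_b) {
  if (any(r_b <= 0)) stop("`r_b` must be positive", call. = FALSE)
  r_a / r_b
}

#' Clot-free baseline resistance fixtures
#'
#' Measured glycerol-water baseline resistances of the studied chambers
#' (mmHg.min/mL): 0.333, 0.365 and 0.379 for 40/50/60% packing at 2 cm
#' path length, and 0.615 for 50% packing at 4 cm. These are measured
#' constants shipped for tests and simulator calibration, not computed
#' from geometry.
#'
#' @param pd Packing density fraction (0.4, 0.5 or 0.6). If `NULL`, the
#'   full fixture table is returned.
#' @param path_length_cm Path length in cm (2 or 4).
#' @return A single resistance, or the full tibble when `pd` is `NULL`.
#' @examples
#' baseline_resistance(0.5, 2)
#' baseline_resistance()
#' @export
baseline_resistance <- function(pd = NULL, path_length_cm = 2) {
  tbl <- tibble::tibble(
    pd = c(0.4, 0.5, 0.6, 0.5),
    path_length_cm = c(2, 2, 2, 4),
    r0_mmhg_min_ml = c(0.333, 0.365, 0.379, 0.615),
    r0_sd = c(0.003, 0.008, 0.005, 0.010)
  )
  if (is.null(pd)) {
    return(tbl)
  }
  hit <- tbl[abs(tbl$pd - pd) < 1e-9 &
    abs(tbl$path_length_cm - path_length_cm) < 1e-9, ]
  if (nrow(hit) != 1) {
    stop(sprintf(
      "no baseline fixture for pd = %g, path length = %g cm",
      pd, path_length_cm
    ), call. = FALSE)
  }
  hit$r0_mmhg_min_ml
}

# Baseline resistance for arbitrary geometry: exact fixture when the
# chamber matches a studied condition, otherwise linear interpolation in
# packing density (clamped to the studied range) and linear scaling in
# path length anchored at the measured 2 cm and 4 cm points.
default_baseline_r0 <- function(pd, path_length_mm) {
  tbl <- baseline_resistance()
  hit <- tbl[abs(tbl$pd - pd) < 1e-9 &
    abs(tbl$path_length_cm * 10 - path_length_mm) < 1e-9, ]
  if (nrow(hit) == 1) {
    return(hit$r0_mmhg_min_ml)
  }
  two_cm <- tbl[tbl$path_length_cm == 2, ]
  r_pd <- stats::approx(two_cm$pd, two_cm$r0_mmhg_min_ml,
    xout = min(max(pd, 0.4), 0.6)
  )$y
  # R(L) fitted through the measured (20 mm, 0.365) and (40 mm, 0.615)
  # points at 50% packing: slope 0.0125 per mm, intercept 0.115
  r_pd * (0.115 + 0.0125 * path_length_mm) / 0.365
}

#' Build a resistance series from pressure and flow measurements
#'
#' Assembles time-stamped pressure-drop and flow measurements into the
#' standard series form with resistance and ln-resistance columns.
#'
#' @param time_min Measurement times, minutes (strictly increasing).
#' @param dp_mmhg Pressure drops, mmHg.
#' @param q_ml_min Flow rates, mL/min (positive).
#' @param baseline_r0 Optional clot-free baseline resistance to attach.
#' @return A `resistance_series` tibble.
#' @export
resistance_series <- function(time_min, dp_mmhg, q_ml_min,
                              baseline_r0 = NULL) {
  stopifnot(length(time_min) == length(dp_mmhg))
  if (any(diff(time_min) <= 0)) {
    stop("`time_min` must be strictly increasing", call. = FALSE)
  }
  res <- resistance(dp_mmhg, q_ml_min)
  out <- tibble::tibble(
    time_min = time_min,
    q_ml_min = q_ml_min,
    dp_mmhg = dp_mmhg,
    resistance = res,
    ln_resistance = log(res)
  )
  attr(out, "baseline_r0") <- baseline_r0
  class(out) <- c("resistance_series", class(out))
  out
}
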