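#' Define a rod-array flow chamber
#'
#' A chamber is a rectangular duct of width `width_mm` (x), height
#' `height_mm` (y, the rod axis) and path length `path_length_mm` (z, the
#' flow axis) containing an even array of vertical rods of diameter
#' `fiber_um` that stand in for the hollow fibers of an oxygenator bundle.
#' The packing density `pd` is the areal fraction of the plan (x-z) region
#' covered by rod cross-sections.
#'
#' @param pd Packing density, a fraction in (0, 1). For a square lattice the
#'   circle-packing bound requires `pd < pi/4`.
#' @param path_length_mm Path length from inlet face to outlet face, mm.
#' @param width_mm Chamber width, mm.
#' @param height_mm Chamber height (rod length), mm.
#' @param fiber_um Rod (fiber) diameter, micrometres.
#' @param lattice Rod arrangement, `"square"` (default) or `"hexagonal"`.
#' @return An object of class `chamber_spec`.
#' @examples
#' chamber_spec(pd = 0.5, path_length_mm = 20)
#' @export
chamber_spec <- function(pd = 0.5, path_length_mm = 20, width_mm = 7.3,
                         height_mm = 3, fiber_um = 380,
                         lattice = c("square", "hexagonal")) {
  lattice <- match.arg(lattice)
  stopifnot(is.numeric(pd), length(pd) == 1L, is.finite(pd))
  if (pd <= 0 || pd >= 1) {
    stop("`pd` must be a fraction strictly between 0 and 1", call. = FALSE)
  }
  bound <- if (lattice == "square") pi / 4 else pi / (2 * sqrt(3))
  if (pd >= bound) {
    stop(sprintf(
      "infeasible packing: pd = %.3f exceeds the %s-lattice bound %.4f",
      pd, lattice, bound
    ), call. = FALSE)
  }
  if (any(c(width_mm, height_mm, path_length_mm, fiber_um) <= 0)) {
    stop("all chamber dimensions must be positive", call. = FALSE)
  }
  structure(
    list(
      width_mm = width_mm, height_mm = height_mm,
      path_length_mm = path_length_mm, pd = pd,
      fiber_um = fiber_um, lattice = lattice
    ),
    class = "chamber_spec"
  )
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf(
    "<chamber_spec> %.1f x %.1f x %.1f mm (W x H x L), PD %.0f%%, %g um rods, %s lattice\n",
    x$width_mm, x$height_mm, x$path_length_mm, 100 * x$pd, x$fiber_um,
    x$lattice
  ))
  invisible(x)
}

#' Frontal area of a chamber
#'
#' Cross-section perpendicular to flow, `W x H`, in mm^2.
#'
#' @param spec A [chamber_spec()].
#' @return Frontal area in mm^2.
#' @export
frontal_area <- function(spec) {
  stopifnot(inherits(spec, "chamber_spec"))
  spec$width_mm * spec$height_mm
}

#' Define a flow condition
#'
#' Either the superficial velocity `u_cm_min` or the flow rate `q_ml_min`
#' may be given; the missing one is derived from the chamber frontal area.
#' The superficial convention is `Q = u * W * H`. If both are given they
#' must be consistent to 0.5%.
#'
#' @param u_cm_min Superficial velocity, cm/min.
#' @param spec A [chamber_spec()] (needed to convert between Q and u).
#' @param q_ml_min Flow rate, mL/min.
#' @param viscosity_cp Dynamic viscosity, centipoise.
#' @param density_g_ml Fluid density, g/mL.
#' @return An object of class `flow_condition` with both `u_cm_min` and
#'   `q_ml_min` populated.
#' @examples
#' flow_condition(u_cm_min = 20, spec = chamber_spec())
#' @export
flow_condition <- function(u_cm_min = NULL, spec = chamber_spec(),
                           q_ml_min = NULL, viscosity_cp = 3.4,
                           density_g_ml = 1.09) {
  stopifnot(inherits(spec, "chamber_spec"))
  if (viscosity_cp <= 0 || density_g_ml <= 0) {
    stop("viscosity and density must be positive", call. = FALSE)
  }
  if (is.null(u_cm_min) && is.null(q_ml_min)) {
    stop("supply `u_cm_min` or `q_ml_min`", call. = FALSE)
  }
  a_cm2 <- frontal_area(spec) / 100 # mm^2 -> cm^2
  if (is.null(q_ml_min)) q_ml_min <- u_cm_min * a_cm2
  if (is.null(u_cm_min)) u_cm_min <- q_ml_min / a_cm2
  if (abs(q_ml_min - u_cm_min * a_cm2) > 0.005 * max(q_ml_min, 1e-12)) {
    stop("`q_ml_min` and `u_cm_min` disagree by more than 0.5%",
      call. = FALSE
    )
  }
  structure(
    list(
      u_cm_min = u_cm_min, q_ml_min = q_ml_min,
      viscosity_cp = viscosity_cp, density_g_ml = density_g_ml
    ),
    class = "flow_condition"
  )
}

#' @export
print.flow_condition <- function(x, ...) {
  cat(sprintf(
    "<flow_condition> u = %g cm/min, Q = %.3f mL/min, mu = %g cP, rho = %g g/mL\n",
    x$u_cm_min, x$q_ml_min, x$viscosity_cp, x$density_g_ml
  ))
  invisible(x)
}

#' Lay out the rod array for a chamber
#'
#' Places rod centres on an even lattice over the `W x L` plan region so
#' that the areal fraction covered by rod cross-sections equals the spec's
#' packing density. For a square lattice the spacing is
#' `s = d_f * sqrt(pi / (4 * PD))`; for a hexagonal lattice
#' `s = d_f * sqrt(pi / (2 * sqrt(3) * PD))` with rows `s * sqrt(3) / 2`
#' apart and alternate rows offset by `s / 2`. Rods whose circles cross the
#' chamber boundary are kept; the voxelizer clips them.
#'
#' @param spec A [chamber_spec()].
#' @return A `rod_array` object: a tibble of centres (`x_mm`, `z_mm`) plus
#'   attributes `radius_mm`, `spacing_mm` and the originating spec.
#' @examples
#' build_rod_array(chamber_spec(pd = 0.5, path_length_mm = 4))
#' @export
build_rod_array <- function(spec) {
  stopifnot(inherits(spec, "chamber_spec"))
  d_mm <- spec$fiber_um / 1000
  if (spec$lattice == "square") {
    s <- d_mm * sqrt(pi / (4 * spec$pd))
    xs <- seq(s / 2, spec$width_mm, by = s)
    zs <- seq(s / 2, spec$path_length_mm, by = s)
    centers <- tidyr::expand_grid(x_mm = xs, z_mm = zs)
  } else {
    s <- d_mm * sqrt(pi / (2 * sqrt(3) * spec$pd))
    row_h <- s * sqrt(3) / 2
    zs <- seq(row_h / 2, spec$path_length_mm, by = row_h)
    centers <- purrr::map_dfr(seq_along(zs), function(i) {
      off <- if (i %% 2 == 0) s / 2 else 0
      tibble::tibble(x_mm = seq(s / 2 + off, spec$width_mm, by = s), z_mm = zs[i])
    })
  }
  structure(
    centers,
    class = c("rod_array", class(centers)),
    radius_mm = d_mm / 2, spacing_mm = s, spec = spec
  )
}

#' Convert a superficial velocity to a flow rate
#'
#' `Q = u * W * H`: the stated chamber velocities are superficial, i.e.
#' flow rate divided by the full frontal area (20 cm/min through the
#' 7.3 x 3 mm chamber is 4.38 mL/min).
#'
#' @param u_cm_min Superficial velocity, cm/min.
#' @param spec A [chamber_spec()].
#' @return Flow rate in mL/min.
#' @export
flow_rate_for_velocity <- function(u_cm_min, spec = chamber_spec()) {
  stopifnot(inherits(spec, "chamber_spec"), u_cm_min >= 0)
  u_cm_min * frontal_area(spec) / 100
}

#' Interstitial velocity in the rod array
#'
#' The mean velocity in the void space, `u_s / (1 - PD)`.
#'
#' @param u_cm_min Superficial velocity, cm/min.
#' @param pd Packing density fraction in `[0, 1)`.
#' @return Interstitial velocity, cm/min.
#' @export
interstitial_velocity <- function(u_cm_min, pd) {
  if (any(pd < 0 | pd >= 1)) stop("`pd` must be in [0, 1)", call. = FALSE)
  u_cm_min / (1 - pd)
}

#' Hydraulic diameter of an infinite rod bundle
#'
#' `D_h = 4 * void volume / wetted rod surface = d_f * (1 - PD) / PD`,
#' chamber walls excluded.
#'
#' @param spec A [chamber_spec()].
#' @return Hydraulic diameter in mm.
#' @export
hydraulic_diameter <- function(spec) {
  stopifnot(inherits(spec, "chamber_spec"))
  (spec$fiber_um / 1000) * (1 - spec$pd) / spec$pd
}

#' Reynolds number
#'
#' `Re = rho * u * D_h / mu`, evaluated in SI units. Inputs are accepted in
#' the package's working units (g/mL, cm/min, mm, cP) and converted
#' internally.
#'
#' @param density_g_ml Fluid density, g/mL.
#' @param u_cm_min Velocity, cm/min.
#' @param dh_mm Hydraulic diameter, mm.
#' @param viscosity_cp Dynamic viscosity, cP.
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(density_g_ml, u_cm_min, dh_mm, viscosity_cp) {
  stopifnot(density_g_ml > 0, u_cm_min >= 0, dh_mm > 0, viscosity_cp > 0)
  rho <- density_g_ml * 1000 # kg/m^3
  u <- u_cm_min / 100 / 60 # m/s
  dh <- dh_mm / 1000 # m
  mu <- viscosity_cp / 1000 # Pa s
  rho * u * dh / mu
}

#' Cumulative fiber surface area from the inlet
#'
#' Rod lateral surface between the inlet face and depth `z`:
#' `S(z) = 4 * PD * W * H * z / d_f` (walls excluded). Each rod contributes
#' `pi * d_f * H`, and there are `PD * W * z / (pi * d_f^2 / 4)` rods per
#' unit plan area, giving the closed form.
#'
#' @param spec A [chamber_spec()].
#' @param z_mm Depth from the inlet, mm, in `[0, L]`. Vectorised.
#' @return Cumulative surface area in mm^2.
#' @export
cumulative_surface_area <- function(spec, z_mm) {
  stopifnot(inherits(spec, "chamber_spec"))
  if (any(z_mm < 0 | z_mm > spec$path_length_mm)) {
    stop("`z_mm` must lie within [0, path length]", call. = FALSE)
  }
  4 * spec$pd * spec$width_mm * spec$height_mm * z_mm / (spec$fiber_um / 1000)
}

# Published equivalent distances: one row per (u, PD) condition studied.
equivalent_distance_table <- function() {
  tibble::tibble(
    u_cm_min = c(16, 20, 25, 20, 20),
    pd = c(0.5, 0.5, 0.5, 0.4, 0.6),
    distance_mm = c(6.8, 5.7, 4.5, 10.0, 3.2)
  )
}

#' Equivalent distances from the inlet for surface-area-fair comparison
#'
#' Depth from the inlet at which blood under each condition has encountered
#' a matched fiber surface exposure, so clot volumes can be compared fairly
#' across velocities or packing densities. `criterion = "paper_table"`
#' (default) returns the published distances for the five studied
#' conditions: 6.8 / 5.7 / 4.5 mm for 16 / 20 / 25 cm/min at 50% packing,
#' and 10.0 / 5.7 / 3.2 mm for 40 / 50 / 60% packing at 20 cm/min.
#' `criterion = "equal_cumulative_surface"` instead solves for the depth at
#' which cumulative surface per unit flow, `S(d) / Q`, matches the
#' reference condition (20 cm/min, 50% packing, 5.7 mm):
#' `d = 5.7 * (0.5 / PD) * (Q / Q_ref)`. The analytic rule does not
#' reproduce the published distances (see the methods vignette).
#'
#' @param conditions A data frame with columns `u_cm_min` and `pd`, one row
#'   per condition.
#' @param criterion `"paper_table"` or `"equal_cumulative_surface"`.
#' @param spec Chamber spec used for the analytic criterion.
#' @return The input tibble with a `distance_mm` column appended.
#' @examples
#' equivalent_distance(data.frame(u_cm_min = 20, pd = 0.4))
#' @export
equivalent_distance <- function(conditions,
                                criterion = c(
                                  "paper_table",
                                  "equal_cumulative_surface"
                                ),
                                spec = chamber_spec()) {
  criterion <- match.arg(criterion)
  stopifnot(is.data.frame(conditions), all(c("u_cm_min", "pd") %in% names(conditions)))
  conditions <- tibble::as_tibble(conditions)
  if (criterion == "paper_table") {
    out <- dplyr::left_join(conditions, equivalent_distance_table(),
      by = c("u_cm_min", "pd")
    )
    if (anyNA(out$distance_mm)) {
      bad <- out[is.na(out$distance_mm), c("u_cm_min", "pd")]
      stop(sprintf(
        "no published equivalent distance for condition(s): %s",
        paste(sprintf("(%g cm/min, %g%%)", bad$u_cm_min, 100 * bad$pd),
          collapse = ", "
        )
      ), call. = FALSE)
    }
    return(out)
  }
  ref <- list(u = 20, pd = 0.5, d = 5.7)
  # Equal S(d)/Q: S ~ PD * d, Q ~ u, so d = d_ref * (PD_ref/PD) * (u/u_ref).
  dplyr::mutate(
    conditions,
    distance_mm = ref$d * (ref$pd / .data$pd) * (.data$u_cm_min / ref$u)
  )
}
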