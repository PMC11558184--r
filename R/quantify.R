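#' Segment a grayscale volume into a solid-or-clot mask
#'
#' `otsu_two_stage` separates fluid from everything denser (clot + rods):
#' the global intensity histogram of a clotted scan is three-class
#' (fluid, clot, solid), so two thresholds are found by maximising the
#' three-class between-class variance (multi-level Otsu over 256 bins)
#' and the mask keeps everything above the lower one. The clot itself is
#' isolated afterwards by clean-mask subtraction ([subtract_mask()]) —
#' the second stage. `fixed` thresholds at a supplied intensity.
#'
#' @param gray A grayscale [voxel_volume()] with intensities in `[0, 1]`.
#' @param method `"otsu_two_stage"` (default) or `"fixed"`.
#' @param threshold Threshold intensity for `method = "fixed"`.
#' @return A binary [voxel_volume()] marking solid-or-clot.
#' @export
segment_volume <- function(gray, method = c("otsu_two_stage", "fixed"),
                           threshold = 0.4) {
  method <- match.arg(method)
  stopifnot(inherits(gray, "voxel_volume"))
  v <- gray$grid
  if (min(v) < 0 || max(v) > 1) {
    stop("grayscale intensities must lie in [0, 1]", call. = FALSE)
  }
  if (method == "otsu_two_stage") {
    if (stats::var(as.vector(v)) == 0) {
      stop("flat image: cannot segment a zero-variance volume", call. = FALSE)
    }
    threshold <- otsu_thresholds(as.vector(v))[1]
  }
  out <- voxel_volume(array(v > threshold, dim(v)), gray$voxel_um, gray$origin_mm)
  out$spec <- gray$spec
  out
}

# Two-threshold (three-class) Otsu on the global histogram: returns the
# pair (t_low, t_high) maximising between-class variance. t_low splits
# fluid from clot-or-denser.
otsu_thresholds <- function(x, nbins = 256L) {
  h <- tabulate(pmin(pmax(floor(x * nbins), 0), nbins - 1L) + 1L, nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  W <- c(0, cumsum(p))
  M <- c(0, cumsum(p * mids))
  best <- c(-Inf, 1L, 2L)
  for (k1 in 1:(nbins - 2L)) {
    w0 <- W[k1 + 1L]
    if (w0 == 0) next
    m0 <- M[k1 + 1L]
    k2 <- (k1 + 1L):(nbins - 1L)
    w1 <- W[k2 + 1L] - w0
    w2 <- 1 - W[k2 + 1L]
    m1 <- M[k2 + 1L] - m0
    m2 <- M[nbins + 1L] - M[k2 + 1L]
    ok <- w1 > 0 & w2 > 0
    if (!any(ok)) next
    between <- rep(-Inf, length(k2))
    between[ok] <- m0^2 / w0 + m1[ok]^2 / w1[ok] + m2[ok]^2 / w2[ok]
    j <- which.max(between)
    if (between[j] > best[1]) best <- c(between[j], k1, k2[j])
  }
  # threshold at the upper edge of the chosen bin
  c(best[2] / nbins, best[3] / nbins)
}

#' Subtract a clean-chamber mask to isolate clot
#'
#' Removes the rods and walls from a segmented scan so that only clot
#' remains: `clot = segmented AND NOT clean`. Both volumes must share a
#' grid.
#'
#' @param seg Binary solid-or-clot mask (e.g. from [segment_volume()]).
#' @param clean Binary clean-chamber mask ([voxelize_chamber()] or a
#'   segmented clean scan).
#' @return A binary clot [voxel_volume()], disjoint from `clean`.
#' @export
subtract_mask <- function(seg, clean) {
  stopifnot(inherits(seg, "voxel_volume"), inherits(clean, "voxel_volume"))
  if (!identical(dim(seg$grid), dim(clean$grid))) {
    stop("segmented and clean volumes differ in shape", call. = FALSE)
  }
  out <- voxel_volume(
    seg$grid & !clean$grid, seg$voxel_um, seg$origin_mm
  )
  out$spec <- if (!is.null(seg$spec)) seg$spec else clean$spec
  out
}

#' Crop edge regions from a volume
#'
#' Removes the wall-adjacent margins where contact activation at the
#' chamber boundary distorts clot measurements: by default 0.4 mm from
#' top and bottom (y), 1.3 mm from each side (x) and 1 mm from the inlet
#' face (z); the outlet edge is untouched. Margins are snapped to whole
#' voxels toward the interior (ceiling), and the volume's physical origin
#' is updated so downstream distances remain measured from the true
#' inlet.
#'
#' @param vol A [voxel_volume()].
#' @param top_bottom_mm,side_mm,inlet_mm Margins in mm.
#' @return The cropped [voxel_volume()].
#' @export
crop_volume <- function(vol, top_bottom_mm = 0.4, side_mm = 1.3,
                        inlet_mm = 1.0) {
  stopifnot(inherits(vol, "voxel_volume"))
  vox <- vol$voxel_um / 1000
  d <- dim(vol$grid)
  nx_m <- ceiling(side_mm / vox - 1e-9)
  ny_m <- ceiling(top_bottom_mm / vox - 1e-9)
  nz_m <- ceiling(inlet_mm / vox - 1e-9)
  if (2 * nx_m >= d[1] || 2 * ny_m >= d[2] || nz_m >= d[3]) {
    stop("crop margins exceed the volume extent", call. = FALSE)
  }
  g <- vol$grid[
    (nx_m + 1):(d[1] - nx_m),
    (ny_m + 1):(d[2] - ny_m),
    (nz_m + 1):d[3],
    drop = FALSE
  ]
  out <- voxel_volume(
    g, vol$voxel_um,
    vol$origin_mm + c(nx_m, ny_m, nz_m) * vox
  )
  out$spec <- vol$spec
  out
}

#' Crop a clot segmentation
#'
#' Applies [crop_volume()] to the clot mask of a [clot_segmentation()],
#' preserving provenance.
#'
#' @inheritParams crop_volume
#' @param seg A [clot_segmentation()].
#' @return The cropped [clot_segmentation()].
#' @export
crop_segmentation <- function(seg, top_bottom_mm = 0.4, side_mm = 1.3,
                              inlet_mm = 1.0) {
  stopifnot(inherits(seg, "clot_segmentation"))
  seg$clot <- crop_volume(seg$clot, top_bottom_mm, side_mm, inlet_mm)
  if (!is.null(seg$spec)) seg$clot$spec <- seg$spec
  seg
}

as_clot_volume <- function(clot) {
  if (inherits(clot, "clot_segmentation")) clot$clot else clot
}

#' Longitudinal clot slice profile
#'
#' Sums clot volume in segments along the flow axis. `five_segments`
#' (default) places 2-mm segments centred at 5%, 25%, 50%, 75% and 95% of
#' the (cropped) length — entrance, first quarter, middle, third quarter
#' and downstream end — clipped to the volume bounds; `tiling` covers the
#' length with contiguous segments (so segment volumes sum exactly to the
#' total clot volume). Each segment volume is also normalized by the void
#' volume available for clot in that segment,
#' `segment gross volume * (1 - PD)`.
#'
#' @param clot A [clot_segmentation()] or binary clot [voxel_volume()].
#' @param mode `"five_segments"` or `"tiling"`.
#' @param segment_mm Segment length, mm.
#' @param spec Chamber spec (for the packing density); taken from the
#'   object if present.
#' @return A `slice_profile` tibble: `segment_center_mm` (from the true
#'   inlet), `segment_length_mm`, `clot_volume_mm3`,
#'   `normalized_fraction`.
#' @export
slice_profile <- function(clot, mode = c("five_segments", "tiling"),
                          segment_mm = 2, spec = NULL) {
  mode <- match.arg(mode)
  vol <- as_clot_volume(clot)
  stopifnot(inherits(vol, "voxel_volume"))
  if (is.null(spec)) {
    spec <- if (inherits(clot, "clot_segmentation")) clot$spec else vol$spec
  }
  if (is.null(spec)) stop("supply `spec` (packing density needed)", call. = FALSE)
  vox <- vol$voxel_um / 1000
  d <- dim(vol$grid)
  len <- d[3] * vox
  if (segment_mm > len + 1e-9) {
    stop("segment length exceeds the volume length", call. = FALSE)
  }
  if (mode == "five_segments") {
    centers <- c(0.05, 0.25, 0.50, 0.75, 0.95) * len
    starts <- pmin(pmax(centers - segment_mm / 2, 0), len - segment_mm)
    ends <- starts + segment_mm
  } else {
    starts <- seq(0, len - 1e-9, by = segment_mm)
    ends <- pmin(starts + segment_mm, len)
  }
  counts_per_slice <- apply(vol$grid, 3, sum)
  xs_area_mm2 <- d[1] * d[2] * vox^2
  rows <- purrr::map2_dfr(starts, ends, function(a, b) {
    iz <- which((seq_len(d[3]) - 0.5) * vox >= a &
      (seq_len(d[3]) - 0.5) * vox < b)
    v <- sum(counts_per_slice[iz]) * vox^3
    gross <- xs_area_mm2 * length(iz) * vox
    tibble::tibble(
      segment_center_mm = (a + b) / 2 + vol$origin_mm[3],
      segment_length_mm = b - a,
      clot_volume_mm3 = v,
      normalized_fraction = normalize_clot_volume(v, spec, gross)
    )
  })
  class(rows) <- c("slice_profile", class(rows))
  rows
}

#' Normalize a clot volume by the void volume available for clot
#'
#' `V_clot / (region volume * (1 - PD))`: the clot volume as a fraction of
#' the region's volume not occupied by fibers, making chambers of
#' different packing density comparable.
#'
#' @param v_clot_mm3 Clot volume, mm^3.
#' @param spec A [chamber_spec()] (for the packing density).
#' @param region_mm3 Gross volume of the region the clot was measured in,
#'   mm^3.
#' @return Normalized fraction, nominally in `[0, 1]`; values above
#'   `1.05` raise an error as physically impossible (a few percent of
#'   slack is allowed because cropped regions near walls hold slightly
#'   more void than `1 - PD`).
#' @examples
#' normalize_clot_volume(21.9, chamber_spec(pd = 0.5), 438)
#' @export
normalize_clot_volume <- function(v_clot_mm3, spec, region_mm3) {
  stopifnot(inherits(spec, "chamber_spec"))
  if (any(region_mm3 <= 0)) stop("`region_mm3` must be positive", call. = FALSE)
  avail <- region_mm3 * (1 - spec$pd)
  # allow a few percent of slack: near chamber walls the true void
  # fraction exceeds 1 - PD because boundary rods are clipped
  if (any(v_clot_mm3 > avail * 1.05)) {
    stop("clot volume exceeds the available void volume", call. = FALSE)
  }
  v_clot_mm3 / avail
}

#' Voxelwise clot probability map across replicates
#'
#' Averages the binary clot masks of replicate runs of one condition into
#' a per-voxel probability of clot occupancy.
#'
#' @param replicates A list of [clot_segmentation()]s (or binary
#'   [voxel_volume()]s) on identical grids.
#' @param label Optional condition label.
#' @return A `probability_map`: a scalar [voxel_volume()] in `[0, 1]` with
#'   fields `n_replicates` and `label`.
#' @export
probability_map <- function(replicates, label = NULL) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  vols <- lapply(replicates, as_clot_volume)
  ref <- vols[[1]]
  for (v in vols[-1]) {
    if (!same_grid(ref, v)) stop("replicate grids differ", call. = FALSE)
  }
  acc <- array(0, dim(ref$grid))
  for (v in vols) acc <- acc + (v$grid != 0)
  out <- voxel_volume(acc / length(vols), ref$voxel_um, ref$origin_mm)
  out$n_replicates <- length(vols)
  out$label <- label
  class(out) <- c("probability_map", class(out))
  out
}

#' Project a volume along an axis
#'
#' Averages a probability map (or any volume) along the rod axis
#' (default), producing the inlet-to-outlet plan view used to display
#' clot distributions, or along the flow axis for a cross-sectional view.
#'
#' @param map A `probability_map` or [voxel_volume()].
#' @param axis `"rod_axis"` (y; plan view) or `"flow_axis"` (z).
#' @return A tibble in long form: coordinates in mm (`x_mm` and `z_mm` or
#'   `y_mm`) and the mean `value`.
#' @export
project_axis <- function(map, axis = c("rod_axis", "flow_axis")) {
  axis <- match.arg(axis)
  stopifnot(inherits(map, "voxel_volume"))
  vox <- map$voxel_um / 1000
  d <- dim(map$grid)
  if (axis == "rod_axis") {
    img <- apply(map$grid, c(1, 3), mean) # nx x nz
    out <- tidyr::expand_grid(
      x_mm = (seq_len(d[1]) - 0.5) * vox + map$origin_mm[1],
      z_mm = (seq_len(d[3]) - 0.5) * vox + map$origin_mm[3]
    )
    out$value <- as.vector(t(img)) # expand_grid varies the last column fastest
  } else {
    img <- apply(map$grid, c(1, 2), mean) # nx x ny
    out <- tidyr::expand_grid(
      x_mm = (seq_len(d[1]) - 0.5) * vox + map$origin_mm[1],
      y_mm = (seq_len(d[2]) - 0.5) * vox + map$origin_mm[2]
    )
    out$value <- as.vector(t(img))
  }
  class(out) <- c("axis_projection", class(out))
  attr(out, "axis") <- axis
  out
}

#' Clot volume in a slab at a given distance from the inlet
#'
#' Sums clot in a slab `[distance, distance + slab)` along the flow axis,
#' with distance measured from the true (pre-crop) inlet face: the
#' volume's recorded origin accounts for any inlet crop.
#'
#' @param clot A [clot_segmentation()] or binary clot [voxel_volume()].
#' @param distance_mm Distance of the slab's upstream face from the
#'   inlet, mm. Vectorised.
#' @param slab_mm Slab thickness, mm.
#' @return A tibble with `distance_mm`, `slab_mm` and `clot_volume_mm3`.
#' @export
clot_at_equivalent_distance <- function(clot, distance_mm, slab_mm = 1) {
  vol <- as_clot_volume(clot)
  stopifnot(inherits(vol, "voxel_volume"), slab_mm > 0)
  vox <- vol$voxel_um / 1000
  d <- dim(vol$grid)
  z0 <- vol$origin_mm[3]
  z_end <- z0 + d[3] * vox
  if (any(distance_mm < z0 - 1e-9) ||
    any(distance_mm + slab_mm > z_end + 1e-9)) {
    stop(sprintf(
      "slab outside the volume: z range is [%.3f, %.3f] mm from the inlet",
      z0, z_end
    ), call. = FALSE)
  }
  counts_per_slice <- apply(vol$grid, 3, sum)
  zc <- (seq_len(d[3]) - 0.5) * vox + z0
  purrr::map_dfr(distance_mm, function(dist) {
    iz <- which(zc >= dist & zc < dist + slab_mm)
    tibble::tibble(
      distance_mm = dist, slab_mm = slab_mm,
      clot_volume_mm3 = sum(counts_per_slice[iz]) * vox^3
    )
  })
}

#' Dice overlap coefficient between two binary volumes
#'
#' `2|A intersect B| / (|A| + |B|)`; used to validate segmentation against
#' generator ground truth.
#'
#' @param a,b Binary [voxel_volume()]s on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as_clot_volume(a)
  b <- as_clot_volume(b)
  stopifnot(identical(dim(a$grid), dim(b$grid)))
  ga <- a$grid != 0
  gb <- b$grid != 0
  2 * sum(ga & gb) / (sum(ga) + sum(gb))
}
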