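#' Voxel volume container
#'
#' An axis-aligned 3D grid with isotropic physical voxel size. Axis
#' convention throughout the package: axis 1 = width x, axis 2 = height y
#' (the rod axis), axis 3 = flow z with the inlet at index 1. `origin_mm`
#' records the physical position of the first voxel's lower corner in the
#' chamber frame, so cropped volumes remember where they sit relative to
#' the true inlet.
#'
#' @param grid A 3D numeric or logical array.
#' @param voxel_um Voxel edge length, micrometres (isotropic).
#' @param origin_mm Numeric length-3, physical offset of the grid's lower
#'   corner from the chamber origin, mm.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(grid, voxel_um, origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(grid), length(dim(grid)) == 3L, voxel_um > 0,
    length(origin_mm) == 3L)
  structure(
    list(grid = grid, voxel_um = voxel_um, origin_mm = as.numeric(origin_mm)),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$grid)
  ext <- d * x$voxel_um / 1000
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels @ %g um (%.2f x %.2f x %.2f mm), %s\n",
    d[1], d[2], d[3], x$voxel_um, ext[1], ext[2], ext[3],
    if (is.logical(x$grid)) "binary" else "grayscale"
  ))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$grid)

#' Physical extent of a voxel volume
#'
#' @param vol A [voxel_volume()].
#' @return Numeric length-3, extent in mm along (x, y, z).
#' @export
voxel_extent_mm <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  dim(vol$grid) * vol$voxel_um / 1000
}

#' Physical volume of one voxel in mm^3
#' @param vol A [voxel_volume()].
#' @return Scalar, mm^3.
#' @export
voxel_mm3 <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  (vol$voxel_um / 1000)^3
}

#' Total volume of a binary mask in mm^3
#'
#' @param vol A binary [voxel_volume()].
#' @return Clotted/solid volume in mm^3.
#' @export
mask_volume_mm3 <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  sum(vol$grid != 0) * voxel_mm3(vol)
}

is_binary_volume <- function(vol) {
  is.logical(vol$grid) || all(vol$grid %in% c(0, 1))
}

same_grid <- function(a, b) {
  identical(dim(a$grid), dim(b$grid)) &&
    isTRUE(all.equal(a$voxel_um, b$voxel_um)) &&
    isTRUE(all.equal(a$origin_mm, b$origin_mm))
}

#' Clot segmentation record
#'
#' Binds a binary clot volume to its provenance: the chamber it came from,
#' the flow condition, and the donor/replicate/seed identifiers. The clot
#' mask is disjoint from the chamber solid by construction (enforced when
#' both are supplied).
#'
#' @param clot Binary [voxel_volume()] of clot only.
#' @param spec The [chamber_spec()].
#' @param condition The [flow_condition()].
#' @param donor_id Donor identifier.
#' @param replicate Replicate index.
#' @param seed RNG seed or source-file provenance.
#' @param solid Optional chamber solid mask; if given, disjointness with
#'   the clot is checked.
#' @return An object of class `clot_segmentation`.
#' @export
clot_segmentation <- function(clot, spec = NULL, condition = NULL,
                              donor_id = NA, replicate = NA, seed = NA,
                              solid = NULL) {
  stopifnot(inherits(clot, "voxel_volume"))
  if (!is_binary_volume(clot)) stop("clot mask must be binary", call. = FALSE)
  if (!is.null(solid)) {
    stopifnot(inherits(solid, "voxel_volume"))
    if (any(clot$grid & solid$grid)) {
      stop("clot mask overlaps chamber solid", call. = FALSE)
    }
  }
  structure(
    list(
      clot = clot, spec = spec, condition = condition,
      donor_id = donor_id, replicate = replicate, seed = seed
    ),
    class = "clot_segmentation"
  )
}

#' @export
print.clot_segmentation <- function(x, ...) {
  cat(sprintf(
    "<clot_segmentation> donor %s rep %s: %.3f mm^3 clot\n",
    as.character(x$donor_id), as.character(x$replicate),
    mask_volume_mm3(x$clot)
  ))
  invisible(x)
}
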