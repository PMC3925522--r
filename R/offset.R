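#' Absolute clearance between the articular surface and a screw axis
#'
#' The minimal stand-off a screw axis must keep from the acetabular
#' articular surface so that neither the subchondral bone layer nor the
#' screw body breaches the joint: the maximal subchondral thickness plus
#' the minimal screw radius. With the reported bounds (subchondral bone up
#' to 1.2 mm thick, smallest common screw radius 1.75 mm) this evaluates to
#' 2.95 mm.
#'
#' @param subchondral_thickness_max maximal subchondral bone thickness (mm).
#' @param screw_radius_min minimal screw radius (mm).
#' @return clearance in mm.
#' @examples
#' compute_absolute_clearance(1.2, 1.75)
#' @export
compute_absolute_clearance <- function(subchondral_thickness_max = 1.2,
                                       screw_radius_min = 1.75) {
  if (!is.numeric(subchondral_thickness_max) ||
      !is.numeric(screw_radius_min) ||
      length(subchondral_thickness_max) != 1L ||
      length(screw_radius_min) != 1L ||
      is.na(subchondral_thickness_max) || is.na(screw_radius_min) ||
      subchondral_thickness_max < 0 || screw_radius_min < 0) {
    stop_quadzone("quadzone_invalid_argument",
                  "thickness and radius must be single non-negative numbers")
  }
  subchondral_thickness_max + screw_radius_min
}

#' Clearance specification for shell construction
#'
#' Bundles the two shelling distances: the absolute clearance
#' (`d_absolute`, derived as subchondral thickness + screw radius) and the
#' error-margin clearance (`d_with_margin`, a configured constant of 6 mm
#' that allows roughly a 3 mm insertion error on top of the absolute
#' clearance).
#'
#' @param subchondral_thickness_max maximal subchondral thickness (mm).
#' @param screw_radius_min minimal screw radius (mm).
#' @param error_margin nominal insertion error allowance (mm).
#' @param d_with_margin the margin shelling distance (mm); kept as an
#'   explicit constant rather than recomputed from the error margin.
#' @return an `offset_spec` list with fields `subchondral_thickness_max`,
#'   `screw_radius_min`, `error_margin`, `d_absolute`, `d_with_margin`.
#' @export
offset_spec <- function(subchondral_thickness_max = 1.2,
                        screw_radius_min = 1.75,
                        error_margin = 3,
                        d_with_margin = 6) {
  vals <- c(subchondral_thickness_max, screw_radius_min, error_margin,
            d_with_margin)
  if (!all(is.finite(vals)) || any(vals < 0)) {
    stop_quadzone("quadzone_invalid_argument",
                  "offset_spec fields must be non-negative and finite")
  }
  d_absolute <- compute_absolute_clearance(subchondral_thickness_max,
                                           screw_radius_min)
  if (d_with_margin < d_absolute) {
    stop_quadzone("quadzone_invalid_argument",
                  "d_with_margin must be at least the absolute clearance")
  }
  structure(list(subchondral_thickness_max = subchondral_thickness_max,
                 screw_radius_min = screw_radius_min,
                 error_margin = error_margin,
                 d_absolute = d_absolute,
                 d_with_margin = d_with_margin),
            class = "offset_spec")
}

#' Offset ("shell") a surface by a fixed distance
#'
#' Constructs the surface at distance `d` from the input surface: the
#' unsigned distance to the input mesh is sampled on a regular voxel grid
#' and the iso-surface at level `d` is extracted with marching tetrahedra.
#' For a closed input this is the outer offset plus the (usually discarded
#' by construction geometry) inner offset; for an open surface such as the
#' acetabular articular cap the result is the closed shell wrapping the cap
#' at stand-off `d`, which is exactly the occluder needed by the zone
#' analysis. The distance-field route cannot self-intersect, unlike naive
#' vertex displacement along normals on concave regions.
#'
#' `d = 0` returns the (validated) input surface itself.
#'
#' @param mesh a [triangle_mesh()].
#' @param d offset distance (mm), non-negative.
#' @param voxel_pitch grid spacing (mm); the offset surface is accurate to
#'   roughly twice the pitch. Must not be coarser than `d`.
#' @param clip_bounds optional 2 x 3 matrix (`rbind(lo, hi)`) restricting
#'   the extraction domain; useful when only part of the shell can ever
#'   act as an occluder. The shell is left open at the clip boundary.
#' @return a `triangle_mesh` of the offset surface.
#' @export
offset_surface <- function(mesh, d, voxel_pitch = 0.5, clip_bounds = NULL) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d)) {
    stop_quadzone("quadzone_invalid_argument", "d must be a single number")
  }
  if (d < 0) {
    stop_quadzone("quadzone_invalid_argument",
                  "offset distance d must be non-negative")
  }
  if (d == 0) {
    return(triangle_mesh(mesh$vertices, mesh$faces,
                         name = sprintf("%s_offset_0", mesh$name)))
  }
  if (voxel_pitch > d) {
    warning(sprintf(
      "voxel pitch %.3g mm is coarser than the offset distance %.3g mm",
      voxel_pitch, d), call. = FALSE)
    stop_quadzone("quadzone_invalid_argument",
                  "refusing to offset: voxel pitch coarser than d")
  }
  band <- d + 6 * voxel_pitch
  bb <- mesh_bbox(mesh)
  lo <- bb["lo", ] - band - voxel_pitch
  hi <- bb["hi", ] + band + voxel_pitch
  if (!is.null(clip_bounds)) {
    clip_bounds <- as.matrix(clip_bounds)
    lo <- pmax(lo, clip_bounds[1L, ])
    hi <- pmin(hi, clip_bounds[2L, ])
    if (any(hi <= lo)) {
      stop_quadzone("quadzone_invalid_argument",
                    "clip_bounds do not intersect the offset domain")
    }
  }
  dims <- as.integer(ceiling((hi - lo) / voxel_pitch)) + 1L
  field <- cpp_distance_field_band(mesh$vertices, mesh$faces, lo,
                                   voxel_pitch, dims, band)
  iso <- cpp_marching_tets(field, dims, lo, voxel_pitch, d)
  if (nrow(iso$faces) == 0L) {
    stop_quadzone("quadzone_degenerate_input",
                  "offset produced an empty surface (check d and clip_bounds)")
  }
  # marching tetrahedra welds shared grid-edge vertices exactly, so the
  # surface is used as-is: re-welding or area-filtering the occasional
  # sliver triangle would open cracks in an otherwise closed surface
  triangle_mesh(iso$vertices, iso$faces,
                name = sprintf("%s_offset_%g", mesh$name, d),
                validate = FALSE)
}
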