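#' Simulated Stoppa incision aperture
#'
#' The modified Stoppa approach is modelled as a straight longitudinal
#' aperture between two skin-level endpoints; a rigid straight instrument
#' (the screw trajectory) must pass through it, so every admissible
#' trajectory to an entry point starts at some point of the aperture.
#' Viewpoints are spaced uniformly along the segment with both endpoints
#' always included; index 1 is the proximal (toward the head) end and the
#' last index the distal end.
#'
#' @param proximal_end,distal_end 3D endpoints (mm).
#' @param n_viewpoints number of viewpoints (at least 2). The default of 21
#'   resolves the aperture finely enough that the absolute zones are stable
#'   under further refinement (verified in the test-suite convergence
#'   checks).
#' @return an `incision_aperture` with fields `proximal_end`, `distal_end`,
#'   `length` (mm) and `viewpoints` (n x 3 matrix).
#' @examples
#' make_incision(c(0, 0, 0), c(0, 100, 0), 11)
#' @export
make_incision <- function(proximal_end, distal_end, n_viewpoints = 21L) {
  proximal_end <- check_point3(proximal_end, "proximal_end")
  distal_end <- check_point3(distal_end, "distal_end")
  len <- sqrt(sum((distal_end - proximal_end)^2))
  if (len < 1e-9) {
    stop_quadzone("quadzone_degenerate_incision",
                  "incision endpoints coincide")
  }
  n_viewpoints <- as.integer(n_viewpoints)
  if (is.na(n_viewpoints) || n_viewpoints < 2L) {
    stop_quadzone("quadzone_invalid_argument",
                  "n_viewpoints must be an integer >= 2")
  }
  s <- seq(0, 1, length.out = n_viewpoints)
  vp <- matrix(proximal_end, nrow = n_viewpoints, ncol = 3L, byrow = TRUE) +
    outer(s, distal_end - proximal_end)
  structure(list(proximal_end = proximal_end, distal_end = distal_end,
                 length = len, viewpoints = vp),
            class = "incision_aperture")
}

#' @export
print.incision_aperture <- function(x, ...) {
  cat(sprintf("<incision_aperture: length %.1f mm, %d viewpoints>\n",
              x$length, nrow(x$viewpoints)))
  invisible(x)
}
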