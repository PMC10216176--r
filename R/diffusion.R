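#' One explicit finite-volume step of diffusion-decay with sources
#'
#' Advances `dC/dt = D * lap(C) - decay * C + sources` by one step `dt` on
#' a regular voxel grid with no-flux boundaries. Fluxes are assembled per
#' face, so with zero decay and no sources the total mass is conserved to
#' machine precision. The explicit scheme requires `dt <= h^2 / (6 D)` in
#' 3-D; a violating combination is rejected up front rather than allowed
#' to go unstable mid-run.
#'
#' @param field Numeric 3-D array of concentrations (one value per voxel).
#' @param D Diffusivity in um^2/day.
#' @param decay First-order decay rate in 1/day.
#' @param sources Numeric array of source rates (same shape as `field`),
#'   or a single 0 for none.
#' @param dt Time step in days.
#' @param h Voxel edge length in micrometers.
#' @return The updated field (same shape).
#' @export
diffuse_field <- function(field, D, decay, sources = 0, dt, h) {
  if (!is.array(field) || length(dim(field)) != 3L)
    stop("field must be a 3-D array", call. = FALSE)
  if (D < 0 || decay < 0 || dt <= 0 || h <= 0)
    stop("D, decay >= 0 and dt, h > 0 required", call. = FALSE)
  if (D > 0 && dt > h^2 / (6 * D))
    stop(sprintf(
      "explicit diffusion unstable: dt = %g > h^2/(6D) = %g; reduce dt or D",
      dt, h^2 / (6 * D)), call. = FALSE)
  no_src <- length(sources) == 1L && all(sources == 0)
  if (no_src && !any(field != 0)) return(field) # nothing to diffuse
  if (!no_src && !identical(dim(field), dim(sources)))
    stop("sources must match the field's shape", call. = FALSE)
  out <- diffuse_step_cpp(field, dim(field), D, decay,
                          if (no_src) NULL else sources, dt, h)
  dim(out) <- dim(field)
  out
}
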