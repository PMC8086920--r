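#' Digital inflammation: a perception-only perturbation
#'
#' Inflammation of the intestinal wall triggers the stretch-sensing neurons
#' so that the nervous system perceives the membrane as more stretched than
#' it is.  The model reproduces only this perceptual effect: a strain offset
#' \code{eps_phi} is added to the controller's pooled input, while the
#' physics is never touched.  The degree of inflammation is
#' \deqn{\phi = 100 \, \epsilon_\phi / (\epsilon + \epsilon_\phi)}
#' so \code{phi = 50\%} means the perceived strain is twice the true strain.
#'
#' A profile maps axial position to \code{phi} through piecewise-constant
#' regions, with an optional onset time before which the whole tube is
#' healthy.  Because \code{eps_phi} depends on the instantaneous true
#' strain, the offset is recomputed from \code{phi} at every controller
#' step, keeping \code{phi} constant within a region.
#'
#' @param regions data.frame with columns \code{x_start}, \code{x_end} (m)
#'   and \code{phi} (\%, in [0, 100)); positions outside every region are
#'   healthy.  Regions are evaluated on wrapped coordinates.
#' @param t0 optional onset time (s): before \code{t0} the tube is healthy
#'   everywhere.
#' @return an object of class \code{inflammation_profile}.
#' @export
inflammation_profile <- function(regions = data.frame(x_start = numeric(0),
                                                      x_end = numeric(0),
                                                      phi = numeric(0)),
                                 t0 = NULL) {
  stopifnot(all(c("x_start", "x_end", "phi") %in% names(regions)))
  if (any(regions$phi < 0 | regions$phi >= 100))
    stop("degree of inflammation must lie in [0, 100)", call. = FALSE)
  structure(list(regions = regions, t0 = t0),
            class = "inflammation_profile")
}

#' Degree of inflammation from strain offset and true strain
#'
#' \code{phi = 100 * eps_phi / (eps + eps_phi)}, in [0, 100).
#'
#' @param eps_phi perceptual strain offset (>= 0).
#' @param eps true strain (> 0 unless \code{eps_phi > 0}).
#' @return degree of inflammation (\%).
#' @export
inflammation_degree <- function(eps_phi, eps) {
  if (any(eps_phi < 0)) stop("strain offset must be >= 0", call. = FALSE)
  if (any(eps_phi + eps <= 0))
    stop("degree of inflammation undefined for eps + eps_phi <= 0",
         call. = FALSE)
  100 * eps_phi / (eps + eps_phi)
}

#' Strain offset that realizes a given degree of inflammation
#'
#' Inverts the definition of \code{\link{inflammation_degree}}:
#' \code{eps_phi = phi * eps / (100 - phi)}.  Round-trips through
#' \code{inflammation_degree} to the input \code{phi} within 1e-12.
#'
#' @param phi degree of inflammation (\%, in [0, 100)).
#' @param eps true strain.
#' @return the strain offset \code{eps_phi}.
#' @export
strain_offset <- function(phi, eps) {
  if (any(phi < 0 | phi >= 100))
    stop("degree of inflammation must lie in [0, 100): perception diverges",
         call. = FALSE)
  phi * eps / (100 - phi)
}

phi_at <- function(profile, x, t, L) {
  if (!is.null(profile$t0) && t < profile$t0) return(0)
  x <- x %% L
  rg <- profile$regions
  for (r in seq_len(nrow(rg))) {
    x0 <- rg$x_start[r] %% L
    x1 <- rg$x_end[r]
    w <- (x1 - rg$x_start[r])
    if (((x - x0) %% L) < w) return(rg$phi[r])
  }
  0
}

#' Perceived strain under an inflammation profile
#'
#' Returns \code{eps_true + eps_phi} where the offset realizes the degree of
#' inflammation looked up at the receiving segment's axial midpoint
#' \code{x}; healthy regions and times (before \code{t0}) return the true
#' strain unchanged.  Negative true strains (a locally collapsed segment)
#' pass through unmodified: the offset is only defined for distension.
#'
#' @param eps_true true pooled strain.
#' @param x axial lookup position (m), typically the receiving-segment
#'   midpoint.
#' @param t current time (s).
#' @param profile an \code{\link{inflammation_profile}}.
#' @param L axial period (m).
#' @return the perceived strain.
#' @export
perceive <- function(eps_true, x, t, profile, L) {
  phi <- phi_at(profile, x, t, L)
  if (phi == 0 || eps_true <= 0) return(eps_true)
  eps_true + strain_offset(phi, eps_true)
}
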