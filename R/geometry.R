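#' Tube geometry descriptor
#'
#' Describes the flexible tube: a cylindrical membrane lattice of
#' \code{n_rings} rings with \code{n_per_ring} particles each, an interior
#' fluid packed as axial slices of concentric-circle discs, and the length
#' \code{dL} of the travelling contraction window.  The tube axis is x and
#' axial coordinates live on the half-open periodic interval \code{[0, L)}.
#'
#' @param L tube length (m).
#' @param R tube radius (m).
#' @param dL contraction-section length (m); must not exceed \code{L}.
#' @param n_rings number of membrane rings along the axis (>= 1).
#' @param n_per_ring membrane particles per ring (>= 3).
#' @param fluid_slices number of fluid discs, placed midway between
#'   consecutive ring planes (default \code{n_rings - 1}; 0 gives an empty
#'   lumen).
#' @param disc_counts integer vector: particles on each concentric circle of
#'   a fluid disc, innermost (the axis point) first.  Circle \code{j} sits at
#'   radius \code{(j-1) * dr} with \code{dr = (R - clearance)/(length - 1)}.
#' @param clearance radial gap (m) between the outermost fluid circle and the
#'   membrane; keeping it at or above the coupling range \code{r0} makes the
#'   freshly built tube an exact force equilibrium.
#' @param spring_cutoff neighbour-search cutoff (m) for the spring network;
#'   default 1.5 axial spacings, which bonds axial, circumferential and
#'   diagonal lattice neighbours (8 bonds per particle).
#' @return an object of class \code{tube_geometry}.
#' @export
tube_geometry <- function(L = 0.63, R = 0.025, dL = 0.063,
                          n_rings = 100, n_per_ring = 25,
                          fluid_slices = n_rings - 1,
                          disc_counts = c(1, 6, 12, 18, 24, 30, 31),
                          clearance = 0.0065,
                          spring_cutoff = 1.5 * L / n_rings) {
  if (L <= 0 || R <= 0 || dL <= 0)
    stop("tube dimensions must be positive", call. = FALSE)
  if (dL > L) stop("contraction section dL cannot exceed L", call. = FALSE)
  if (n_rings < 1) stop("need at least one membrane ring", call. = FALSE)
  if (n_per_ring < 3) stop("need at least 3 particles per ring", call. = FALSE)
  if (fluid_slices < 0) stop("fluid_slices must be >= 0", call. = FALSE)
  if (clearance >= R)
    stop("fluid packing radius >= R: clearance leaves no room for fluid",
         call. = FALSE)
  structure(list(L = L, R = R, dL = dL,
                 n_rings = as.integer(n_rings),
                 n_per_ring = as.integer(n_per_ring),
                 fluid_slices = as.integer(fluid_slices),
                 disc_counts = as.integer(disc_counts),
                 clearance = clearance,
                 spring_cutoff = spring_cutoff),
            class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf("tube_geometry: L=%g m, R=%g m, dL=%g m\n", x$L, x$R, x$dL))
  cat(sprintf("  membrane: %d rings x %d = %d particles\n",
              x$n_rings, x$n_per_ring, x$n_rings * x$n_per_ring))
  cat(sprintf("  fluid: %d slices x %d = %d particles\n",
              x$fluid_slices, sum(x$disc_counts),
              x$fluid_slices * sum(x$disc_counts)))
  invisible(x)
}

#' Geometry presets
#'
#' \describe{
#'   \item{full}{the reference colon-scale tube: 0.63 m x 0.025 m, 100 x 25
#'     membrane lattice (2500 particles, 250 per contraction window) and
#'     99 x 122 = 12 078 fluid particles.}
#'   \item{mini}{a short narrow tube at the \emph{same} lattice resolution
#'     (~6 mm spacing) for desk-scale physics tests: 25 x 12 membrane,
#'     24 x 19 fluid, 756 particles total.}
#'   \item{micro}{the smallest physically consistent tube, used for
#'     desk-scale training runs: 16 x 10 membrane, 15 x 7 fluid,
#'     265 particles total.}
#' }
#' All force constants and interaction ranges are identical across presets;
#' only the tube dimensions and particle counts shrink.
#'
#' @param name one of \code{"full"}, \code{"mini"}, \code{"micro"}.
#' @return a \code{\link{tube_geometry}}.
#' @export
geometry_preset <- function(name = c("full", "mini", "micro")) {
  name <- match.arg(name)
  switch(name,
    full  = tube_geometry(),
    mini  = tube_geometry(L = 0.1575, R = 0.0125, dL = 0.01575,
                          n_rings = 25, n_per_ring = 12,
                          disc_counts = c(1, 6, 12),
                          spring_cutoff = 1.5 * 0.1575 / 25),
    micro = tube_geometry(L = 0.1008, R = 0.010, dL = 0.0126,
                          n_rings = 16, n_per_ring = 10,
                          disc_counts = c(1, 6),
                          spring_cutoff = 1.5 * 0.1008 / 16))
}

new_particle_state <- function(pos, vel, rho, phase, xun, mass) {
  structure(list(pos = pos, vel = vel, rho = rho, phase = phase,
                 xun = xun, mass = mass),
            class = "particle_state")
}

#' @export
print.particle_state <- function(x, ...) {
  cat(sprintf("particle_state: %d particles (%d membrane, %d fluid), m=%g kg\n",
              nrow(x$pos), sum(x$phase == 0L), sum(x$phase == 1L), x$mass))
  invisible(x)
}

#' Build the membrane particle lattice
#'
#' Places \code{n_rings x n_per_ring} particles on a cylinder of radius
#' \code{R}: ring \code{r} sits at axial position \code{(r-1) * L/n_rings},
#' with particles equally spaced around the circumference.  Ring-major
#' ordering (all particles of ring 1, then ring 2, ...).
#'
#' @param geometry a \code{\link{tube_geometry}}.
#' @param mass per-particle mass (kg).
#' @return a \code{particle_state} with phase 0 (membrane) for all particles.
#' @export
build_membrane <- function(geometry, mass = 2.5e-4) {
  stopifnot(inherits(geometry, "tube_geometry"))
  nr <- geometry$n_rings
  np <- geometry$n_per_ring
  xs <- (seq_len(nr) - 1) * geometry$L / nr
  th <- (seq_len(np) - 1) * 2 * pi / np
  pos <- cbind(x = rep(xs, each = np),
               y = geometry$R * cos(rep(th, times = nr)),
               z = geometry$R * sin(rep(th, times = nr)))
  n <- nrow(pos)
  new_particle_state(pos = pos,
                     vel = matrix(0, n, 3),
                     rho = rep(1000, n),
                     phase = rep(0L, n),
                     xun = pos[, 1],
                     mass = mass)
}

#' Build the interior fluid packing
#'
#' Fluid discs are placed midway between consecutive ring planes (slice
#' \code{s} at \code{(s - 1/2) * L/n_rings}); each disc is a set of
#' concentric circles with \code{disc_counts} particles, the outermost at
#' radius \code{R - clearance}.  Alternate slices are rotated half an angular
#' step to avoid perfectly aligned columns.  Densities start at
#' \code{rho0 = 1000} kg m^-3.
#'
#' @inheritParams build_membrane
#' @param rho0 initial (reference) density, kg m^-3.
#' @return a \code{particle_state} with phase 1 (fluid) for all particles.
#' @export
build_fluid <- function(geometry, mass = 2.5e-4, rho0 = 1000) {
  stopifnot(inherits(geometry, "tube_geometry"))
  ns <- geometry$fluid_slices
  counts <- geometry$disc_counts
  if (ns == 0L) {
    return(new_particle_state(pos = matrix(numeric(0), 0, 3,
                                           dimnames = list(NULL, c("x","y","z"))),
                              vel = matrix(numeric(0), 0, 3),
                              rho = numeric(0), phase = integer(0),
                              xun = numeric(0), mass = mass))
  }
  r_pack <- geometry$R - geometry$clearance
  ncirc <- length(counts)
  radii <- if (ncirc == 1L) 0 else (seq_len(ncirc) - 1) * r_pack / (ncirc - 1)
  dx <- geometry$L / geometry$n_rings
  slice_x <- (seq_len(ns) - 0.5) * dx
  per_slice <- sum(counts)
  pos <- matrix(NA_real_, ns * per_slice, 3,
                dimnames = list(NULL, c("x", "y", "z")))
  row <- 1L
  for (s in seq_len(ns)) {
    stagger <- if (s %% 2L == 0L) 0.5 else 0
    for (ci in seq_len(ncirc)) {
      cnt <- counts[ci]
      if (cnt == 1L && radii[ci] == 0) {
        pos[row, ] <- c(slice_x[s], 0, 0)
        row <- row + 1L
      } else {
        th <- (seq_len(cnt) - 1 + stagger) * 2 * pi / cnt
        idx <- row:(row + cnt - 1L)
        pos[idx, 1] <- slice_x[s]
        pos[idx, 2] <- radii[ci] * cos(th)
        pos[idx, 3] <- radii[ci] * sin(th)
        row <- row + cnt
      }
    }
  }
  n <- nrow(pos)
  new_particle_state(pos = pos,
                     vel = matrix(0, n, 3),
                     rho = rep(rho0, n),
                     phase = rep(1L, n),
                     xun = pos[, 1],
                     mass = mass)
}

#' Combine membrane and fluid into one system
#'
#' @inheritParams build_membrane
#' @param rho0 initial fluid density (kg m^-3).
#' @return a \code{particle_state}; membrane particles come first.
#' @export
build_tube <- function(geometry, mass = 2.5e-4, rho0 = 1000) {
  mem <- build_membrane(geometry, mass = mass)
  flu <- build_fluid(geometry, mass = mass, rho0 = rho0)
  new_particle_state(pos = rbind(mem$pos, flu$pos),
                     vel = rbind(mem$vel, flu$vel),
                     rho = c(mem$rho, flu$rho),
                     phase = c(mem$phase, flu$phase),
                     xun = c(mem$xun, flu$xun),
                     mass = mass)
}

#' Build the membrane spring network
#'
#' Bonds every pair of membrane particles closer than \code{cutoff}
#' (minimum-image in x, period \code{L}).  With the default cutoff of 1.5
#' lattice spacings this connects each particle to its 2 axial, 2
#' circumferential and 4 diagonal neighbours.  Each bond's rest length is the
#' initial pair distance, so the freshly built tube is stress-free.
#'
#' @param membrane a \code{particle_state} holding membrane particles (as
#'   built by \code{\link{build_membrane}}; fluid rows are ignored).
#' @param cutoff neighbour cutoff (m).
#' @param L axial period (m).
#' @param min_spacing smallest lattice spacing (m); a cutoff below it would
#'   disconnect the lattice and is rejected.  Defaults to the smallest
#'   nearest-neighbour distance found.
#' @return a \code{bond_set}: data.frame with columns \code{i}, \code{j}
#'   (1-based indices into the membrane state, \code{i < j}) and \code{rest}.
#' @export
build_springs <- function(membrane, cutoff, L, min_spacing = NULL) {
  stopifnot(inherits(membrane, "particle_state"))
  keep <- which(membrane$phase == 0L)
  pos <- membrane$pos[keep, , drop = FALSE]
  if (nrow(pos) < 2L) {
    out <- data.frame(i = integer(0), j = integer(0), rest = numeric(0))
    class(out) <- c("bond_set", "data.frame")
    return(out)
  }
  pr <- cpp_pairs_within(pos, cutoff, L)
  if (nrow(pr) == 0L)
    stop("spring cutoff smaller than the lattice spacing: no bonds found",
         call. = FALSE)
  dxv <- pos[pr[, 1], 1] - pos[pr[, 2], 1]
  dxv <- dxv - L * round(dxv / L)
  rest <- sqrt(dxv^2 +
               (pos[pr[, 1], 2] - pos[pr[, 2], 2])^2 +
               (pos[pr[, 1], 3] - pos[pr[, 2], 3])^2)
  if (is.null(min_spacing)) min_spacing <- min(rest)
  if (cutoff < min_spacing)
    stop("spring cutoff smaller than the lattice spacing", call. = FALSE)
  deg <- tabulate(c(pr[, 1], pr[, 2]), nbins = nrow(pos))
  if (any(deg < 2L))
    warning("some membrane particles have fewer than 2 bonds")
  out <- data.frame(i = keep[pr[, 1]], j = keep[pr[, 2]], rest = rest)
  o <- order(out$i, out$j)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bond_set", "data.frame")
  out
}

#' Particles inside an axial window under periodic wrap
#'
#' Returns the indices whose wrapped axial coordinate lies in the half-open
#' interval \code{[x_start, x_start + width)} modulo \code{L}.
#'
#' @param x axial coordinates (m; wrapped or not, they are re-wrapped).
#' @param x_start window origin (m), in \code{[0, L)}.
#' @param width window width (m), at most \code{L}.
#' @param L axial period (m).
#' @return integer indices into \code{x}.
#' @export
window_members <- function(x, x_start, width, L) {
  if (width > L) stop("window width exceeds the tube length", call. = FALSE)
  if (x_start < 0 || x_start >= L)
    stop("x_start must lie in [0, L)", call. = FALSE)
  if (width == L) return(seq_along(x))
  d <- (x - x_start) %% L
  which(d < width)
}
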