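# Analytic flow phantoms standing in for 4D-flow acquisitions.
#
# Three kinds on a regular lattice, each confined to a stated geometric
# support so region-of-interest tests have exact expectations:
#   rigid_rotation  v = (-Omega*y, Omega*x, 0) about the grid center inside a
#                   spherical support; |curl| = 2*Omega everywhere inside.
#   lamb_oseen      tangential v_theta(r) = Gamma/(2*pi*r)*(1 - exp(-r^2/rc^2))
#                   about the central z axis; axial core vorticity
#                   omega_z(0) = Gamma/(pi*rc^2).
#   uniform_pipe    axial speed U inside a cylinder; curl 0 in the interior.
# A temporal envelope (binary diastole on/off by default, smooth sin^2
# optionally) scales the field per frame; Gaussian noise is added per voxel,
# component, and frame from per-frame substreams.

#' Specify a flow phantom
#'
#' @param kind one of \code{"rigid_rotation"}, \code{"lamb_oseen"},
#'   \code{"uniform_pipe"}.
#' @param grid_shape integer length-3 lattice dimensions.
#' @param spacing voxel size, mm (scalar or length-3).
#' @param n_frames number of cardiac frames.
#' @param frame_duration ms per frame.
#' @param diastole_frames integer vector of diastolic frame indices.
#' @param params kind-specific parameters: \code{omega} (rad/s) for rotation;
#'   \code{gamma} (cm^2/s) and \code{r_c} (cm) for Lamb-Oseen; \code{speed}
#'   (cm/s) and \code{radius} (cm) for the pipe. Optional
#'   \code{support_radius} (cm) bounds the flow support (default 0.4 of the
#'   smallest in-plane extent).
#' @param noise_sd Gaussian noise sd per component, cm/s.
#' @param venc velocity encoding limit, cm/s (default 150).
#' @param seed integer root seed.
#' @param envelope \code{"binary"} (1 on diastole frames, 0 elsewhere) or
#'   \code{"smooth"} (sin^2 bump over the diastole range).
#' @return A validated list of class \code{"FlowPhantomSpec"}.
#' @export
flowPhantomSpec <- function(kind, grid_shape, spacing, n_frames, frame_duration,
                            diastole_frames, params = list(), noise_sd = 0,
                            venc = 150, seed = 1, envelope = c("binary", "smooth")) {
  kind <- as.character(kind)
  if (!kind %in% c("rigid_rotation", "lamb_oseen", "uniform_pipe"))
    .stopf("unknown phantom kind '%s'", kind)
  envelope <- match.arg(envelope)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) .stopf("spacing must be positive")
  if (n_frames < 1) .stopf("n_frames must be at least 1")
  if (noise_sd < 0) .stopf("noise_sd must be non-negative")
  if (venc <= 0) .stopf("venc must be positive")
  diastole_frames <- as.integer(diastole_frames)
  if (length(diastole_frames) &&
      (min(diastole_frames) < 1 || max(diastole_frames) > n_frames))
    .stopf("diastole_frames outside 1..n_frames")
  structure(list(kind = kind, grid_shape = as.integer(grid_shape),
                 spacing = spacing, n_frames = as.integer(n_frames),
                 frame_duration = frame_duration,
                 diastole_frames = diastole_frames, params = params,
                 noise_sd = noise_sd, venc = venc, seed = as.integer(seed),
                 envelope = envelope),
            class = "FlowPhantomSpec")
}

# Noise-free spatial base field (cm/s) of a phantom spec: (nx,ny,nz,3) array.
.phantomBaseField <- function(spec) {
  dims <- spec$grid_shape
  co <- .coordArrays(dims, spec$spacing)
  ctr <- .gridCenter(dims, spec$spacing)
  xc <- (co$x - ctr[1]) / 10; yc <- (co$y - ctr[2]) / 10; zc <- (co$z - ctr[3]) / 10  # cm
  v <- array(0, dim = c(dims, 3))
  extent_cm <- (dims - 1) * spec$spacing / 10
  supp <- spec$params$support_radius %||% (0.4 * min(extent_cm[1:2]))
  if (spec$kind == "rigid_rotation") {
    omega <- spec$params$omega %||% .stopf("rigid_rotation needs params$omega")
    inside <- (xc^2 + yc^2 + zc^2) <= supp^2
    v[, , , 1] <- -omega * yc * inside
    v[, , , 2] <- omega * xc * inside
  } else if (spec$kind == "lamb_oseen") {
    gamma <- spec$params$gamma %||% .stopf("lamb_oseen needs params$gamma")
    r_c <- spec$params$r_c %||% .stopf("lamb_oseen needs params$r_c")
    if (r_c < 2 * min(spec$spacing) / 10)
      .warnf("Lamb-Oseen core radius below 2 voxels; discretization unreliable")
    rho2 <- xc^2 + yc^2
    rho <- sqrt(rho2)
    inside <- rho <= supp
    # v_theta / rho, finite at the axis: Gamma/(2*pi*rc^2) * (1-exp(-u))/u
    u <- rho2 / r_c^2
    f <- ifelse(u < 1e-12, 1 - u / 2, (1 - exp(-u)) / pmax(u, 1e-300))
    vt_over_r <- gamma / (2 * pi * r_c^2) * f
    v[, , , 1] <- -vt_over_r * yc * inside
    v[, , , 2] <- vt_over_r * xc * inside
  } else { # uniform_pipe
    speed <- spec$params$speed %||% .stopf("uniform_pipe needs params$speed")
    radius <- spec$params$radius %||% .stopf("uniform_pipe needs params$radius")
    inside <- (xc^2 + yc^2) <= radius^2
    v[, , , 3] <- speed * inside
  }
  v
}

# Temporal envelope over frames: binary indicator of diastole, or a sin^2
# bump spanning the diastole range (zero exactly at the range edges' outer
# boundary, peaking mid-diastole).
.temporalEnvelope <- function(spec) {
  env <- numeric(spec$n_frames)
  df <- spec$diastole_frames
  if (!length(df)) return(env)
  if (spec$envelope == "binary") {
    env[df] <- 1
  } else {
    d0 <- min(df); d1 <- max(df); L <- d1 - d0 + 2
    t <- df
    env[df] <- sin(pi * (t - d0 + 1) / L)^2
  }
  env
}

#' Generate an analytic flow phantom
#'
#' Evaluates the spec's analytic velocity field on the lattice, applies the
#' temporal envelope, and adds per-frame Gaussian noise. Reproducible from
#' the root seed via per-frame substreams.
#'
#' @param spec a \code{"FlowPhantomSpec"} from [flowPhantomSpec()].
#' @return A [VelocityField-class].
#' @export
generateFlowPhantom <- function(spec) {
  stopifnot(inherits(spec, "FlowPhantomSpec"))
  base <- .phantomBaseField(spec)
  env <- .temporalEnvelope(spec)
  dims <- spec$grid_shape
  vals <- array(0, dim = c(dims, 3, spec$n_frames))
  nv <- prod(dims) * 3
  for (t in seq_len(spec$n_frames)) {
    frame <- base * env[t]
    if (spec$noise_sd > 0) {
      set.seed(subSeed(spec$seed, t))
      frame <- frame + array(stats::rnorm(nv, 0, spec$noise_sd), dim = dim(base))
    }
    vals[, , , , t] <- frame
  }
  new("VelocityField", values = vals, spacing = spec$spacing,
      frameDuration = spec$frame_duration, venc = spec$venc,
      diastoleFrames = spec$diastole_frames)
}

#' Wrap velocities beyond the encoding limit (simulated aliasing)
#'
#' Phase-contrast velocities beyond +-VENC alias: each component v is
#' replaced by \code{((v + venc) mod 2*venc) - venc}, so output components
#' lie in \code{[-venc, venc)}. Idempotent on in-range values and periodic
#' with period \code{2*venc}.
#'
#' @param field a [VelocityField-class].
#' @param venc encoding limit, cm/s; defaults to the field's VENC.
#' @return A [VelocityField-class] with wrapped values.
#' @export
wrapVelocity <- function(field, venc = NULL) {
  stopifnot(is(field, "VelocityField"))
  venc <- venc %||% field@venc
  if (venc <= 0) .stopf("venc must be positive")
  v <- ((field@values + venc) %% (2 * venc)) - venc
  initialize(field, values = v, venc = venc)
}
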