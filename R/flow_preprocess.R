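# Velocity preprocessing: antialiasing, background phase correction,
# pluggable denoising, and transvalvular volume quantification.
# Every operation preserves grid shape, spacing, and frame count.

#' Body surface area by the Mosteller formula
#'
#' \code{sqrt(height_cm * weight_kg / 3600)} in m^2. Vectorized.
#'
#' @param height_cm height in cm (> 0).
#' @param weight_kg weight in kg (> 0).
#' @return BSA in m^2.
#' @examples
#' bsaMosteller(170, 72)  # 1.8439
#' @export
bsaMosteller <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    .stopf("height and weight must be positive")
  sqrt(height_cm * weight_kg / 3600)
}

#' Unwrap aliased velocities by temporal continuity
#'
#' Single-wrap phase-velocity antialiasing, extending the usable range to
#' +-2*VENC: per voxel and component, each frame's value \code{w_t} (assumed
#' in \code{[-venc, venc)}) is replaced by \code{w_t + 2*venc*k_t} with
#' \code{k_t in \{-1, 0, 1\}} chosen to minimize the total squared temporal
#' second difference of the trace (boundary frames enter only through the
#' one-sided terms available to them). The minimization is exact: a dynamic
#' program over the wrap offsets with a vanishing preference for \code{k = 0}
#' to break the global-offset tie. Fields with a single frame are returned
#' unchanged with a warning.
#'
#' @param field a [VelocityField-class] with components in \code{[-venc, venc)}.
#' @param venc encoding limit (cm/s); defaults to the field's VENC.
#' @return A [VelocityField-class] with unwrapped values.
#' @export
unwrapVelocity <- function(field, venc = NULL) {
  stopifnot(is(field, "VelocityField"))
  venc <- venc %||% field@venc
  if (venc <= 0) .stopf("venc must be positive")
  d <- dim(field@values)
  T <- d[5]
  if (T < 3) {
    .warnf("fewer than 3 frames; returning field unchanged")
    return(field)
  }
  nSeries <- prod(d[1:4])
  # series in rows, frames in columns
  W <- matrix(aperm(field@values, c(5, 1, 2, 3, 4)), nrow = T)
  K <- .unwrapDP(W, venc)
  V <- W + 2 * venc * K
  vals <- aperm(array(V, dim = c(T, d[1:4])), c(2, 3, 4, 5, 1))
  initialize(field, values = vals)
}

# Exact DP over wrap offsets k in {-1,0,1} minimizing
#   sum_t (v_{t+1} - 2 v_t + v_{t-1})^2 + eps * sum_t k_t^2
# for every column trace of W (T x nSeries). Chunked over series to bound
# memory. Returns the offset matrix K (same shape as W).
.unwrapDP <- function(W, venc, chunk = 20000L) {
  T <- nrow(W); nS <- ncol(W)
  K <- matrix(0L, T, nS)
  offs <- c(-1, 0, 1) * 2 * venc
  eps <- 1e-9 * (2 * venc)^2
  reg <- eps * c(1, 0, 1)
  for (start in seq(1L, nS, by = chunk)) {
    cols <- start:min(start + chunk - 1L, nS)
    m <- length(cols)
    Wc <- W[, cols, drop = FALSE]
    # state s = (i, j) = (k_{t-1}, k_t), flattened s = (i-1)*3 + j
    cost <- matrix(0, m, 9)
    for (i in 1:3) for (j in 1:3)
      cost[, (i - 1) * 3 + j] <- reg[i] + reg[j]
    back <- array(0L, dim = c(m, 9, max(T - 2, 0)))
    for (t in 3:T) {
      newcost <- matrix(Inf, m, 9)
      newback <- matrix(0L, m, 9)
      v_t2 <- outer(Wc[t - 2, ], rep(1, 3)) + rep(offs, each = m)   # m x 3 over i
      v_t1 <- outer(Wc[t - 1, ], rep(1, 3)) + rep(offs, each = m)   # over j
      v_t0 <- outer(Wc[t, ], rep(1, 3)) + rep(offs, each = m)       # over l
      for (j in 1:3) for (l in 1:3) {
        s_new <- (j - 1) * 3 + l
        best <- rep(Inf, m); bestI <- rep(0L, m)
        for (i in 1:3) {
          w <- (v_t0[, l] - 2 * v_t1[, j] + v_t2[, i])^2
          tot <- cost[, (i - 1) * 3 + j] + w
          sel <- tot < best
          best[sel] <- tot[sel]; bestI[sel] <- i
        }
        newcost[, s_new] <- best + reg[l]
        newback[, s_new] <- bestI
      }
      cost <- newcost
      back[, , t - 2] <- newback
    }
    sFin <- max.col(-cost, ties.method = "first")
    kT <- ((sFin - 1L) %% 3L) + 1L
    kT1 <- ((sFin - 1L) %/% 3L) + 1L
    Kc <- matrix(0L, T, m)
    Kc[T, ] <- kT - 2L
    Kc[T - 1, ] <- kT1 - 2L
    curJ <- kT1; curL <- kT
    for (t in T:3) {
      s <- (curJ - 1L) * 3L + curL
      prevI <- back[cbind(seq_len(m), s, t - 2)]
      Kc[t - 2, ] <- prevI - 2L
      curL <- curJ; curJ <- prevI
    }
    K[, cols] <- Kc
  }
  K
}

#' Correct background phase offsets
#'
#' Fits, per velocity component, a polynomial of the given order in the
#' voxel-center coordinates (x, y, z) to the time-averaged velocity over a
#' user-supplied static-tissue mask by least squares, and subtracts the
#' fitted surface from every frame. Exact for offsets that are polynomial of
#' the stated order.
#'
#' @param field a [VelocityField-class].
#' @param static_mask logical (nx, ny, nz) array marking static voxels.
#' @param order polynomial order, 0, 1 or 2.
#' @return A corrected [VelocityField-class].
#' @export
correctBackgroundPhase <- function(field, static_mask, order = 1) {
  stopifnot(is(field, "VelocityField"))
  d <- dim(field@values)
  if (!identical(dim(static_mask), d[1:3])) .stopf("static_mask must match the grid")
  if (!any(static_mask)) .stopf("static_mask is empty")
  if (!order %in% 0:2) .stopf("order must be 0, 1 or 2")
  co <- .coordArrays(d[1:3], field@spacing)
  basisOf <- function(x, y, z) {
    B <- cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z)
    nterms <- switch(as.character(order), "0" = 1L, "1" = 4L, "2" = 10L)
    B[, seq_len(nterms), drop = FALSE]
  }
  sel <- which(static_mask)
  Bm <- basisOf(co$x[sel], co$y[sel], co$z[sel])
  if (length(sel) < ncol(Bm))
    .stopf("static mask has %d voxels, fewer than the %d polynomial terms",
           length(sel), ncol(Bm))
  Ball <- basisOf(as.numeric(co$x), as.numeric(co$y), as.numeric(co$z))
  vals <- field@values
  for (cmp in 1:3) {
    avg <- apply(vals[, , , cmp, , drop = FALSE], 1:3, mean)
    beta <- qr.solve(Bm, avg[sel])
    fit <- array(Ball %*% beta, dim = d[1:3])
    for (t in seq_len(d[5])) vals[, , , cmp, t] <- vals[, , , cmp, t] - fit
  }
  initialize(field, values = vals)
}

#' Denoise a velocity field (pluggable)
#'
#' The denoising slot of the preprocessing chain, honoring the contract that
#' grid shape, spacing, and frame count never change. \code{method = "none"}
#' is the identity; \code{method = "gaussian"} applies isotropic spatial
#' Gaussian smoothing of the stated sd (in voxels) independently per frame
#' and component, with truncated-kernel renormalization at the boundaries
#' (constants preserved everywhere, linear fields preserved in the interior).
#'
#' @param field a [VelocityField-class].
#' @param method \code{"none"} or \code{"gaussian"}.
#' @param sd Gaussian sd in voxels (for \code{method = "gaussian"}).
#' @return A [VelocityField-class] of identical geometry.
#' @export
denoiseVelocity <- function(field, method = c("none", "gaussian"), sd = 1) {
  stopifnot(is(field, "VelocityField"))
  method <- match.arg(method)
  if (method == "none") return(field)
  if (sd <= 0) .stopf("gaussian sd must be positive")
  d <- dim(field@values)
  Ms <- lapply(1:3, function(a) .gaussConvMatrix(d[a], sd))
  vals <- field@values
  for (t in seq_len(d[5])) for (cmp in 1:3) {
    a <- vals[, , , cmp, t]
    for (ax in 1:3) a <- .applyAlongAxis(a, Ms[[ax]], ax)
    vals[, , , cmp, t] <- a
  }
  initialize(field, values = vals)
}

#' Define a valve plane
#'
#' A static plane with a circular integration aperture, on which
#' transvalvular flux is integrated.
#'
#' @param origin mm point on the plane.
#' @param normal plane normal (normalized internally).
#' @param radius aperture radius, mm (> 0).
#' @return A list of class \code{"ValvePlane"}.
#' @export
valvePlane <- function(origin, normal, radius) {
  if (radius <= 0) .stopf("radius must be positive")
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) .stopf("normal must be nonzero")
  structure(list(origin = as.numeric(origin), normal = as.numeric(normal) / nrm,
                 radius = radius), class = "ValvePlane")
}

#' Transvalvular flow volumes by plane flux integration
#'
#' Per frame, samples the velocity by trilinear interpolation on a uniform
#' raster over the circular aperture (raster pitch a fixed fraction of the
#' voxel size), integrates the normal velocity to an instantaneous flux Q(t)
#' in mL/s, and accumulates forward volume \code{sum_t max(Q,0)*dt} and
#' reverse volume \code{sum_t max(-Q,0)*dt} over the cycle. The regurgitant
#' fraction is reverse/forward (NA when forward is zero) and the indexed
#' regurgitant volume divides reverse volume by BSA.
#'
#' @param field a [VelocityField-class].
#' @param plane a \code{"ValvePlane"} from [valvePlane()].
#' @param bsa body surface area in m^2 (for the indexed volume); NA to skip.
#' @param pitch_frac raster pitch as a fraction of the smallest voxel size
#'   (default 1/4).
#' @return A list of class \code{"FlowVolumes"}: \code{forward_volume},
#'   \code{reverse_volume}, \code{net_volume} (mL/cycle),
#'   \code{regurgitant_fraction}, \code{prvi} (mL/cycle/m^2), and the
#'   per-frame flux trace \code{flux_ml_s}.
#' @export
computeTransvalvularVolumes <- function(field, plane, bsa = NA_real_,
                                        pitch_frac = 0.25) {
  stopifnot(is(field, "VelocityField"), inherits(plane, "ValvePlane"))
  d <- dim(field@values)
  sp <- field@spacing
  pitch <- pitch_frac * min(sp)
  nrm <- plane$normal
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  g <- seq(-plane$radius, plane$radius, by = pitch)
  ab <- expand.grid(a = g, b = g)
  ab <- ab[ab$a^2 + ab$b^2 <= plane$radius^2, ]
  pts <- outer(ab$a, e1) + outer(ab$b, e2)
  pts <- sweep(pts, 2, plane$origin, `+`)
  idx <- sweep(pts, 2, sp, `/`) + 1
  if (any(idx < 1) || any(sweep(idx, 2, d[1:3], `>`)))
    .stopf("valve-plane aperture extends outside the grid")
  dt_s <- field@frameDuration / 1000
  cell_mm2 <- pitch^2
  flux <- numeric(d[5])
  for (t in seq_len(d[5])) {
    vn <- numeric(nrow(idx))
    for (cmp in 1:3)
      vn <- vn + nrm[cmp] * .trilinear(field@values[, , , cmp, t], idx)
    # cm/s * mm^2 = 0.01 mL/s
    flux[t] <- sum(vn) * cell_mm2 * 0.01
  }
  forward <- sum(pmax(flux, 0)) * dt_s
  reverse <- sum(pmax(-flux, 0)) * dt_s
  structure(list(forward_volume = forward, reverse_volume = reverse,
                 net_volume = forward - reverse,
                 regurgitant_fraction = if (forward > 0) reverse / forward else NA_real_,
                 prvi = if (is.na(bsa)) NA_real_ else reverse / bsa,
                 flux_ml_s = flux),
            class = "FlowVolumes")
}
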