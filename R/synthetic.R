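# Synthetic acquisition: the degradations present in measured focal series
# (photon noise, plane-to-plane source flicker, stage jitter) and the
# matching corrections (registration, deflicker), so the analysis chain can
# be exercised end to end on data with known ground truth.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Acquisition-noise description
#'
#' Per-plane degradations applied by [corrupt_stack()]: a multiplicative
#' source-flicker factor, an integer-pixel stage-jitter shift, and Poisson
#' photon noise at `photon_scale` expected counts per unit intensity.
#' Factors and shifts may be supplied explicitly or drawn reproducibly from
#' `seed` (flicker log-normal with standard deviation `flicker_sd`; shifts
#' uniform integers in \[-jitter_max, jitter_max\]).
#'
#' @param n_planes Number of stack planes.
#' @param photon_scale Expected photon counts per unit intensity (> 0).
#' @param flicker Optional explicit per-plane factors (> 0).
#' @param jitter Optional explicit n x 2 integer matrix of (dy, dx) shifts.
#' @param flicker_sd Log-scale flicker standard deviation (default 5%).
#' @param jitter_max Maximum |shift| in pixels.
#' @param seed RNG seed for drawing the factors and for the photon noise.
#' @return Object of class `acquisition_noise`.
#' @export
acquisition_noise <- function(n_planes, photon_scale = 1e4,
                              flicker = NULL, jitter = NULL,
                              flicker_sd = 0.05, jitter_max = 3, seed = 1) {
  stopifnot(photon_scale > 0, n_planes >= 1)
  if (is.null(flicker) || is.null(jitter)) {
    drawn <- with_seed(seed, list(
      flicker = exp(stats::rnorm(n_planes, 0, flicker_sd)),
      jitter = matrix(sample(seq(-jitter_max, jitter_max),
                             2 * n_planes, replace = TRUE), ncol = 2)))
    if (is.null(flicker)) flicker <- drawn$flicker
    if (is.null(jitter)) jitter <- drawn$jitter
  }
  jitter <- matrix(as.integer(jitter), ncol = 2)
  stopifnot(length(flicker) == n_planes, all(flicker > 0),
            nrow(jitter) == n_planes)
  structure(list(photon_scale = photon_scale, flicker = flicker,
                 jitter = jitter, seed = seed),
            class = "acquisition_noise")
}

circ_shift <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
}

#' Corrupt a clean stack with acquisition noise
#'
#' Applies, per plane: the integer-pixel jitter shift (circular), the
#' multiplicative flicker factor, and Poisson counting at
#' `photon_scale` expected counts per unit intensity (the returned
#' intensities are counts / photon_scale). Fully reproducible from the
#' noise object's seed.
#'
#' @param stack A clean, background-normalized [image_stack].
#' @param noise An [acquisition_noise] with matching plane count.
#' @return A corrupted [image_stack] (normalization `"raw"`).
#' @export
corrupt_stack <- function(stack, noise) {
  stopifnot(inherits(stack, "image_stack"), inherits(noise, "acquisition_noise"))
  d <- dim(stack$intensities)
  if (length(noise$flicker) != d[1]) stop("noise plane count mismatch")
  if (any(abs(noise$jitter[, 1]) > d[2] / 4) ||
      any(abs(noise$jitter[, 2]) > d[3] / 4)) {
    stop("jitter shifts exceed a quarter of the field of view")
  }
  out <- stack$intensities
  for (i in seq_len(d[1])) {
    pl <- circ_shift(stack$intensities[i, , ], noise$jitter[i, 1], noise$jitter[i, 2])
    out[i, , ] <- pl * noise$flicker[i]
  }
  counts <- with_seed(noise$seed + 1L, {
    stats::rpois(length(out), lambda = pmax(out, 0) * noise$photon_scale)
  })
  out[] <- counts / noise$photon_scale
  image_stack(out, stack$voxel, "raw", z_planes = stack$z_planes)
}

#' Register a stack by integer-pixel cross-correlation
#'
#' Aligns every plane to the central plane by the argmax of the circular
#' cross-correlation (translation only, integer pixels) and applies the
#' inverse shifts. Planes without usable contrast (near-constant) produce a
#' warning and are left unshifted.
#'
#' @param stack An [image_stack].
#' @return List with `stack` (aligned) and `shifts` (n x 2 matrix: the
#'   detected (dy, dx) displacement of each plane relative to the reference
#'   plane; the inverse shift was applied). For a stack corrupted with known
#'   jitter these equal jitter minus the reference plane's jitter.
#' @export
register_stack <- function(stack) {
  d <- dim(stack$intensities)
  if (d[1] < 2) stop("need at least 2 planes to register")
  ref_i <- (d[1] + 1) %/% 2
  ref <- stack$intensities[ref_i, , ]
  Fr <- stats::fft(ref - mean(ref))
  out <- stack$intensities
  shifts <- matrix(0L, d[1], 2)
  for (i in seq_len(d[1])) {
    pl <- stack$intensities[i, , ]
    if (stats::sd(pl) < 1e-12 * (abs(mean(pl)) + 1e-12)) {
      warning(sprintf("plane %d is featureless; leaving it unshifted", i))
      next
    }
    cc <- Re(stats::fft(Fr * Conj(stats::fft(pl - mean(pl))), inverse = TRUE))
    m <- arrayInd(which.max(cc), dim(cc))
    dy <- m[1] - 1L; dx <- m[2] - 1L
    if (dy > d[2] / 2) dy <- dy - d[2]
    if (dx > d[3] / 2) dx <- dx - d[3]
    # (-dy, -dx) is the displacement of this plane relative to the reference;
    # shifting by (dy, dx) removes it
    shifts[i, ] <- c(-dy, -dx)
    out[i, , ] <- circ_shift(pl, dy, dx)
  }
  list(stack = image_stack(out, stack$voxel, stack$normalization,
                           z_planes = stack$z_planes),
       shifts = shifts)
}

#' Remove plane-to-plane source flicker
#'
#' Rescales every plane so that its pixel sum equals the stack-median plane
#' sum (the absorbed flux of a small object is conserved across defocus, so
#' plane sums of a flicker-free stack are equal).
#'
#' @param stack An [image_stack].
#' @return A deflickered [image_stack].
#' @export
deflicker_stack <- function(stack) {
  d <- dim(stack$intensities)
  sums <- apply(stack$intensities, 1, sum)
  if (any(sums <= 0)) stop("cannot deflicker: plane with non-positive sum")
  target <- stats::median(sums)
  out <- stack$intensities * rep(target / sums, times = d[2] * d[3])
  # rep() above recycles along z only because z is the first dimension
  image_stack(out, stack$voxel, stack$normalization, z_planes = stack$z_planes)
}
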