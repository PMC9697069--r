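#' Parameters for the synthetic nerve cross-section generator
#'
#' Emulates a toluidine-blue-stained sciatic-nerve cross-section as pure
#' geometry: non-overlapping myelinated fibers, each an outer (fiber)
#' polygon with a nested inner (axon) polygon. Fiber diameters are
#' lognormal; g-ratios are normal truncated to (0, 1). `degeneration_level`
#' moves the field from healthy (0) to degenerated (1): it adds smooth
#' radial boundary irregularity (amplitude proportional to the level) and
#' thins the myelin by inflating the g-ratio toward 1. At level 0 every
#' boundary is a regular 64-gon circle approximation.
#'
#' @param n_fibers number of fibers to place.
#' @param fiber_diameter_mean_um,fiber_diameter_sd_um mean and SD of the
#'   fiber (outer) diameter distribution in microns (lognormal).
#' @param g_ratio_mean,g_ratio_sd normal parameters of the healthy g-ratio,
#'   truncated to (0, 1).
#' @param degeneration_level in `[0, 1]`.
#' @param field_size_um edge of the square field (microns).
#' @param seed integer RNG seed.
#' @return an object of class `nerve_synth_params`.
#' @export
nerve_synth_params <- function(n_fibers = 100,
                               fiber_diameter_mean_um = 8,
                               fiber_diameter_sd_um = 2,
                               g_ratio_mean = 0.6,
                               g_ratio_sd = 0.05,
                               degeneration_level = 0,
                               field_size_um = 120,
                               seed = 1) {
  assert_that(is_count(n_fibers) && n_fibers >= 1, "n_fibers must be >= 1")
  assert_that(fiber_diameter_mean_um > 0 && fiber_diameter_sd_um >= 0,
              "diameter parameters must be positive")
  assert_that(g_ratio_mean > 0 && g_ratio_mean < 1,
              "g_ratio_mean must lie in (0, 1)")
  assert_that(is_prob(degeneration_level),
              "degeneration_level must lie in [0, 1]")
  structure(list(
    n_fibers = as.integer(n_fibers),
    fiber_diameter_mean_um = fiber_diameter_mean_um,
    fiber_diameter_sd_um = fiber_diameter_sd_um,
    g_ratio_mean = g_ratio_mean,
    g_ratio_sd = g_ratio_sd,
    degeneration_level = degeneration_level,
    field_size_um = field_size_um,
    seed = as.integer(seed)
  ), class = "nerve_synth_params")
}

# Smooth periodic radial perturbation: low-order Fourier modes, amplitude a
# (fraction of the radius), zero-mean over the circle.
#' @noRd
radial_profile <- function(theta, a) {
  if (a == 0) return(rep(1, length(theta)))
  modes <- 2:5
  coef_c <- stats::rnorm(length(modes))
  coef_s <- stats::rnorm(length(modes))
  norm <- sqrt(sum(coef_c^2 + coef_s^2))
  pert <- colSums(coef_c * t(outer(theta, modes, function(t, m) cos(m * t))) +
                  coef_s * t(outer(theta, modes, function(t, m) sin(m * t)))) / norm
  pmax(1 + a * pert, 0.2)
}

#' Generate a synthetic nerve cross-section
#'
#' Fibers are placed by rejection sampling of centers (no overlap, inside
#' the field); if the requested count does not fit at the requested density
#' within the attempt budget, the shortfall is reported with a warning and
#' fewer fibers are returned — never an infinite loop. Deterministic given
#' the seed.
#'
#' @param params a [nerve_synth_params()].
#' @param n_vertices vertices per boundary polygon (default 64).
#' @param max_attempts_per_fiber rejection-sampling budget per fiber.
#' @return list of [fiber_geometry()] objects.
#' @export
generate_nerve_cross_section <- function(params, n_vertices = 64,
                                         max_attempts_per_fiber = 200) {
  assert_that(inherits(params, "nerve_synth_params"),
              "`params` must come from nerve_synth_params()")
  withr::with_seed(params$seed, {
    L <- params$field_size_um
    lvl <- params$degeneration_level
    # lognormal with the requested mean/SD on the natural scale
    m <- params$fiber_diameter_mean_um
    s <- params$fiber_diameter_sd_um
    if (s > 0) {
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
    } else {
      sdlog <- 0; meanlog <- log(m)
    }
    theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]

    placed_xy <- matrix(numeric(0), ncol = 2)
    placed_r <- numeric(0)
    fibers <- list()
    for (i in seq_len(params$n_fibers)) {
      d <- if (sdlog > 0) stats::rlnorm(1, meanlog, sdlog) else m
      r <- d / 2
      ok <- FALSE
      for (att in seq_len(max_attempts_per_fiber)) {
        cx <- stats::runif(1, r, L - r)
        cy <- stats::runif(1, r, L - r)
        # margin covers the worst-case outer radial perturbation (<= 2x the
        # normalized Fourier amplitude, i.e. 0.25 * level on the radius)
        margin <- 1.02 + 0.25 * lvl
        if (length(placed_r) == 0 ||
            all(sqrt((placed_xy[, 1] - cx)^2 + (placed_xy[, 2] - cy)^2) >
                  (placed_r + r) * margin)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) next
      # healthy g-ratio: normal truncated to (0, 1)
      g <- if (params$g_ratio_sd > 0) {
        repeat {
          g_try <- stats::rnorm(1, params$g_ratio_mean, params$g_ratio_sd)
          if (g_try > 0 && g_try < 1) break
        }
        g_try
      } else params$g_ratio_mean
      # myelin thinning with degeneration: g drifts toward 1
      g <- g + lvl * (1 - g) * 0.6

      amp <- 0.25 * lvl
      outer_prof <- radial_profile(theta, amp / 2)
      inner_prof <- radial_profile(theta, amp)
      r_out <- r * outer_prof
      r_in <- pmin(g * r * inner_prof, 0.98 * r_out)
      outer_poly <- cbind(cx + r_out * cos(theta), cy + r_out * sin(theta))
      inner_poly <- cbind(cx + r_in * cos(theta), cy + r_in * sin(theta))
      fibers[[length(fibers) + 1]] <- fiber_geometry(
        sprintf("fiber%03d", length(fibers) + 1), outer_poly, inner_poly)
      placed_xy <- rbind(placed_xy, c(cx, cy))
      placed_r <- c(placed_r, r)
    }
    if (length(fibers) < params$n_fibers) {
      warning("placed ", length(fibers), " of ", params$n_fibers,
              " fibers (density too high for the field)", call. = FALSE)
    }
    fibers
  })
}

#' Rasterize fiber geometry to an integer label mask
#'
#' Lossy export companion to the exact polygon pathway. Fiber `k` is
#' encoded as axon label `2k` and myelin label `2k + 1`. Pixel centers are
#' classified by point-in-polygon tests against the axon and fiber
#' boundaries.
#'
#' @param fibers list of [fiber_geometry()] objects.
#' @param field_size_um field edge in microns.
#' @param pixel_size_um physical pixel edge (microns); smaller = finer mask.
#' @return integer matrix of labels (0 = background) with attribute
#'   `pixel_size_um`.
#' @export
rasterize_fibers <- function(fibers, field_size_um, pixel_size_um = 0.25) {
  npx <- ceiling(field_size_um / pixel_size_um)
  mask <- matrix(0L, npx, npx)
  centers <- (seq_len(npx) - 0.5) * pixel_size_um
  for (k in seq_along(fibers)) {
    f <- fibers[[k]]
    bb_x <- range(f$outer[, 1]); bb_y <- range(f$outer[, 2])
    ix <- which(centers >= bb_x[1] - pixel_size_um &
                centers <= bb_x[2] + pixel_size_um)
    iy <- which(centers >= bb_y[1] - pixel_size_um &
                centers <= bb_y[2] + pixel_size_um)
    if (length(ix) == 0 || length(iy) == 0) next
    pts <- cbind(rep(centers[ix], times = length(iy)),
                 rep(centers[iy], each = length(ix)))
    in_fiber <- mgcv::in.out(rbind(f$outer, f$outer[1, ]), pts)
    in_axon <- mgcv::in.out(rbind(f$inner, f$inner[1, ]), pts)
    lab <- integer(nrow(pts))
    lab[in_fiber] <- 2L * k + 1L
    lab[in_axon] <- 2L * k
    sel <- lab > 0L
    if (any(sel)) {
      rows <- rep(ix, times = length(iy))[sel]
      cols <- rep(iy, each = length(ix))[sel]
      mask[cbind(rows, cols)] <- lab[sel]
    }
  }
  attr(mask, "pixel_size_um") <- pixel_size_um
  mask
}
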