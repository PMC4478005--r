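# Synthetic otolith outline generator. Emulates the statistical structure
# the analysis assumes — populations ordered along a coast whose localized
# outline deformations grow linearly with along-coast position, smooth
# individual noise that shrinks with age, and fish length coupled to age —
# so that every downstream stage can be exercised with known truth.

#' Simulation configuration
#'
#' Builds the parameter list for [generateDataset()]. Defaults describe a
#' herring-like survey: 12 populations evenly spread over a 2200 km
#' synthetic coast, two deformation sites on the outline — a notch near
#' 10 deg (excisura-major-like, negative sign) and a bump near 175 deg
#' (rostrum/excisura-minor region, positive sign) — whose amplitude grows
#' by 2.5% of the mean radius per 1000 km of coast, smooth individual
#' radial noise of 2% shrinking with age, ages 3--12 and total length
#' rising linearly with age.
#'
#' @param n_populations number of populations (default 12).
#' @param n_per_population specimens per population (default 30).
#' @param coast_positions km along the coast, one per population
#'   (default evenly spaced on [0, 2200]).
#' @param deformation_sites data.frame with columns \code{center}
#'   (degrees), \code{width} (degrees, Gaussian SD) and \code{sign}.
#' @param gradient_slope fractional radial amplitude per 1000 km.
#' @param noise_sd SD of the smooth individual radial noise, as a
#'   fraction of the mean radius, at the youngest age.
#' @param noise_harmonics number of circular harmonics in the noise;
#'   low-order harmonics keep outlines smooth and simple.
#' @param age_range inclusive integer age span (default 3--12).
#' @param age_variance_slope per-year multiplier slope on the noise SD
#'   (negative = older fish less variable); the multiplier is floored at
#'   0.2.
#' @param length_age_model numeric (intercept, slope, sd) of length in cm
#'   on age in years.
#' @param base_radius mean radius r0 (arbitrary units; 1 by default).
#' @param n_angles outline sampling resolution (power of two).
#' @param rng_seed integer seed; all generator randomness flows from it.
#' @return list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_populations = 12L,
                      n_per_population = 30L,
                      coast_positions = NULL,
                      deformation_sites = data.frame(
                        center = c(10, 175), width = c(20, 15),
                        sign = c(-1, 1)),
                      gradient_slope = 0.025,
                      noise_sd = 0.02,
                      noise_harmonics = 8L,
                      age_range = c(3L, 12L),
                      age_variance_slope = -0.08,
                      length_age_model = c(intercept = 24, slope = 0.9,
                                           sd = 1.5),
                      base_radius = 1,
                      n_angles = 512L,
                      rng_seed = 1L) {
  if (is.null(coast_positions))
    coast_positions <- seq(0, 2200, length.out = n_populations)
  stopifnot(length(coast_positions) == n_populations,
            isPowerOfTwo(n_angles),
            all(deformation_sites$center >= 0 & deformation_sites$center < 360),
            all(deformation_sites$width > 0),
            noise_sd >= 0, gradient_slope >= 0, base_radius > 0,
            age_range[1] >= 1L, age_range[2] >= age_range[1])
  cfg <- list(n_populations = as.integer(n_populations),
              n_per_population = as.integer(n_per_population),
              coast_positions = as.numeric(coast_positions),
              deformation_sites = deformation_sites,
              gradient_slope = gradient_slope, noise_sd = noise_sd,
              noise_harmonics = as.integer(noise_harmonics),
              age_range = as.integer(age_range),
              age_variance_slope = age_variance_slope,
              length_age_model = length_age_model,
              base_radius = base_radius, n_angles = as.integer(n_angles),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "SimConfig"
  cfg
}

# Deterministic deformation field of one population: fractional radius
# offset at each angle (degrees), sum of Gaussian bumps with circular
# angular distance.
.deformation <- function(anglesDeg, sites, amplitude) {
  out <- numeric(length(anglesDeg))
  for (i in seq_len(nrow(sites))) {
    d <- angleDiff(anglesDeg, sites$center[i])
    out <- out + amplitude * sites$sign[i] * exp(-d^2 / (2 * sites$width[i]^2))
  }
  out
}

# Smooth circular noise with spatial SD ~ sdTarget: a mixture of the first
# `harmonics` Fourier modes with random amplitudes and phases.
.smoothNoise <- function(anglesRad, sdTarget, harmonics) {
  if (sdTarget <= 0) return(numeric(length(anglesRad)))
  eps <- numeric(length(anglesRad))
  amp <- sdTarget / sqrt(harmonics)
  for (h in seq_len(harmonics)) {
    ab <- rnorm(2L, sd = amp)
    eps <- eps + ab[1] * cos(h * anglesRad) + ab[2] * sin(h * anglesRad)
  }
  eps
}

#' Generate a synthetic otolith shape dataset
#'
#' Draws \code{n_populations x n_per_population} specimens. Each specimen's
#' radius function is
#' \deqn{r(\theta) = r_0 [1 + \sum_s a_{p,s} e^{-(\theta - c_s)^2 / 2 w_s^2}
#'   + \epsilon(\theta)]}
#' with site amplitude \code{a_[p,s] = gradient_slope * coast_km_p / 1000 *
#' sign_s} and smooth circular noise whose SD is \code{noise_sd * max(1 +
#' age_variance_slope * (age - age_min), 0.2)}. Ages are uniform on the age
#' range, lengths follow the linear length--age model, and populations are
#' laid out south-to-north along a synthetic meridional coastline so the
#' geographic stage can be exercised end to end. Everything is reproducible
#' from \code{rng_seed}.
#'
#' @param config a \code{SimConfig} from [simConfig()].
#' @return list with \code{specimens} (metadata data.frame), \code{radii}
#'   (specimens x n_angles matrix, rows named by specimen id),
#'   \code{outlines} (named list of (x, y) matrices), \code{coastline}
#'   (waypoint data.frame for [coastlineDistances()]), and \code{truth}
#'   (per-population site amplitudes, coast positions and the config).
#' @export
generateDataset <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(config$rng_seed, {
    nP <- config$n_populations
    nS <- config$n_per_population
    n <- config$n_angles
    thetaDeg <- 360 * (seq_len(n) - 1L) / n
    thetaRad <- thetaDeg * pi / 180
    popIds <- sprintf("P%02d", seq_len(nP))
    # synthetic coast: due-north meridian at 5 deg E starting at 58 deg N
    latPerKm <- 1 / (pi / 180 * .EARTH_RADIUS_KM)
    coastKm <- seq(0, max(config$coast_positions), length.out = 64L)
    coastline <- data.frame(lat = 58 + coastKm * latPerKm, lon = 5)
    popLat <- 58 + config$coast_positions * latPerKm
    amp <- config$gradient_slope * config$coast_positions / 1000
    specimens <- list()
    radii <- matrix(NA_real_, nP * nS, n)
    row <- 0L
    ages <- config$age_range[1]:config$age_range[2]
    lam <- config$length_age_model
    for (p in seq_len(nP)) {
      defo <- .deformation(thetaDeg, config$deformation_sites, amp[p])
      for (s in seq_len(nS)) {
        row <- row + 1L
        age <- sample(ages, 1L)
        sdMult <- max(1 + config$age_variance_slope * (age - ages[1]), 0.2)
        eps <- .smoothNoise(thetaRad, config$noise_sd * sdMult,
                            config$noise_harmonics)
        r <- config$base_radius * (1 + defo + eps)
        if (any(r <= 0))
          stop("non-positive radius generated; reduce gradient_slope or ",
               "noise_sd")
        radii[row, ] <- r
        specimens[[row]] <- data.frame(
          specimen_id = sprintf("%s_F%03d", popIds[p], s),
          population_id = popIds[p],
          latitude = popLat[p], longitude = 5,
          length_cm = max(lam[1] + lam[2] * age + rnorm(1L, sd = lam[3]), 5),
          age_years = age,
          year = 2012L)
      }
    }
    specimens <- do.call(rbind, specimens)
    rownames(radii) <- specimens$specimen_id
    outlines <- lapply(seq_len(nrow(radii)),
                       function(i) profileToOutline(radii[i, ]))
    names(outlines) <- specimens$specimen_id
    list(specimens = specimens, radii = radii, outlines = outlines,
         coastline = coastline,
         truth = list(population_id = popIds,
                      coast_positions = config$coast_positions,
                      site_amplitude = amp,
                      sites = config$deformation_sites,
                      config = config))
  })
}

#' Rasterize an outline into a synthetic grayscale image
#'
#' Renders a filled white-on-black shape with a soft (anti-aliased) one
#' pixel edge, scaled and centred to fit the frame. The fill is radial:
#' a pixel is inside when its distance from the outline centroid is below
#' the boundary radius at the pixel's angle, so the outline must be
#' star-shaped about its centroid (all outlines from [generateDataset()]
#' are, by the positive-radius construction).
#'
#' @param outline two-column (x, y) vertex matrix.
#' @param size_px image side length in pixels (default 1024).
#' @param fill fraction of the half-frame spanned by the largest radius
#'   (default 0.9, leaving a 10% margin).
#' @return numeric [x, y] matrix in [0, 1] suitable for [binarizeImage()].
#' @export
rasterizeOutline <- function(outline, size_px = 1024L, fill = 0.9) {
  p <- as.matrix(outline)
  if (nrow(p) < 3L) stop("empty or degenerate outline")
  prof <- radialProfile(p, nAngles = 2^ceiling(log2(max(64L, nrow(p)))))
  rb <- profileRadii(prof)
  scale <- fill * (size_px / 2 - 1) / max(rb)
  rb <- rb * scale
  ctr <- (size_px + 1) / 2
  gx <- matrix(seq_len(size_px) - ctr, size_px, size_px)
  gy <- matrix(seq_len(size_px) - ctr, size_px, size_px, byrow = TRUE)
  rPix <- sqrt(gx^2 + gy^2)
  aPix <- atan2(gy, gx) %% (2 * pi)
  nb <- length(rb)
  # linear interpolation of the boundary radius around the circle
  idx <- aPix / (2 * pi) * nb
  i0 <- floor(idx)
  w <- idx - i0
  rBound <- (1 - w) * rb[(i0 %% nb) + 1L] + w * rb[((i0 + 1) %% nb) + 1L]
  img <- pmin(pmax(rBound - rPix + 0.5, 0), 1)
  img
}
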