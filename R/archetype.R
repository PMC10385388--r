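#' Species reflectance archetypes
#'
#' A species archetype is a parametric description of one grassland species'
#' reflectance curve: a low visible continuum, Gaussian chlorophyll absorption
#' wells (blue ~490 nm, red ~670 nm), a Gaussian green reflectance peak
#' (~550 nm), a logistic red-edge transition to a near-infrared plateau, and a
#' leaf-water absorption band near 960 nm.  Phase modifiers adjust well
#' depths, red-edge position and plateau level per acquisition phase
#' (year x month), emulating phenology: in August (maturity) chlorophyll
#' declines, so absorption wells are shallower and the red edge shifts to
#' shorter wavelengths relative to June (growth).  On top of the phase
#' effects, individual samples vary in brightness (illumination/geometry),
#' chlorophyll content (scaling the pigment wells and shifting the red edge)
#' and water content (scaling the 960 nm band).
#'
#' @param species_name species label (character scalar).
#' @param baseline_continuum visible continuum reflectance, in `[0,1]`.
#' @param absorption_features list of numeric triples
#'   `c(center_nm, width_nm, depth)` for the pigment wells; each subtracts
#'   `depth * exp(-(lambda-center)^2 / (2 width^2))`.
#' @param green_peak numeric triple `c(center_nm, width_nm, height)`.
#' @param red_edge numeric pair `c(inflection_nm, steepness_nm)`; the logistic
#'   transition from the continuum to the NIR plateau.
#' @param nir_plateau NIR plateau reflectance, in `[0,1]`.
#' @param water_band numeric triple `c(center_nm, width_nm, depth)` for the
#'   leaf-water absorption well (~960 nm).
#' @param phase_modifiers named list with exactly the four entries
#'   `"2020-June"`, `"2020-August"`, `"2021-June"`, `"2021-August"`, each a
#'   list with `depth_scale` (pigment wells), `redge_shift` (nm),
#'   `plateau_scale`, `water_scale` and `amplitude`.
#' @param noise_sigma per-band Gaussian noise SD (reflectance units).
#' @param amplitude_sd SD of the per-sample multiplicative brightness factor
#'   (illumination/geometry variation between ROIs).
#' @param chlorophyll_sd SD of the per-sample chlorophyll factor; the factor
#'   scales the pigment wells and shifts the red edge by
#'   `edge_coupling * (factor - 1)` nm.
#' @param water_sd SD of the per-sample water factor scaling `water_band`.
#' @param offset_sd SD of the per-sample additive baseline offset
#'   (radiometric calibration residual, reflectance units).
#' @param tilt_sd SD of the per-sample additive spectral tilt; the tilt basis
#'   ramps linearly from -1 at 400 nm to +1 at 1000 nm.
#' @param outlier_rate fraction of samples whose brightness factor is instead
#'   drawn from `U(0.5, 1.5)` — shadowed or specular ROIs whose overall level
#'   is unreliable while the spectral shape is preserved.
#' @param edge_coupling red-edge shift (nm) per unit chlorophyll-factor
#'   deviation.
#' @return object of class `"species_archetype"`.
#' @seealso [default_archetypes()], [simulate_spectrum()]
#' @export
species_archetype <- function(species_name,
                              baseline_continuum,
                              absorption_features,
                              green_peak,
                              red_edge,
                              nir_plateau,
                              water_band = c(960, 28, 0),
                              phase_modifiers = default_phase_modifiers(),
                              noise_sigma = 0.015,
                              amplitude_sd = 0.02,
                              chlorophyll_sd = 0.05,
                              water_sd = 0.05,
                              offset_sd = 0.01,
                              tilt_sd = 0.008,
                              outlier_rate = 0,
                              edge_coupling = 25) {
  stopifnot(is.character(species_name), length(species_name) == 1L)
  chk01 <- function(x, what) {
    if (any(x < 0 | x > 1))
      stop(sprintf("species_archetype '%s': %s must lie in [0,1]", species_name, what))
  }
  chk01(baseline_continuum, "baseline_continuum")
  chk01(nir_plateau, "nir_plateau")
  for (w in absorption_features) {
    if (length(w) != 3L) stop("each absorption feature is c(center, width, depth)")
    if (w[2] <= 0) stop("absorption well width must be strictly positive")
    chk01(w[3], "well depth")
  }
  if (length(water_band) != 3L || water_band[2] <= 0)
    stop("water_band is c(center, width > 0, depth)")
  chk01(water_band[3], "water band depth")
  if (length(green_peak) != 3L || green_peak[2] <= 0)
    stop("green_peak is c(center, width > 0, height)")
  chk01(green_peak[3], "green peak height")
  if (length(red_edge) != 2L || red_edge[2] <= 0)
    stop("red_edge is c(inflection, steepness > 0)")
  if (noise_sigma < 0 || amplitude_sd < 0 || chlorophyll_sd < 0 ||
      water_sd < 0 || offset_sd < 0 || tilt_sd < 0)
    stop("noise and variability SDs must be non-negative")
  if (outlier_rate < 0 || outlier_rate >= 1)
    stop("outlier_rate must lie in [0, 1)")
  need <- phase_keys()
  if (!setequal(names(phase_modifiers), need) || length(phase_modifiers) != 4L)
    stop("phase_modifiers must have exactly the entries: ", paste(need, collapse = ", "))
  structure(list(species_name = species_name,
                 baseline_continuum = baseline_continuum,
                 absorption_features = absorption_features,
                 green_peak = green_peak,
                 red_edge = red_edge,
                 nir_plateau = nir_plateau,
                 water_band = water_band,
                 phase_modifiers = phase_modifiers[need],
                 noise_sigma = noise_sigma,
                 amplitude_sd = amplitude_sd,
                 chlorophyll_sd = chlorophyll_sd,
                 water_sd = water_sd,
                 offset_sd = offset_sd,
                 tilt_sd = tilt_sd,
                 outlier_rate = outlier_rate,
                 edge_coupling = edge_coupling),
            class = "species_archetype")
}

# The four acquisition phases, in canonical order.
phase_keys <- function() c("2020-June", "2020-August", "2021-June", "2021-August")

phase_key <- function(year, month) paste0(year, "-", month)

#' @export
print.species_archetype <- function(x, ...) {
  cat(sprintf("Species archetype '%s': continuum %.3f, NIR plateau %.3f, red edge %.0f nm\n",
              x$species_name, x$baseline_continuum, x$nir_plateau, x$red_edge[1]))
  invisible(x)
}

#' Default phenological phase modifiers
#'
#' August (maturity) shallows the chlorophyll wells, blue-shifts the red
#' edge, and slightly lowers the NIR plateau and leaf-water band relative to
#' June (growth); the second year carries small amplitude differences
#' (weather, soil moisture).
#'
#' @return named list of four phase-modifier lists.
#' @export
default_phase_modifiers <- function() {
  list(
    "2020-June"   = list(depth_scale = 1.00, redge_shift =  0, plateau_scale = 1.00,
                         water_scale = 1.00, amplitude = 1.00),
    "2020-August" = list(depth_scale = 0.82, redge_shift = -4, plateau_scale = 0.95,
                         water_scale = 0.90, amplitude = 1.00),
    "2021-June"   = list(depth_scale = 1.03, redge_shift =  1, plateau_scale = 1.02,
                         water_scale = 1.01, amplitude = 0.98),
    "2021-August" = list(depth_scale = 0.84, redge_shift = -3, plateau_scale = 0.97,
                         water_scale = 0.92, amplitude = 0.99)
  )
}

#' Default archetypes for the seven grassland species
#'
#' Deterministic parameter sets for the seven forage species of the study
#' design (four *Fabaceae* and three grasses).  The species differ in shape,
#' not merely in level: chlorophyll well depths, the green-peak position and
#' height, the red-edge inflection and slope, the NIR plateau and the
#' leaf-water band all vary, and several species share similar NIR levels
#' while differing in visible/edge shape (and vice versa), so no single band
#' separates all classes once per-sample brightness, chlorophyll and water
#' variability are added.
#'
#' @param noise_sigma per-band noise SD passed to every archetype.
#' @param amplitude_sd per-sample brightness jitter SD.
#' @param chlorophyll_sd per-sample chlorophyll-content SD.
#' @param water_sd per-sample water-content SD.
#' @param offset_sd per-sample additive baseline-offset SD.
#' @param tilt_sd per-sample additive spectral-tilt SD.
#' @param outlier_rate fraction of brightness-corrupted ROIs.
#' @return list of 7 [species_archetype()] objects.
#' @export
default_archetypes <- function(noise_sigma = 0.015, amplitude_sd = 0.02,
                               chlorophyll_sd = 0.05, water_sd = 0.05,
                               offset_sd = 0.01, tilt_sd = 0.008,
                               outlier_rate = 0) {
  # name, continuum, nir, blue(center width depth), red(center width depth),
  # green(center width height), red edge(nm steepness), water depth at 960 nm
  p <- list(
    list("Medicago sativa",        0.040, 0.52, c(490, 25, 0.030), c(672, 22, 0.120),
         c(552, 18, 0.100), c(718, 10.0), 0.090),
    list("Medicago ruthenica",     0.100, 0.40, c(487, 22, 0.020), c(668, 19, 0.065),
         c(545, 15, 0.150), c(707, 13.5), 0.035),
    list("Elymus canadensis",      0.022, 0.85, c(494, 30, 0.020), c(676, 26, 0.045),
         c(561, 21, 0.055), c(727,  8.5), 0.150),
    list("Hordeum brevisubulatum", 0.140, 0.15, c(489, 24, 0.050), c(665, 18, 0.140),
         c(541, 14, 0.075), c(703, 14.5), 0.105),
    list("Medicago varia",         0.060, 0.64, c(492, 27, 0.035), c(671, 24, 0.090),
         c(550, 17, 0.175), c(714, 11.0), 0.050),
    list("Onobrychis viciaefolia", 0.045, 0.74, c(486, 23, 0.016), c(674, 20, 0.080),
         c(554, 20, 0.115), c(721, 13.0), 0.045),
    list("Bromus ciliatus",        0.110, 0.28, c(491, 28, 0.042), c(669, 23, 0.105),
         c(547, 16, 0.130), c(710,  9.0), 0.160)
  )
  lapply(p, function(a) {
    species_archetype(
      species_name        = a[[1]],
      baseline_continuum  = a[[2]],
      nir_plateau         = a[[3]],
      absorption_features = list(a[[4]], a[[5]]),
      green_peak          = a[[6]],
      red_edge            = a[[7]],
      water_band          = c(960, 28, a[[8]]),
      noise_sigma         = noise_sigma,
      amplitude_sd        = amplitude_sd,
      chlorophyll_sd      = chlorophyll_sd,
      water_sd            = water_sd,
      offset_sd           = offset_sd,
      tilt_sd             = tilt_sd,
      outlier_rate        = outlier_rate
    )
  })
}

# Validate a phase specification against the archetype's configured phases.
resolve_phase <- function(archetype, phase) {
  ph <- if (length(phase) == 2L) phase_key(phase[[1]], phase[[2]]) else as.character(phase)
  if (!ph %in% names(archetype$phase_modifiers))
    stop(sprintf("unknown phase '%s'; configured phases: %s",
                 ph, paste(names(archetype$phase_modifiers), collapse = ", ")))
  ph
}

# Spectrum matrix for n samples of one archetype at one phase, given the
# per-sample nuisance factors (brightness amp, chlorophyll chl, water wtr,
# additive baseline offset off and spectral tilt tlt) as length-n vectors.
# Returns an n x length(grid) matrix before band noise and clipping.
archetype_curves <- function(archetype, phase, grid, amp, chl, wtr,
                             off = 0 * amp, tlt = 0 * amp) {
  ph <- resolve_phase(archetype, phase)
  mods <- archetype$phase_modifiers[[ph]]
  lam <- as.numeric(grid)
  n <- length(amp)
  cont <- archetype$baseline_continuum
  nir <- clip01(archetype$nir_plateau * mods$plateau_scale)
  steep <- archetype$red_edge[2]
  redge <- archetype$red_edge[1] + mods$redge_shift +
    archetype$edge_coupling * (chl - 1)                     # per sample
  edge <- stats::plogis(outer(-redge, lam, `+`) / steep)    # n x S
  r <- cont + (nir - cont) * edge
  gp <- archetype$green_peak
  r <- r + rep(1, n) %o% (gp[3] * exp(-(lam - gp[1])^2 / (2 * gp[2]^2)))
  wells <- rep(0, length(lam))
  for (w in archetype$absorption_features)
    wells <- wells + mods$depth_scale * w[3] * exp(-(lam - w[1])^2 / (2 * w[2]^2))
  r <- r - chl %o% wells
  wb <- archetype$water_band
  r <- r - (wtr * mods$water_scale * wb[3]) %o% exp(-(lam - wb[1])^2 / (2 * wb[2]^2))
  r <- r * (amp * mods$amplitude)
  # additive calibration residuals: constant offset plus linear tilt
  r + off + tlt %o% ((lam - mean(range(lam))) / (diff(range(lam)) / 2))
}

# Per-sample brightness factors: N(1, amplitude_sd), except that a fraction
# outlier_rate of samples are shadowed/specular ROIs with U(0.5, 1.5).
draw_amplitude <- function(n, archetype) {
  amp <- if (archetype$amplitude_sd > 0) rnorm(n, 1, archetype$amplitude_sd) else rep(1, n)
  if (archetype$outlier_rate > 0) {
    bad <- runif(n) < archetype$outlier_rate
    if (any(bad)) amp[bad] <- runif(sum(bad), 0.5, 1.5)
  }
  amp
}

#' Noise-free archetype reflectance curve
#'
#' Evaluates the closed-form curve of an archetype at one phase on a
#' wavelength grid — the population mean shape, with all per-sample
#' variability factors at their nominal value 1 — clipped to `[0,1]`.
#'
#' @param archetype a [species_archetype()].
#' @param phase phase key like `"2020-June"`, or `c(year, month)`.
#' @param grid a [wavelength_grid()].
#' @return numeric reflectance vector, one value per band.
#' @export
archetype_spectrum <- function(archetype, phase, grid = wavelength_grid()) {
  clip01(as.numeric(archetype_curves(archetype, phase, grid, 1, 1, 1)))
}

#' Simulate one reflectance spectrum
#'
#' Draws a noisy spectrum from an archetype at a given phase: per-sample
#' brightness, chlorophyll and water factors (each `N(1, sd)`) perturb the
#' closed-form curve, i.i.d. per-band Gaussian noise of SD `noise_sigma` is
#' added, and the result is clipped to `[0,1]`.
#'
#' @inheritParams archetype_spectrum
#' @param seed optional integer seed; if supplied the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return numeric reflectance vector of `length(grid)`.
#' @examples
#' a <- default_archetypes()[[1]]
#' s <- simulate_spectrum(a, "2020-June", seed = 1)
#' range(s)
#' @export
simulate_spectrum <- function(archetype, phase, grid = wavelength_grid(), seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  draw <- function(s, centre = 1) if (s > 0) rnorm(1L, centre, s) else centre
  amp <- draw_amplitude(1L, archetype)
  chl <- draw(archetype$chlorophyll_sd)
  wtr <- draw(archetype$water_sd)
  off <- draw(archetype$offset_sd, centre = 0)
  tlt <- draw(archetype$tilt_sd, centre = 0)
  r <- as.numeric(archetype_curves(archetype, phase, grid, amp, chl, wtr, off, tlt))
  if (archetype$noise_sigma > 0)
    r <- r + rnorm(length(r), 0, archetype$noise_sigma)
  clip01(r)
}

# Shrink every archetype's discriminative parameters toward the across-species
# mean by `overlap` in [0,1): 0 keeps the archetypes as given, values near 1
# collapse the classes.  Requires all archetypes to share the same feature
# structure (true for the defaults).
blend_archetypes <- function(archetypes, overlap) {
  if (overlap < 0) stop("class_overlap must be >= 0")
  if (overlap == 0) return(archetypes)
  if (overlap >= 1) stop("class_overlap must be < 1")
  mean_of <- function(f) Reduce(`+`, lapply(archetypes, f)) / length(archetypes)
  m_cont  <- mean_of(function(a) a$baseline_continuum)
  m_nir   <- mean_of(function(a) a$nir_plateau)
  m_green <- mean_of(function(a) a$green_peak)
  m_redge <- mean_of(function(a) a$red_edge)
  m_water <- mean_of(function(a) a$water_band)
  n_wells <- unique(vapply(archetypes, function(a) length(a$absorption_features), 1L))
  if (length(n_wells) != 1L)
    stop("class_overlap blending requires archetypes with matching well counts")
  m_wells <- lapply(seq_len(n_wells), function(j)
    mean_of(function(a) a$absorption_features[[j]]))
  mix <- function(x, m) (1 - overlap) * x + overlap * m
  lapply(archetypes, function(a) {
    a$baseline_continuum <- mix(a$baseline_continuum, m_cont)
    a$nir_plateau <- mix(a$nir_plateau, m_nir)
    a$green_peak <- mix(a$green_peak, m_green)
    a$red_edge <- mix(a$red_edge, m_redge)
    a$water_band <- mix(a$water_band, m_water)
    a$absorption_features <- lapply(seq_len(n_wells), function(j)
      mix(a$absorption_features[[j]], m_wells[[j]]))
    a
  })
}
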