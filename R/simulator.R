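#' Stokes-Einstein diffusion coefficient
#'
#' \eqn{D = k_B T / (6 \pi \eta r)} for a sphere of radius `r` in a fluid of
#' viscosity `eta`, returned in um^2/s.
#'
#' @param radius_nm Sphere radius, nm.
#' @param viscosity_pa_s Dynamic viscosity, Pa s (water at 25 C: 8.9e-4;
#'   90% glycerol: 0.219; 70% glycerol: 0.0227 -- see
#'   [glycerol_properties()]).
#' @param temperature_k Absolute temperature, K (default 298.15).
#' @return Diffusion coefficient, um^2/s. Vectorised over all arguments.
#' @export
#' @examples
#' stokes_einstein(100, 8.9e-4)   # ~2.45 um^2/s, 100 nm sphere in water
#' stokes_einstein(25, 0.219)     # ~0.0399 um^2/s in 90% glycerol
stokes_einstein <- function(radius_nm, viscosity_pa_s,
                            temperature_k = 298.15) {
  if (any(radius_nm <= 0) || any(viscosity_pa_s <= 0) ||
      any(temperature_k <= 0)) {
    abort("All Stokes-Einstein arguments must be positive.",
          class = "ipws_domain_error")
  }
  d_m2_s <- .kB * temperature_k / (6 * pi * viscosity_pa_s * radius_nm * 1e-9)
  d_m2_s * 1e12
}

#' Fresnel normal-incidence reflectance
#'
#' Intensity reflectance of the substrate-medium interface that forms the
#' reference arm, \eqn{R = ((n_1 - n_2)/(n_1 + n_2))^2}.
#'
#' @param n1,n2 Refractive indices on either side of the interface (default:
#'   sapphire 1.77 against 90% glycerol 1.46).
#' @return Reflectance in \[0, 1\].
#' @export
fresnel_reflectance <- function(n1 = 1.77, n2 = 1.46) {
  ((n1 - n2) / (n1 + n2))^2
}

#' Nanoscatterer ensemble for the phantom simulator
#'
#' Draws scatterer positions uniformly in a box covering the field of view
#' (plus a lateral margin, so scatterers can diffuse across the edges) and a
#' depth window above the reference interface. The scattering amplitude is
#' Rayleigh-like: proportional to sphere volume times the Clausius-Mossotti
#' refractive-index contrast,
#' \eqn{a = a_0 (r/50\,nm)^3 (n_s^2 - n_m^2)/(n_s^2 + 2 n_m^2)},
#' valid because the 25-100 nm radii are far below the wavelength. Each
#' scatterer carries a fixed random scattering phase.
#'
#' @param radius_nm Sphere radius, nm (one value; the ensemble is
#'   monodisperse).
#' @param volume_fraction Volume fraction of spheres, in (0, 0.05].
#' @param fov_um Numeric length-2, lateral field of view `(x, y)` in um.
#' @param depth_um Thickness of the scattering layer, um.
#' @param z0_um Distance from the reference interface to the bottom of the
#'   layer, um.
#' @param margin_um Lateral margin beyond the field of view, um.
#' @param viscosity_pa_s,temperature_k Medium viscosity (Pa s) and
#'   temperature (K); set the Stokes-Einstein `true_D`.
#' @param sphere_ri,medium_ri Refractive indices (polystyrene 1.60; 90%
#'   glycerol 1.46).
#' @param amplitude_scale Overall scattering-amplitude scale `a_0`
#'   (dimensionless field amplitude of a 50 nm reference sphere before the
#'   index-contrast factor).
#' @param mobile Logical; FALSE freezes every scatterer (D = 0).
#' @param seed Integer seed for positions and phases.
#' @return A `pws_ensemble` list: `positions` (n x 3 matrix, um), `radius_nm`,
#'   `amplitude`, `phase`, `mobile`, `true_D` (um^2/s), `volume_fraction`,
#'   medium properties, and the bounding `box`.
#' @export
scatterer_ensemble <- function(radius_nm, volume_fraction,
                               fov_um = c(8, 8), depth_um = 1.5,
                               z0_um = 0.5, margin_um = 0.5,
                               viscosity_pa_s = 0.219,
                               temperature_k = 298.15,
                               sphere_ri = 1.60, medium_ri = 1.46,
                               amplitude_scale = 0.03,
                               mobile = TRUE, seed = 1L) {
  stopifnot(radius_nm > 0, viscosity_pa_s > 0, depth_um > 0)
  if (volume_fraction < 0 || volume_fraction > 0.05) {
    abort("`volume_fraction` must lie in [0, 0.05].", class = "ipws_domain_error")
  }
  lx <- fov_um[1] + 2 * margin_um
  ly <- fov_um[2] + 2 * margin_um
  v_box <- lx * ly * depth_um
  v_sphere <- 4 / 3 * pi * (radius_nm * 1e-3)^3
  n <- round(volume_fraction * v_box / v_sphere)
  set.seed(seed)
  positions <- cbind(
    x = runif(n, -margin_um, fov_um[1] + margin_um),
    y = runif(n, -margin_um, fov_um[2] + margin_um),
    z = runif(n, z0_um, z0_um + depth_um)
  )
  contrast <- (sphere_ri^2 - medium_ri^2) / (sphere_ri^2 + 2 * medium_ri^2)
  amp <- rep(amplitude_scale * (radius_nm / 50)^3 * contrast, n)
  structure(
    list(
      positions = positions,
      radius_nm = radius_nm,
      amplitude = amp,
      phase = runif(n, 0, 2 * pi),
      mobile = rep(isTRUE(mobile), n),
      true_D = if (isTRUE(mobile)) {
        stokes_einstein(radius_nm, viscosity_pa_s, temperature_k)
      } else 0,
      volume_fraction = volume_fraction,
      viscosity_pa_s = viscosity_pa_s,
      temperature_k = temperature_k,
      sphere_ri = sphere_ri,
      medium_ri = medium_ri,
      amplitude_scale = amplitude_scale,
      box = list(x0 = -margin_um, y0 = -margin_um, z0 = z0_um,
                 lx = lx, ly = ly, lz = depth_um,
                 fov_um = fov_um, margin_um = margin_um),
      seed = seed
    ),
    class = "pws_ensemble"
  )
}

#' @export
print.pws_ensemble <- function(x, ...) {
  cat(sprintf(
    "<pws_ensemble> %d spheres r = %g nm, phi = %.2g%%, eta = %.3g Pa.s, D = %.4g um^2/s%s\n",
    nrow(x$positions), x$radius_nm, 100 * x$volume_fraction,
    x$viscosity_pa_s, x$true_D, if (all(x$mobile)) "" else " (frozen)"))
  invisible(x)
}

# One chunk of Brownian substeps; advances `pos` in place conventions:
# reflecting walls in z (keeps the layer density uniform), periodic wrap in
# x/y over the extended box.
brownian_chunk <- function(pos, n_sub, dt, step_sd, box) {
  n <- nrow(pos)
  out <- array(NA_real_, c(n_sub, n, 3))
  for (s in seq_len(n_sub)) {
    if (any(step_sd > 0)) {
      pos <- pos + matrix(rnorm(3 * n), n, 3) * step_sd
      pos[, 1] <- box$x0 + (pos[, 1] - box$x0) %% box$lx
      pos[, 2] <- box$y0 + (pos[, 2] - box$y0) %% box$ly
      u <- (pos[, 3] - box$z0) %% (2 * box$lz)
      pos[, 3] <- box$z0 + ifelse(u > box$lz, 2 * box$lz - u, u)
    }
    out[s, , ] <- pos
  }
  list(positions = out, last = pos)
}

#' Brownian trajectories for a scatterer ensemble
#'
#' Each mobile scatterer takes independent Gaussian steps with per-axis
#' variance `2 * D * dt` where `dt = frame_interval_s / substeps`; immobile
#' scatterers stay put. The z coordinate reflects at the depth-window walls
#' and x/y wrap periodically over the (margin-extended) field, so the layer
#' density stays uniform. Fully reproducible under a fixed seed.
#'
#' For long acquisitions the returned array can be large
#' (`n_frames * substeps x n x 3`); [render_interference()] can instead
#' stream the same trajectories frame by frame without materialising them.
#'
#' @param ensemble A [scatterer_ensemble()].
#' @param frame_interval_s Seconds between frame starts.
#' @param n_frames Number of frames.
#' @param substeps Substeps per frame interval (>= 1).
#' @param seed Integer seed.
#' @return Array `(n_frames * substeps, n, 3)` of positions in um.
#' @export
simulate_brownian <- function(ensemble, frame_interval_s, n_frames,
                              substeps = 10L, seed = 1L) {
  stopifnot(inherits(ensemble, "pws_ensemble"), substeps >= 1, n_frames >= 1)
  d_scatter <- ifelse(ensemble$mobile, ensemble$true_D, 0)
  if (any(!is.finite(d_scatter)) || any(d_scatter < 0)) {
    abort("Non-finite or negative diffusion coefficient.",
          class = "ipws_domain_error")
  }
  dt <- frame_interval_s / substeps
  step_sd <- sqrt(2 * d_scatter * dt)
  n <- nrow(ensemble$positions)
  set.seed(seed)
  out <- array(NA_real_, c(n_frames * substeps, n, 3))
  pos <- ensemble$positions
  for (f in seq_len(n_frames)) {
    ch <- brownian_chunk(pos, substeps, dt, step_sd, ensemble$box)
    out[(f - 1L) * substeps + seq_len(substeps), , ] <- ch$positions
    pos <- ch$last
  }
  out
}

#' Detection-noise model for the simulator
#'
#' @param photon_budget Expected photons per pixel per frame at unit
#'   reflectance; drives Poisson shot noise (use `Inf` to disable).
#' @param read_noise_sd Read noise, photons RMS per pixel per frame.
#' @param led_drift_amplitude Relative RMS amplitude of the multiplicative
#'   LED intensity drift (an AR(1) process common to all pixels of a frame).
#' @param led_drift_tau_s Correlation time of the LED drift, seconds.
#' @return A `pws_noise_model` list.
#' @export
noise_model <- function(photon_budget = 2e8, read_noise_sd = 30,
                        led_drift_amplitude = 0.001, led_drift_tau_s = 1) {
  stopifnot(photon_budget > 0, read_noise_sd >= 0, led_drift_amplitude >= 0,
            led_drift_tau_s > 0)
  structure(list(photon_budget = photon_budget, read_noise_sd = read_noise_sd,
                 led_drift_amplitude = led_drift_amplitude,
                 led_drift_tau_s = led_drift_tau_s),
            class = "pws_noise_model")
}

apply_detection_noise <- function(arr, noise, frame_interval_s) {
  if (is.null(noise)) return(list(arr = arr, drift = NULL))
  d <- dim(arr)
  drift <- NULL
  if (noise$led_drift_amplitude > 0) {
    phi <- exp(-frame_interval_s / noise$led_drift_tau_s)
    u <- numeric(d[1])
    u[1] <- rnorm(1, sd = noise$led_drift_amplitude)
    if (d[1] > 1) {
      innov <- rnorm(d[1] - 1, sd = noise$led_drift_amplitude * sqrt(1 - phi^2))
      for (i in 2:d[1]) u[i] <- phi * u[i - 1] + innov[i - 1]
    }
    drift <- 1 + u
    arr <- arr * drift  # recycles along the frame axis
  }
  b <- noise$photon_budget
  if (is.finite(b)) {
    counts <- rpois(length(arr), lambda = pmax(as.vector(arr), 0) * b)
    if (noise$read_noise_sd > 0) {
      counts <- counts + rnorm(length(counts), sd = noise$read_noise_sd)
    }
    arr <- array(counts / b, d)
  }
  list(arr = arr, drift = drift)
}

psf_sigma_um <- function(wavelength_nm, collection_na) {
  0.21 * (wavelength_nm * 1e-3) / collection_na
}

#' Render a temporal interference cube from scatterer trajectories
#'
#' Evaluates the scalar-field forward model per pixel: the complex field is
#' the reference reflection `sqrt(R_ref)` plus each scatterer's amplitude
#' carried on the backscattering phase `2 k z + phi`, weighted by a Gaussian
#' lateral point-spread function integrated over the pixel. Detected
#' intensity `|field|^2` is averaged over the substeps inside each exposure
#' window (finite-exposure integration), then shot noise, read noise and LED
#' drift are applied per the noise model. The mean intensity is approximately
#' `R_ref + sum(w^2 a^2)` and the ensemble autocorrelation of the mobile
#' fluctuations decays at rate `4 k^2 D`.
#'
#' @param ensemble A [scatterer_ensemble()].
#' @param meta [acquisition_meta()] with exactly one wavelength; exposure
#'   must not exceed the frame interval.
#' @param ny,nx Image size in pixels; the field of view
#'   `(nx, ny) * pixel_size_um` should match the ensemble box.
#' @param trajectories Optional precomputed [simulate_brownian()] array
#'   sampled at `substeps` per frame interval. When `NULL` (default), the
#'   same trajectories are generated on the fly frame-by-frame, which keeps
#'   memory flat for long acquisitions.
#' @param substeps Substeps per frame interval (the exposure window is
#'   covered by `substeps * exposure / frame_interval` of them).
#' @param reference_reflectance Reference-arm intensity reflectance `R_ref`;
#'   defaults to the sapphire/medium Fresnel value. Chosen strong relative to
#'   scattering so the interference term dominates (heterodyne regime).
#' @param noise A [noise_model()] or `NULL` for a noiseless cube.
#' @param seed Integer seed (trajectories and noise).
#' @return A normalized `pws_cube` (temporal), with simulation provenance.
#' @export
render_interference <- function(ensemble, meta, ny, nx,
                                trajectories = NULL, substeps = 10L,
                                reference_reflectance = NULL,
                                noise = noise_model(), seed = 1L) {
  stopifnot(inherits(ensemble, "pws_ensemble"), inherits(meta, "pws_meta"))
  if (length(meta$wavelengths_nm) != 1) {
    abort("Temporal rendering needs a single-wavelength meta.",
          class = "ipws_metadata_error")
  }
  r_ref <- reference_reflectance %||%
    fresnel_reflectance(1.77, ensemble$medium_ri)
  k <- meta$wavenumber_um
  sig <- psf_sigma_um(meta$wavelengths_nm, meta$collection_na)
  nfr <- meta$n_frames
  substeps <- as.integer(substeps)
  n_exp_sub <- max(1L, as.integer(round(
    substeps * meta$exposure_time_s / meta$frame_interval_s)))
  n <- nrow(ensemble$positions)
  arr <- array(0, c(nfr, ny, nx))
  set.seed(seed)
  if (is.null(trajectories)) {
    d_scatter <- ifelse(ensemble$mobile, ensemble$true_D, 0)
    dt <- meta$frame_interval_s / substeps
    step_sd <- sqrt(2 * d_scatter * dt)
    pos <- ensemble$positions
    for (f in seq_len(nfr)) {
      if (n > 0) {
        ch <- brownian_chunk(pos, substeps, dt, step_sd, ensemble$box)
        pos <- ch$last
        arr[f, , ] <- .render_frame_chunk(
          as.vector(ch$positions[, , 1]), as.vector(ch$positions[, , 2]),
          as.vector(ch$positions[, , 3]),
          ensemble$amplitude, ensemble$phase,
          substeps, n_exp_sub, k, sig, meta$pixel_size_um, 0, 0,
          as.integer(ny), as.integer(nx), r_ref)
      } else {
        arr[f, , ] <- r_ref
      }
    }
  } else {
    stopifnot(dim(trajectories)[1] == nfr * substeps,
              dim(trajectories)[2] == n)
    for (f in seq_len(nfr)) {
      idx <- (f - 1L) * substeps + seq_len(substeps)
      if (n > 0) {
        arr[f, , ] <- .render_frame_chunk(
          as.vector(trajectories[idx, , 1, drop = FALSE]),
          as.vector(trajectories[idx, , 2, drop = FALSE]),
          as.vector(trajectories[idx, , 3, drop = FALSE]),
          ensemble$amplitude, ensemble$phase,
          substeps, n_exp_sub, k, sig, meta$pixel_size_um, 0, 0,
          as.integer(ny), as.integer(nx), r_ref)
      } else {
        arr[f, , ] <- r_ref
      }
    }
  }
  noised <- apply_detection_noise(arr, noise, meta$frame_interval_s)
  temporal_cube(noised$arr, meta, normalized = TRUE,
                is_reference = (n == 0)) |>
    add_provenance(list(simulation = list(
      r_ref = r_ref, psf_sigma_um = sig, substeps = substeps,
      n_exp_sub = n_exp_sub, n_scatterers = n, seed = seed,
      true_D = ensemble$true_D, radius_nm = ensemble$radius_nm,
      volume_fraction = ensemble$volume_fraction,
      amplitude_scale = ensemble$amplitude_scale,
      photon_budget = if (is.null(noise)) Inf else noise$photon_budget,
      k_convention = meta$k_convention)))
}

add_provenance <- function(cube, entries) {
  cube$provenance <- c(cube$provenance, entries)
  cube
}

#' Render a spectral interference cube from a static snapshot
#'
#' Evaluates the same scalar-field model at each wavelength of the metadata
#' (the wavenumber, and with it the backscattering phase `2 k z`, varies with
#' wavelength) for a static snapshot of the ensemble. A scatterer at depth
#' `z` produces a spectral oscillation with period `pi / (n z)` in vacuum
#' wavenumber, so deeper scatterers oscillate faster.
#'
#' @param ensemble A [scatterer_ensemble()]; its current `positions` are the
#'   snapshot.
#' @param meta [acquisition_meta()] carrying >= 3 wavelengths.
#' @param ny,nx Image size in pixels.
#' @param reference_reflectance,noise,seed As in [render_interference()].
#' @return A normalized spectral `pws_cube`.
#' @export
render_spectral <- function(ensemble, meta, ny, nx,
                            reference_reflectance = NULL,
                            noise = noise_model(), seed = 1L) {
  stopifnot(inherits(ensemble, "pws_ensemble"), inherits(meta, "pws_meta"))
  if (length(meta$wavelengths_nm) < 3) {
    abort("Spectral rendering needs at least 3 wavelengths.",
          class = "ipws_domain_error")
  }
  r_ref <- reference_reflectance %||%
    fresnel_reflectance(1.77, ensemble$medium_ri)
  n <- nrow(ensemble$positions)
  nl <- length(meta$wavelengths_nm)
  arr <- array(r_ref, c(nl, ny, nx))
  set.seed(seed)
  if (n > 0) {
    for (l in seq_len(nl)) {
      k_l <- wavenumber(meta$wavelengths_nm[l], meta$medium_ri)
      sig_l <- psf_sigma_um(meta$wavelengths_nm[l], meta$collection_na)
      arr[l, , ] <- .render_frame_chunk(
        ensemble$positions[, 1], ensemble$positions[, 2],
        ensemble$positions[, 3],
        ensemble$amplitude, ensemble$phase,
        1L, 1L, k_l, sig_l, meta$pixel_size_um, 0, 0,
        as.integer(ny), as.integer(nx), r_ref)
    }
  }
  noised <- apply_detection_noise(arr, noise, meta$frame_interval_s)
  spectral_cube(noised$arr, meta, normalized = TRUE) |>
    add_provenance(list(simulation = list(
      r_ref = r_ref, n_scatterers = n, seed = seed,
      k_convention = meta$k_convention)))
}

#' Analytic expectation of the temporal fluctuation variance
#'
#' Closed-form (quadrature) expectation of the per-pixel temporal variance
#' `Sigma_t^2` produced by the interference forward model, before exposure
#' attenuation and detection noise: in the heterodyne regime each mobile
#' scatterer contributes `2 R_ref a^2 w^2` of variance (the squared
#' interference cross-term averaged over its uniformly distributed phase),
#' and the expected per-pixel sum over scatterers follows from the uniform
#' scatterer density and the pixel-integrated Gaussian point-spread profile.
#'
#' This is the theory value that exposure-corrected measured `Sigma_t^2` is
#' validated against on phantom suites.
#'
#' @inheritParams render_interference
#' @return Expected per-pixel `Sigma_t^2` (scalar).
#' @export
analytic_sigma_t2 <- function(ensemble, meta, ny, nx,
                              reference_reflectance = NULL) {
  r_ref <- reference_reflectance %||%
    fresnel_reflectance(1.77, ensemble$medium_ri)
  sig <- psf_sigma_um(meta$wavelengths_nm[1], meta$collection_na)
  px <- meta$pixel_size_um
  n <- nrow(ensemble$positions)
  if (n == 0 || !any(ensemble$mobile)) return(0)
  # mean over sub-pixel offsets of the summed squared 1-D pixel weights
  hw <- ceiling(4 * sig / px) + 1
  offs <- (seq_len(65) - 0.5) / 65      # scatterer position within one pixel
  w2_1d <- mean(vapply(offs, function(t0) {
    x <- t0 * px
    i <- (-hw):hw
    w <- pnorm(((i + 1) * px - x) / sig) - pnorm((i * px - x) / sig)
    sum(w^2)
  }, numeric(1)))
  area_px <- (ensemble$box$lx / px) * (ensemble$box$ly / px)
  dens <- sum(ensemble$mobile) / area_px   # mobile scatterers per pixel area
  2 * r_ref * mean(ensemble$amplitude^2) * dens * w2_1d^2
}

#' Simulate a phantom suite with ground-truth manifest
#'
#' Generates one temporal cube per condition (radius, volume fraction,
#' glycerol mixture) under the phantom acquisition defaults -- 32 ms
#' exposure, contiguous frames, 6.432 s acquisition (201 frames), 550 nm --
#' plus one matching empty-field reference cube per suite, and a manifest
#' tibble tying every cube to its ground truth.
#'
#' The substep count per frame adapts to the correlation time
#' (`t_c = 1/(4 k^2 D)`) so that fast conditions are still integrated finely
#' within the exposure window.
#'
#' @param conditions Tibble with columns `radius_nm`, `volume_fraction`, and
#'   `glycerol_pct` (90 or 70; sets viscosity and medium RI from
#'   [glycerol_properties()]). Defaults to [phantom_conditions()].
#' @param seed Master seed; per-condition seeds are drawn from it.
#' @param ny,nx Image size in pixels.
#' @param meta Acquisition metadata template (single wavelength).
#' @param depth_um Scattering-layer thickness, um.
#' @param amplitude_scale Scattering amplitude scale, see
#'   [scatterer_ensemble()].
#' @param noise A [noise_model()] or `NULL`; the reference cube shares it.
#' @param mobile FALSE freezes all scatterers (fixation analogue).
#' @return A list with `cubes` (list of temporal `pws_cube`), `reference`
#'   (empty-field reference cube), and `manifest` (tibble with per-condition
#'   `true_D`, `t_c`, `sigma_t2_analytic`, seeds and geometry).
#' @export
make_phantom_suite <- function(conditions = phantom_conditions(), seed = 1L,
                               ny = 32, nx = 32,
                               meta = phantom_meta(),
                               depth_um = 1.5, amplitude_scale = 0.03,
                               noise = noise_model(), mobile = TRUE) {
  stopifnot(all(c("radius_nm", "volume_fraction", "glycerol_pct") %in%
                  names(conditions)))
  glyc <- glycerol_properties()
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(conditions) + 1L)
  fov <- c(nx, ny) * meta$pixel_size_um
  k <- meta$wavenumber_um
  cubes <- vector("list", nrow(conditions))
  rows <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    cond <- conditions[i, ]
    g <- glyc[match(cond$glycerol_pct, glyc$glycerol_pct), ]
    if (is.na(g$viscosity_pa_s)) {
      abort(sprintf("No tabulated properties for %g%% glycerol.",
                    cond$glycerol_pct), class = "ipws_domain_error")
    }
    meta_i <- meta
    meta_i$medium_ri <- g$refractive_index
    meta_i$wavenumber_um <- wavenumber(meta$wavelengths_nm[1],
                                       g$refractive_index)
    ens <- scatterer_ensemble(
      radius_nm = cond$radius_nm, volume_fraction = cond$volume_fraction,
      fov_um = fov, depth_um = depth_um,
      viscosity_pa_s = g$viscosity_pa_s, medium_ri = g$refractive_index,
      amplitude_scale = amplitude_scale, mobile = mobile,
      seed = sub_seeds[i])
    t_c <- if (ens$true_D > 0) 1 / (4 * meta_i$wavenumber_um^2 * ens$true_D) else Inf
    substeps <- substeps_for(meta_i$exposure_time_s, t_c)
    cubes[[i]] <- render_interference(
      ens, meta_i, ny = ny, nx = nx, substeps = substeps,
      noise = noise, seed = sub_seeds[i])
    rows[[i]] <- tibble::tibble(
      condition = i, radius_nm = cond$radius_nm,
      volume_fraction = cond$volume_fraction,
      glycerol_pct = cond$glycerol_pct,
      viscosity_pa_s = g$viscosity_pa_s, medium_ri = g$refractive_index,
      true_D = ens$true_D, t_c_s = t_c,
      n_scatterers = nrow(ens$positions),
      sigma_t2_analytic = analytic_sigma_t2(ens, meta_i, ny, nx),
      substeps = substeps, seed = sub_seeds[i])
  }
  ref_meta <- meta
  empty <- scatterer_ensemble(50, 0, fov_um = fov, depth_um = depth_um,
                              amplitude_scale = amplitude_scale,
                              seed = sub_seeds[length(sub_seeds)])
  reference <- render_interference(empty, ref_meta, ny = ny, nx = nx,
                                   noise = noise,
                                   seed = sub_seeds[length(sub_seeds)])
  list(cubes = cubes, reference = reference,
       manifest = dplyr::bind_rows(rows))
}

substeps_for <- function(exposure_s, t_c_s, lo = 10L, hi = 24L) {
  if (!is.finite(t_c_s) || t_c_s <= 0) return(lo)
  min(hi, max(lo, as.integer(ceiling(3 * exposure_s / t_c_s))))
}

#' Default phantom acquisition metadata
#'
#' 550 nm, 32 ms exposure, contiguous frames, 201 frames (6.432 s
#' acquisition), the parameters of the nanosphere-phantom experiments.
#'
#' @param pixel_size_um Pixel size, um.
#' @param medium_ri Medium refractive index (90% glycerol default).
#' @return A `pws_meta`.
#' @export
phantom_meta <- function(pixel_size_um = 0.25, medium_ri = 1.46) {
  acquisition_meta(550, exposure_time_s = 0.032, frame_interval_s = 0.032,
                   n_frames = 201, pixel_size_um = pixel_size_um,
                   medium_ri = medium_ri, illumination_na = 0.55,
                   collection_na = 1.4)
}

#' Default phantom condition grid
#'
#' Radii 25/37.5/50/100 nm at 0.1% volume fraction in 90% glycerol and
#' optionally 0.3% in 70% glycerol.
#'
#' @param radii_nm Sphere radii, nm.
#' @param include_03pct Include the 0.3% / 70% glycerol arm.
#' @return A conditions tibble for [make_phantom_suite()].
#' @export
phantom_conditions <- function(radii_nm = c(25, 37.5, 50, 100),
                               include_03pct = FALSE) {
  out <- tibble::tibble(radius_nm = radii_nm, volume_fraction = 0.001,
                        glycerol_pct = 90)
  if (include_03pct) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(radius_nm = radii_nm, volume_fraction = 0.003,
                     glycerol_pct = 70))
  }
  out
}

#' Simulate a temporal cube containing per-pixel bursts of motion
#'
#' Each pixel's trace is quiescent Gaussian noise around a baseline before
#' its onset frame and gains a step in fluctuation standard deviation (and
#' optionally in mean) from the onset frame onwards -- the synthetic analogue
#' of a cellular paroxysm. Ground truth is stored in the cube provenance.
#'
#' @param n_frames Frames in the cube.
#' @param onset_map Integer matrix `ny x nx`; the 1-based frame at which the
#'   burst starts at that pixel, or `NA` for no event. Must be in
#'   `[2, n_frames]`.
#' @param amplitude_map Matrix or scalar; post-onset noise SD as a multiple
#'   of the baseline SD (default 3).
#' @param mean_shift_map Matrix or scalar; post-onset mean shift in units of
#'   the baseline SD (default 0).
#' @param baseline Mean reflectance level of the quiescent trace.
#' @param noise_sd Baseline fluctuation SD.
#' @param meta Acquisition metadata; defaults to 35 ms frames.
#' @param seed Integer seed.
#' @return A temporal `pws_cube` with `$provenance$ground_truth`.
#' @export
simulate_paroxysm_cube <- function(n_frames, onset_map, amplitude_map = 3,
                                   mean_shift_map = 0,
                                   baseline = 0.01, noise_sd = 5e-4,
                                   meta = NULL, seed = 1L) {
  stopifnot(is.matrix(onset_map))
  onset <- onset_map
  if (any(onset[!is.na(onset)] > n_frames | onset[!is.na(onset)] < 2)) {
    abort("Onsets must lie in [2, n_frames].", class = "ipws_domain_error")
  }
  ny <- nrow(onset); nx <- ncol(onset)
  if (length(amplitude_map) == 1) amplitude_map <- matrix(amplitude_map, ny, nx)
  if (length(mean_shift_map) == 1) mean_shift_map <- matrix(mean_shift_map, ny, nx)
  meta <- meta %||% acquisition_meta(550, exposure_time_s = 0.035,
                                     n_frames = n_frames,
                                     pixel_size_um = 0.25, medium_ri = 1.38)
  meta$n_frames <- as.integer(n_frames)
  meta$acquisition_time_s <- n_frames * meta$frame_interval_s
  set.seed(seed)
  arr <- array(rnorm(n_frames * ny * nx, sd = noise_sd), c(n_frames, ny, nx))
  tt <- seq_len(n_frames)
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      o <- onset[iy, ix]
      if (!is.na(o)) {
        post <- tt >= o
        arr[post, iy, ix] <- arr[post, iy, ix] * amplitude_map[iy, ix] +
          mean_shift_map[iy, ix] * noise_sd
      }
    }
  }
  arr <- arr + baseline
  temporal_cube(arr, meta, normalized = TRUE) |>
    add_provenance(list(ground_truth = list(
      onset_map = onset, amplitude_map = amplitude_map,
      mean_shift_map = mean_shift_map, noise_sd = noise_sd,
      baseline = baseline, seed = seed)))
}
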