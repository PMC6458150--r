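# Independent evaluation of the Stokes-Einstein closed form, against which
# the package function is checked.
se_oracle <- function(r_nm, eta, temp = 298.15) {
  1.380649e-23 * temp / (6 * pi * eta * r_nm * 1e-9) * 1e12
}

test_that("stokes_einstein matches the closed form and its scalings", {
  expect_equal(stokes_einstein(100, 8.9e-4), se_oracle(100, 8.9e-4))
  expect_equal(stokes_einstein(100, 8.9e-4), 2.4537, tolerance = 1e-4)
  expect_equal(stokes_einstein(25, 0.219), se_oracle(25, 0.219))
  expect_equal(stokes_einstein(25, 0.219), 0.039887, tolerance = 1e-4)
  # D halves exactly when the radius doubles
  expect_equal(stokes_einstein(50, 0.219) / stokes_einstein(100, 0.219), 2)
  expect_error(stokes_einstein(-1, 0.219), class = "ipws_domain_error")
  expect_error(stokes_einstein(50, 0), class = "ipws_domain_error")
})

test_that("frozen ensembles do not move and seeds reproduce trajectories", {
  ens <- scatterer_ensemble(50, 1e-4, fov_um = c(4, 4), mobile = FALSE,
                            seed = 1)
  tr <- simulate_brownian(ens, 0.032, n_frames = 5, substeps = 3, seed = 9)
  for (s in 2:dim(tr)[1]) expect_identical(tr[s, , ], tr[1, , ])

  ens2 <- scatterer_ensemble(50, 1e-4, fov_um = c(4, 4), seed = 1)
  t1 <- simulate_brownian(ens2, 0.032, n_frames = 10, substeps = 4, seed = 7)
  t2 <- simulate_brownian(ens2, 0.032, n_frames = 10, substeps = 4, seed = 7)
  expect_identical(t1, t2)
})

test_that("ensemble mean-squared displacement follows 6*D*tau", {
  ens <- scatterer_ensemble(50, 1e-4, fov_um = c(4, 4), seed = 2)
  n <- 400
  ens$positions <- matrix(runif(n * 3, 100, 110), n, 3)
  ens$amplitude <- rep(1e-3, n); ens$phase <- runif(n, 0, 2 * pi)
  ens$mobile <- rep(TRUE, n); ens$true_D <- 0.01
  # huge box: free diffusion, no boundary interactions
  ens$box <- list(x0 = -1e4, y0 = -1e4, z0 = -1e4, lx = 2e4, ly = 2e4,
                  lz = 2e4, fov_um = c(4, 4), margin_um = 0.5)
  tr <- simulate_brownian(ens, 0.001, n_frames = 1000, substeps = 1, seed = 3)
  # disjoint increments at several lags give independent MSD samples
  for (m in c(10, 50, 200)) {
    starts <- seq(1, 1000 - m, by = m)
    d2 <- (tr[starts + m, , 1] - tr[starts, , 1])^2 +
      (tr[starts + m, , 2] - tr[starts, , 2])^2 +
      (tr[starts + m, , 3] - tr[starts, , 3])^2
    expect_rel_equal(mean(d2), 6 * 0.01 * m * 0.001, 0.05)
  }
})

test_that("a static scatterer field renders a time-constant noiseless cube", {
  ens <- scatterer_ensemble(50, 2e-4, fov_um = c(2, 2), mobile = FALSE,
                            seed = 4)
  meta <- acquisition_meta(550, 0.032, n_frames = 6, pixel_size_um = 0.25,
                           medium_ri = 1.46)
  cube <- render_interference(ens, meta, 8, 8, noise = NULL, seed = 4)
  for (f in 2:6) expect_equal(cube$intensities[f, , ], cube$intensities[1, , ])
})

test_that("doubling scattering amplitudes quadruples the fluctuation variance", {
  meta <- acquisition_meta(550, 0.032, n_frames = 80, pixel_size_um = 0.25,
                           medium_ri = 1.46)
  ens <- scatterer_ensemble(50, 5e-4, fov_um = c(2, 2), seed = 5)
  c1 <- render_interference(ens, meta, 8, 8, noise = NULL, seed = 6)
  ens2 <- ens
  ens2$amplitude <- 2 * ens$amplitude
  c2 <- render_interference(ens2, meta, 8, 8, noise = NULL, seed = 6)
  v1 <- mean(ipws:::pixel_variance(c1))
  v2 <- mean(ipws:::pixel_variance(c2))
  # delta-I is linear in amplitude at fixed reference (heterodyne regime), so
  # variance is quadratic; the small |s|^2 self-term perturbs it slightly
  expect_rel_equal(v2 / v1, 4, 0.05)
})

test_that("rendered cubes are deterministic under a fixed seed", {
  meta <- acquisition_meta(550, 0.032, n_frames = 20, pixel_size_um = 0.25,
                           medium_ri = 1.46)
  ens <- scatterer_ensemble(50, 5e-4, fov_um = c(2, 2), seed = 8)
  c1 <- render_interference(ens, meta, 8, 8, seed = 11)
  c2 <- render_interference(ens, meta, 8, 8, seed = 11)
  expect_identical(c1$intensities, c2$intensities)
})

test_that("streamed rendering equals rendering from materialised trajectories", {
  meta <- acquisition_meta(550, 0.032, n_frames = 15, pixel_size_um = 0.25,
                           medium_ri = 1.46)
  ens <- scatterer_ensemble(50, 5e-4, fov_um = c(2, 2), seed = 12)
  tr <- simulate_brownian(ens, meta$frame_interval_s, 15, substeps = 10,
                          seed = 13)
  c_stream <- render_interference(ens, meta, 8, 8, noise = NULL, seed = 13)
  c_mat <- render_interference(ens, meta, 8, 8, trajectories = tr,
                               noise = NULL, seed = 13)
  expect_equal(c_stream$intensities, c_mat$intensities)
})

test_that("an empty field renders a flat spectrum at the reference reflectance", {
  meta <- acquisition_meta(seq(500, 700, 10), 0.035, pixel_size_um = 0.25,
                           medium_ri = 1.46)
  ens <- scatterer_ensemble(50, 0, fov_um = c(2, 2), seed = 1)
  cube <- render_spectral(ens, meta, 8, 8, noise = NULL)
  expect_true(all(cube$intensities == fresnel_reflectance(1.77, 1.46)))
})

test_that("rendered spectra equal a direct scalar-field evaluation", {
  wl <- seq(500, 700, 4)
  meta <- acquisition_meta(wl, 0.035, pixel_size_um = 0.25, medium_ri = 1.46,
                           collection_na = 1.4)
  ens <- scatterer_ensemble(50, 5e-4, fov_um = c(2, 2), seed = 21)
  r_ref <- fresnel_reflectance(1.77, 1.46)
  cube <- render_spectral(ens, meta, 8, 8, noise = NULL)
  px <- meta$pixel_size_um
  # direct evaluation of sqrt(R) + sum_j a_j w_j exp(i(2 k z_j + phi_j))
  # with the same pixel-integrated Gaussian weights and stamp cutoff
  for (l in c(1, 17, 51)) {
    k_l <- wavenumber(wl[l], 1.46)
    sig <- 0.21 * wl[l] * 1e-3 / 1.4
    hw <- ceiling(4 * sig / px) + 1
    fr <- matrix(complex(real = sqrt(r_ref), imaginary = 0), 8, 8)
    for (j in seq_len(nrow(ens$positions))) {
      x <- ens$positions[j, 1]; y <- ens$positions[j, 2]
      cx <- floor(x / px); cy <- floor(y / px)
      for (dx in -hw:hw) for (dy in -hw:hw) {
        ix <- cx + dx; iy <- cy + dy
        if (ix < 0 || ix > 7 || iy < 0 || iy > 7) next
        w <- (pnorm(((ix + 1) * px - x) / sig) - pnorm((ix * px - x) / sig)) *
          (pnorm(((iy + 1) * px - y) / sig) - pnorm((iy * px - y) / sig))
        fr[iy + 1, ix + 1] <- fr[iy + 1, ix + 1] +
          w * ens$amplitude[j] * exp(1i * (2 * k_l * ens$positions[j, 3] +
                                             ens$phase[j]))
      }
    }
    expect_equal(cube$intensities[l, , ], Mod(fr)^2, tolerance = 1e-12)
  }
})

test_that("spectral oscillation frequency grows with scatterer depth", {
  wl <- seq(500, 700, 1)
  meta <- acquisition_meta(wl, 0.035, pixel_size_um = 0.25, medium_ri = 1.46)
  count_crossings <- function(z_um) {
    ens <- scatterer_ensemble(50, 5e-4, fov_um = c(2, 2), seed = 3)
    ens$positions <- matrix(c(1.02, 1.03, z_um), 1, 3)
    ens$amplitude <- 0.01; ens$phase <- 0; ens$mobile <- TRUE
    cube <- render_spectral(ens, meta, 8, 8, noise = NULL)
    sp <- cube$intensities[, 5, 5]
    sum(diff(sign(sp - mean(sp))) != 0)
  }
  # expected number of oscillations: depth z spans 2*n*z*(1/lambda1 - 1/lambda2)
  # full periods over 500-700 nm; period in vacuum wavenumber is pi/(n z)
  n_osc <- function(z) 2 * 1.46 * z * 1e3 * (1 / 500 - 1 / 700)
  c2 <- count_crossings(2); c4 <- count_crossings(4)
  expect_equal(c2, round(2 * n_osc(2)), tolerance = 1)
  expect_equal(c4, round(2 * n_osc(4)), tolerance = 1)
  expect_gt(c4, c2)
})

test_that("phantom suites are reproducible and traceable to their manifest", {
  meta <- acquisition_meta(550, 0.032, n_frames = 40, pixel_size_um = 0.25,
                           medium_ri = 1.46)
  conds <- phantom_conditions(radii_nm = c(50, 100))
  s1 <- make_phantom_suite(conds, seed = 5, ny = 8, nx = 8, meta = meta)
  s2 <- make_phantom_suite(conds, seed = 5, ny = 8, nx = 8, meta = meta)
  expect_identical(s1$cubes[[1]]$intensities, s2$cubes[[1]]$intensities)
  expect_identical(s1$cubes[[2]]$intensities, s2$cubes[[2]]$intensities)
  expect_identical(s1$reference$intensities, s2$reference$intensities)
  expect_equal(nrow(s1$manifest), 2)
  expect_equal(s1$manifest$true_D,
               stokes_einstein(c(50, 100), 0.219))
  expect_true(all(c("sigma_t2_analytic", "seed", "n_scatterers") %in%
                    names(s1$manifest)))
  # true_D of the dilute suite spans the expected range in 90% glycerol
  d_range <- stokes_einstein(c(100, 25), 0.219)
  expect_equal(round(d_range, 3), c(0.010, 0.040), tolerance = 0.05)
})

test_that("a zero-volume-fraction cube is statistically identical to its reference", {
  meta <- acquisition_meta(550, 0.032, n_frames = 60, pixel_size_um = 0.25,
                           medium_ri = 1.46)
  conds <- tibble::tibble(radius_nm = 50, volume_fraction = 0,
                          glycerol_pct = 90)
  s <- make_phantom_suite(conds, seed = 6, ny = 8, nx = 8, meta = meta)
  v_cube <- mean(ipws:::pixel_variance(s$cubes[[1]]))
  v_ref <- mean(ipws:::pixel_variance(s$reference))
  expect_rel_equal(v_cube, v_ref, 0.15)
  expect_equal(mean(s$cubes[[1]]$intensities), mean(s$reference$intensities),
               tolerance = 1e-3)
})

test_that("paroxysm cubes step their variance at the prescribed onsets", {
  onset <- matrix(100L, 6, 6)
  cube <- simulate_paroxysm_cube(201, onset, amplitude_map = 3, seed = 1)
  arr <- cube$intensities
  for (iy in 1:6) for (ix in 1:6) {
    expect_gt(var(arr[100:201, iy, ix]), var(arr[1:99, iy, ix]))
  }
  expect_error(simulate_paroxysm_cube(50, matrix(60L, 2, 2)),
               class = "ipws_domain_error")
  c1 <- simulate_paroxysm_cube(64, matrix(c(10L, NA), 2, 2), seed = 3)
  c2 <- simulate_paroxysm_cube(64, matrix(c(10L, NA), 2, 2), seed = 3)
  expect_identical(c1$intensities, c2$intensities)
})
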