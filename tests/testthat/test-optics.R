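cfg <- optical_config(power = 30e-3, beam_waist = 3e-6)

test_that("beam intensity follows the Gaussian profile on the cell rim", {
  g0 <- cell_geometry(radius = 2e-6, thickness = 0.4e-6, trap_offset = 0)
  # centered point cell: on-axis peak 2P/(pi w0^2), phi-independent
  tiny <- cell_geometry(radius = 1e-12, thickness = 0.5e-12, trap_offset = 0)
  peak <- 2 * cfg$power / (pi * cfg$beam_waist^2)
  expect_equal(beam_intensity(cfg, tiny, 0), peak, tolerance = 1e-9)
  # centered cell with rho = w0: peak * exp(-2), independent of phi
  gw <- cell_geometry(radius = cfg$beam_waist, thickness = 0.4e-6)
  phis <- seq(0, 2 * pi, length.out = 17)[-17]
  expect_equal(beam_intensity(cfg, gw, phis),
               rep(peak * exp(-2), length(phis)))
  # displaced cell: intensity maximal at phi = pi (rim point nearest axis)
  cfg1 <- optical_config(power = 30e-3, beam_waist = 1e-6)
  gd <- cell_geometry(radius = 4e-6, thickness = 0.4e-6,
                      trap_offset = 1e-6)
  expect_gt(beam_intensity(cfg1, gd, pi), beam_intensity(cfg1, gd, 0))
  expect_equal(which.max(beam_intensity(cfg1, gd, phis)),
               which.min(abs(phis - pi)))
  expect_error(beam_intensity(cfg, g0, NaN), "finite")
})

test_that("small-offset force matches an independent hand evaluation", {
  co <- optical_config(power = 30e-3, beam_waist = 3e-6,
                       n_medium = 1.334, index_ratio = 1.05)
  g <- cell_geometry(radius = 2e-6, thickness = 0.4e-6,
                     trap_offset = 0.5e-6)
  # independent re-evaluation of the closed form, term by term
  expected <- 16 * 1.334 * 30e-3 * (2e-6)^2 /
    (2.99792458e8 * (3e-6)^2) *
    abs((1.05^2 - 1) / (1.05^2 + 1)) *
    exp(-2 / (3e-6)^2 * ((2e-6)^2 + (0.5e-6)^2))
  res <- suppressWarnings(trap_force_small_offset(co, g))  # a = 0.44 > 0.1
  expect_equal(res$magnitude, expected, tolerance = 1e-12)
  expect_identical(res$direction_sign, -1L)
  expect_equal(res$small_offset_parameter,
               4 * 0.5e-6 * 2e-6 / (3e-6)^2)
})

test_that("index matching nulls all three force routes exactly", {
  null_cfg <- optical_config(power = 30e-3, beam_waist = 3e-6,
                             index_ratio = 1)
  g <- cell_geometry(radius = 2e-6, thickness = 0.4e-6,
                     trap_offset = 0.3e-6)
  expect_identical(
    suppressWarnings(trap_force_small_offset(null_cfg, g))$magnitude, 0)
  expect_identical(trap_force_exact(null_cfg, g)$magnitude, 0)
  expect_identical(trap_force_numeric(null_cfg, g)$magnitude, 0)
})

test_that("exact force reduces to the small-offset form at zero offset", {
  g0 <- cell_geometry(radius = 2e-6, thickness = 0.4e-6, trap_offset = 0)
  expect_identical(trap_force_exact(cfg, g0)$magnitude,
                   trap_force_small_offset(cfg, g0)$magnitude)
  # at offset parameter 0.05 the Bessel correction is I0(0.05) ~ 1 + a^2/4
  rt <- 0.05 * cfg$beam_waist^2 / (4 * 2e-6)
  ga <- cell_geometry(radius = 2e-6, thickness = 0.4e-6, trap_offset = rt)
  fe <- trap_force_exact(cfg, ga)$magnitude
  fs <- trap_force_small_offset(cfg, ga)$magnitude
  expect_lt(abs(fe - fs) / fe, 0.001)
  expect_equal(fe / fs, 1 + 0.05^2 / 4, tolerance = 1e-5)
})

test_that("small-offset warning fires outside the approximation regime", {
  g <- cell_geometry(radius = 4e-6, thickness = 0.4e-6,
                     trap_offset = 2e-6)
  expect_warning(trap_force_small_offset(cfg, g), "exceeds 0.1")
  expect_error(trap_force_exact(
    optical_config(power = 30e-3, beam_waist = 0.3e-6),
    cell_geometry(radius = 6e-6, thickness = 0.4e-6, trap_offset = 6e-6)),
    "overflow")
})

test_that("exponential decay kills the force at large offsets", {
  g0 <- cell_geometry(radius = 2e-6, thickness = 0.4e-6, trap_offset = 0)
  gfar <- cell_geometry(radius = 2e-6, thickness = 0.4e-6,
                        trap_offset = 10 * cfg$beam_waist)
  f0 <- trap_force_small_offset(cfg, g0)$magnitude
  ffar <- suppressWarnings(trap_force_small_offset(cfg, gfar)$magnitude)
  expect_lt(ffar, 1e-10 * f0)
})

test_that("closed form agrees with the quadrature oracle over random draws", {
  set.seed(421)
  for (i in 1:40) {
    w0 <- runif(1, 1e-6, 5e-6)
    rho <- runif(1, 1e-6, 5e-6)
    a_target <- runif(1, 0, 2)
    rt <- a_target * w0^2 / (4 * rho)
    co <- optical_config(power = runif(1, 1e-3, 50e-3), beam_waist = w0,
                         index_ratio = runif(1, 1.01, 1.1))
    g <- cell_geometry(radius = rho, thickness = rho / 10,
                       trap_offset = rt)
    fe <- trap_force_exact(co, g)$magnitude
    fn <- trap_force_numeric(co, g)$magnitude
    expect_lt(abs(fe - fn) / fn, 0.01)
  }
})

test_that("quadrature agrees with an independent Monte-Carlo surface sample", {
  g <- cell_geometry(radius = 2e-6, thickness = 0.4e-6,
                     trap_offset = 0.8e-6)
  fn <- trap_force_numeric(cfg, g)$magnitude
  # independent route: uniform MC sampling of the azimuthal integral
  set.seed(99)
  phi <- runif(2e5, 0, 2 * pi)
  chi <- abs((1.05^2 - 1) / (1.05^2 + 1))
  pref <- 4 * cfg$n_medium * g$radius / (2.99792458e8 * g$thickness) * chi
  mc <- pref * mean(beam_intensity(cfg, g, phi)) * 2 * pi *
    g$radius * g$thickness
  expect_equal(fn, mc, tolerance = 0.01)
})

test_that("force scales linearly in power and index, rho^2 Gaussian in radius", {
  g0 <- cell_geometry(radius = 2e-6, thickness = 0.4e-6, trap_offset = 0)
  f1 <- trap_force_exact(optical_config(power = 10e-3, beam_waist = 3e-6),
                         g0)$magnitude
  f2 <- trap_force_exact(optical_config(power = 20e-3, beam_waist = 3e-6),
                         g0)$magnitude
  expect_equal(f2 / f1, 2, tolerance = 1e-12)
  fa <- trap_force_exact(optical_config(n_medium = 1.3), g0)$magnitude
  fb <- trap_force_exact(optical_config(n_medium = 1.56), g0)$magnitude
  expect_equal(fb / fa, 1.2, tolerance = 1e-12)
  shape <- function(rho) {
    gg <- cell_geometry(radius = rho, thickness = rho / 10)
    trap_force_exact(cfg, gg)$magnitude /
      (rho^2 * exp(-2 * rho^2 / cfg$beam_waist^2))
  }
  expect_equal(shape(1e-6), shape(4e-6), tolerance = 1e-10)
})

test_that("small-offset error grows monotonically with the offset parameter", {
  rels <- sapply(c(0.02, 0.05, 0.2, 0.5, 1), function(a) {
    rt <- a * cfg$beam_waist^2 / (4 * 2e-6)
    g <- cell_geometry(radius = 2e-6, thickness = 0.4e-6, trap_offset = rt)
    fe <- trap_force_exact(cfg, g)$magnitude
    fs <- suppressWarnings(trap_force_small_offset(cfg, g)$magnitude)
    abs(fe - fs) / fe
  })
  expect_true(all(diff(rels) > 0))
  expect_lt(rels[2], 0.001)
})

test_that("offset profiles are vectorised, ordered and monotone", {
  g <- cell_geometry(radius = 1e-6, thickness = 0.2e-6)
  expect_identical(nrow(force_offset_profile(cfg, g, numeric(0))), 0L)
  single <- force_offset_profile(cfg, g, 0)
  expect_equal(single$magnitude_N, trap_force_exact(cfg, g)$magnitude)
  offs <- seq(0, 0.5e-6, length.out = 6)  # offset parameter stays << 1
  prof <- force_offset_profile(cfg, g, offs)
  expect_true(all(diff(prof$magnitude_N) <= 0))
})
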