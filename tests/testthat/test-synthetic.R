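cfgs <- default_cohort_configs()

test_that("config validation lists offending fields", {
  expect_error(cohort_config("X", "morphology", diameter_mean = -1,
                             diameter_sd = 0.5), "diameter_mean")
  expect_error(cohort_config("X", "elasticity", n_cells = 50,
                             radius_mean = 4.67,
                             radius_range = c(3.84, 5.38),
                             trap_force_mean = 0.26,
                             drag_force_mean = 1.2, stiffness_mean = 1.08),
               "divisible by 7")
  expect_error(cohort_config("X", "elasticity", radius_mean = 3,
                             radius_range = c(4, 5),
                             trap_force_mean = 0.26,
                             drag_force_mean = 1.2, stiffness_mean = 1.08),
               "radius_range")
})

test_that("preset configurations carry the published cohort statistics", {
  expect_equal(cfgs$hbas$trap_force_mean, 0.26)
  expect_equal(cfgs$hbss$trap_force_mean, 0.33)
  expect_equal(cfgs$hbas$radius_mean, 4.67)
  expect_equal(cfgs$hbss$radius_range, c(4.45, 6.12))
  expect_equal(cfgs$hbas$stiffness_mean, 1.08)
  expect_equal(cfgs$hbss$stiffness_mean, 4.47)
  expect_equal(cfgs$sct$diameter_mean, 4.02)
  expect_equal(cfgs$sca$diameter_mean, 6.60)
  expect_equal(cfgs$sca$diameter_sd, 0.90)
})

test_that("generation is deterministic given (config, seed)", {
  a <- generate_elasticity_cohort(cfgs$hbas, seed = 13)
  b <- generate_elasticity_cohort(cfgs$hbas, seed = 13)
  expect_identical(a$records, b$records)
  expect_identical(a$latent, b$latent)
  c2 <- generate_elasticity_cohort(cfgs$hbas, seed = 14)
  expect_false(identical(a$records, c2$records))
  m1 <- generate_morphology_cohort(cfgs$sct, seed = 9)
  m2 <- generate_morphology_cohort(cfgs$sct, seed = 9)
  expect_identical(m1$records, m2$records)
})

test_that("zero diameter spread collapses the morphology cohort", {
  cfg <- cohort_config("X", "morphology", n_cells = 20,
                       diameter_mean = 5, diameter_sd = 0,
                       axis_ratio_sd = 0, noise = 0)
  d <- generate_morphology_cohort(cfg, seed = 1)
  expect_equal(length(unique(d$latent$diameter_um)), 1L)
})

test_that("morphology latents recover the configured mean at large n", {
  cfg <- cohort_config("SCT", "morphology", n_cells = 10000,
                       diameter_mean = 4.02, diameter_sd = 0.60)
  d <- generate_morphology_cohort(cfg, seed = 23)
  expect_lt(abs(mean(d$latent$diameter_um) - 4.02) / 4.02, 0.01)
})

test_that("every elasticity record is physically consistent", {
  for (seed in c(2, 12, 22)) {
    d <- generate_elasticity_cohort(cfgs$hbss, seed = seed)
    r <- d$records
    expect_true(all(r$stretched_rmax_um > r$trapped_rmax_um))
    expect_true(all(r$drag_force_pN > r$trap_force_pN))
    expect_true(all(r$trapped_rmax_um < r$free_rmax_um))
    expect_true(all(r$free_rmax_um >= r$free_rmin_um))
    expect_equal(as.integer(table(r$subgroup)), rep(7L, 7))
  }
})

test_that("ordering survives the independent noise model too", {
  cfg <- cohort_config("HbSS", "elasticity", n_cells = 49,
                       radius_mean = 5.24, radius_range = c(4.45, 6.12),
                       trap_force_mean = 0.33, drag_force_mean = 1.27,
                       stiffness_mean = 4.47, trap_compression_mean = 8,
                       noise = 0.01, noise_model = "independent")
  d <- generate_elasticity_cohort(cfg, seed = 6)
  expect_true(all(d$records$stretched_rmax_um > d$records$trapped_rmax_um))
})

test_that("noiseless cohorts round-trip every latent exactly", {
  cfg <- cfgs$hbas
  cfg$noise <- 0
  d <- generate_elasticity_cohort(cfg, seed = 19)
  m <- cell_metrics(d$records)
  expect_equal(m$stiffness_uN_m, d$latent$stiffness_uN_m,
               tolerance = 1e-10)
  expect_equal(m$pct_dr_free, d$latent$compression_pct, tolerance = 1e-10)
  expect_equal(m$axis_ratio_free, d$latent$axis_ratio, tolerance = 1e-12)
  expect_equal(m$delta_radius_um,
               (d$latent$drag_force_pN - d$latent$trap_force_pN) /
                 d$latent$stiffness_uN_m, tolerance = 1e-10)
})

test_that("49-cell elasticity cohorts recover configured means within 10%", {
  d <- generate_elasticity_cohort(cfgs$hbss, seed = 3)
  m <- cell_metrics(d$records)
  expect_lt(abs(mean(d$records$free_rmax_um) - 5.24) / 5.24, 0.05)
  expect_lt(abs(mean(d$records$trap_force_pN) - 0.33) / 0.33, 0.10)
  expect_lt(abs(mean(d$records$drag_force_pN) - 1.27) / 1.27, 0.10)
  expect_lt(abs(mean(m$stiffness_uN_m) - 4.47) / 4.47, 0.10)
})

test_that("subgroup stage speeds reproduce the drag-force profile", {
  v <- subgroup_stage_speeds(cfgs$hbas)
  expect_length(v, 7)
  drags_pN <- drag_force(cfgs$hbas$fluid, 4.67e-6, v * 1e-6) * 1e12
  expect_equal(mean(drags_pN), 1.20, tolerance = 1e-9)
  # profile shape preserved: monotone mapping to the published subgroup order
  expect_equal(order(drags_pN), order(c(1.48, 1.26, 1.10, 0.853,
                                        0.635, 4.31, 3.23)))
})
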