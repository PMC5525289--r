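test_that("configuration invariants are enforced", {
  expect_s3_class(kinetic_config(), "kinetic_config")
  expect_error(kinetic_config(f_pm = 0.5, f_endo = 0.5, f_deg = 0.5,
                              f_residual = 0.5), "sum to 1")
  expect_error(kinetic_config(t_cytokinesis = -96), "ordered")
  expect_error(kinetic_config(n_zplanes = 0), "n_zplanes")
  expect_error(kinetic_config(frame_interval_min = 0), "frame_interval")
  expect_error(kinetic_config(scenario = "S9"), "scenario")
  expect_error(kinetic_config(baseline_pm = 0.9), "baseline")
})

test_that("scenario overrides realize the four membrane fates", {
  cfg <- kinetic_config()
  s3 <- scenario_override(cfg, "S3")
  expect_equal(s3$f_residual, 1)
  expect_equal(s3$f_pm + s3$f_endo + s3$f_deg + s3$f_ext, 0)
  s1 <- scenario_override(cfg, "S1")
  expect_equal(s1$f_ext, cfg$f_endo)
  expect_equal(s1$f_endo, 0)
  s2 <- scenario_override(cfg, "S2")
  expect_equal(s2$f_residual, cfg$f_residual + cfg$f_endo)
  expect_identical(scenario_override(cfg, "S4")$f_pm, cfg$f_pm)
  expect_error(scenario_override(cfg, "S5"), "scenario")

  # S1: the extracellular pool strictly increases through the exocytosis
  # window; S4: pm and endo increase while extracellular stays flat
  p1 <- simulate_pools(s1)
  exo <- p1$time_min > 0 & p1$time_min <= 10.5
  expect_true(all(diff(p1$extracellular[p1$time_min >= 0 &
                                          p1$time_min <= 10.5]) > 0))
  p4 <- simulate_pools(cfg)
  expect_gt(p4$pm[p4$time_min == 10.5], p4$pm[p4$time_min == 0])
  expect_gt(p4$endo[p4$time_min == 10.5], p4$endo[p4$time_min == 0])
  expect_equal(max(abs(p4$extracellular)), 0)
})

test_that("zero synthesis with an empty transport pool is a fixed point", {
  cfg <- kinetic_config(synthesis_total = 0, f_pm = 0, f_endo = 0,
                        f_deg = 0, f_residual = 1,
                        baseline_pm = 0.5, baseline_transport = 0,
                        baseline_endo = 0.5, n_frames = 30L)
  p <- simulate_pools(cfg)
  for (col in c("pm", "transport", "sdv", "endo", "degraded",
                "extracellular", "residual", "biosilica"))
    expect_equal(max(abs(p[[col]] - p[[col]][1])), 0)
})

test_that("mass balance holds at every frame for random configurations", {
  set.seed(101)
  for (i in 1:100) {
    fr <- stats::rexp(5); fr <- fr / sum(fr)
    bl <- stats::rexp(3); bl <- bl / sum(bl)
    ev <- sort(stats::runif(4, -120, -5))
    cfg <- kinetic_config(
      n_frames = 20L, frame_interval_min = stats::runif(1, 1, 6),
      start_time_min = -130,
      t_nuclear_division = ev[1], t_cytokinesis = ev[2],
      t_sdv_onset = ev[3], t_silica_onset = ev[4],
      t_valve_complete = 0, t_exo_end = stats::runif(1, 2, 20),
      synthesis_total = stats::runif(1, 0, 1),
      f_pm = fr[1], f_endo = fr[2], f_deg = fr[3], f_residual = fr[4],
      f_ext = fr[5],
      baseline_pm = bl[1], baseline_transport = bl[2], baseline_endo = bl[3],
      reporter_type = sample(c("C-tag", "N-tag"), 1))
    p <- simulate_pools(cfg)
    expect_lt(max(abs(pool_mass(p) - (1 + p$synthesized))), 1e-9)
    expect_true(all(as.matrix(p[, 3:10]) > -1e-12))
  }
})

test_that("the plasma-membrane gain is the configured fraction of the SDV pool", {
  cfg <- kinetic_config()
  p <- simulate_pools(cfg)
  i0 <- which(p$time_min == 0)
  i_on <- which(p$time_min == cfg$t_sdv_onset)
  i_end <- which(p$time_min == cfg$t_exo_end)
  delta_pm <- p$pm[i_end] - p$pm[i0]
  delta_sdv <- p$sdv[i0] - p$sdv[i_on]
  expect_equal(delta_pm / delta_sdv, cfg$f_pm, tolerance = 1e-9)
  # independent per-frame accumulation of the partitioned outflow
  exo <- seq(i0 + 1L, i_end)
  outflow <- -diff(p$sdv)[exo - 1L]
  expect_equal(p$pm[i_end] - p$pm[i0], cfg$f_pm * sum(outflow),
               tolerance = 1e-12)
  expect_equal(p$degraded[i_end], cfg$f_deg * sum(outflow),
               tolerance = 1e-12)
  # N-tag reroutes the degraded flux into fluorescent biosilica
  pn <- simulate_pools(kinetic_config(reporter_type = "N-tag"))
  expect_equal(pn$degraded[i_end], 0)
  expect_equal(pn$biosilica[i_end], cfg$f_deg * sum(outflow),
               tolerance = 1e-12)
})
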