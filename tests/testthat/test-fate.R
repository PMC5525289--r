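test_that("window deltas read trace differences at the nearest frames", {
  times <- seq(-14, 14, by = 3.5)
  const <- manual_averaged(list(mid = rep(0.5, 9), pm = rep(1, 9),
                                cyto = rep(1, 9), ext = rep(0, 9)), times)
  expect_equal(window_delta(const, "mid", -7, 7), 0)
  # published plasma-membrane reading: 0.20 RFU -> 0.42 RFU
  pm <- c(rep(0.20, 5), 0.30, 0.38, 0.42, 0.42)
  avg <- manual_averaged(list(pm = pm), times)
  expect_equal(window_delta(avg, "pm", 0, 10.5), 0.42 - 0.20)
  # linear ramp: slope * (t_end - t_start) up to one frame's quantization
  slope <- 0.03
  ramp <- manual_averaged(list(mid = slope * times), times)
  expect_equal(window_delta(ramp, "mid", -10, 10), slope * 21,
               tolerance = 1e-9)  # nearest frames are -10.5 and 10.5
  expect_error(window_delta(ramp, "mid", -100, 0), "outside")
})

test_that("derived fractions reproduce the published arithmetic", {
  rf <- redistribution_fraction(0.42 - 0.20, 1.13 - 0.27)
  expect_equal(rf, 0.22 / 0.86)
  expect_equal(round(100 * rf), 26)       # 25.58%: "~25%" at coarse precision
  expect_true(abs(100 * rf - 25) < 1)
  expect_equal(redistribution_fraction(0, 1), 0)
  expect_equal(redistribution_fraction(1, 1), 1)
  expect_error(redistribution_fraction(0.2, 0), "positive")

  expect_equal(net_synthesis_fraction(1.13 + 0.20 + 0.16, 1.0), 0.49)
  expect_equal(net_synthesis_fraction(2, 2), 0)
  expect_error(net_synthesis_fraction(1, 0), "positive")

  expect_equal(degraded_fraction_of_new(1.5, 1.5, 1.0), 0)
  expect_equal(degraded_fraction_of_new(1.5, 1.0, 1.0), 1)
  expect_error(degraded_fraction_of_new(1.0, 0.9, 1.0), "exceed")
})

test_that("classification rules and precedence resolve the four scenarios", {
  eps <- c(pm = 0.02, endo = 0.02, ext = 0.02)
  # published S4 signature: pm and cytoplasm both gain, nothing outside
  s4 <- classify_scenario(0.22, 0.12, 0.001, retention = 0.41,
                          residual_persists = TRUE, eps = eps)
  expect_equal(s4$scenario, "S4")
  # full retention in the mid region
  s3 <- classify_scenario(0.001, 0.001, 0.001, retention = 0.99,
                          residual_persists = TRUE, eps = eps)
  expect_equal(s3$scenario, "S3")
  # extracellular gain dominates everything (precedence)
  s1 <- classify_scenario(0.22, 0.12, 0.12, retention = 0.99,
                          residual_persists = TRUE, eps = eps)
  expect_equal(s1$scenario, "S1")
  expect_true(s1$evidence[["S3"]])    # fired flags are still reported
  # pm gain without cytoplasm gain plus persistent residue
  s2 <- classify_scenario(0.22, 0.005, 0.001, retention = 0.55,
                          residual_persists = TRUE, eps = eps)
  expect_equal(s2$scenario, "S2")
  none <- classify_scenario(0.001, 0.001, 0.001, retention = 0.2,
                            residual_persists = FALSE, eps = eps)
  expect_equal(none$scenario, "inconclusive")
})

test_that("the fate report is invariant under rescaling of all traces", {
  cfg <- fast_cfg()
  sim <- simulate_cell(cfg, seed = 31)
  ts <- quantify_cell(sim$stack, default_annotation(scene_geometry(), cfg))
  avg <- average_cells(list(ts))
  f1 <- sdv_fate(avg)
  scaled <- avg
  scaled$mean <- scaled$mean * 7.3
  scaled$sd <- scaled$sd * 7.3
  f2 <- sdv_fate(scaled)
  expect_equal(f2$scenario, f1$scenario)
  expect_equal(f2$redistribution_fraction, f1$redistribution_fraction)
  expect_equal(f2$net_synthesis_fraction, f1$net_synthesis_fraction)
  expect_equal(f2$degraded_fraction_of_new, f1$degraded_fraction_of_new)
  expect_equal(f2$retention, f1$retention)
})

test_that("fate accessors and report writing work", {
  cfg <- fast_cfg()
  sim <- simulate_cell(cfg, seed = 32)
  ts <- quantify_cell(sim$stack, default_annotation(scene_geometry(), cfg))
  f <- sdv_fate(average_cells(list(ts)))
  co <- coef(f)
  expect_named(co, c("delta_mid", "delta_pm", "delta_endo", "delta_ext",
                     "redistribution_fraction", "net_synthesis_fraction",
                     "degraded_fraction_of_new", "retention"))
  tmp <- tempfile(fileext = ".json")
  write_fate_report(f, tmp)
  rep <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(rep$scenario, f$scenario)
  expect_equal(rep$deltas$pm, f$delta_pm)
  unlink(tmp)
  expect_output(print(f), "scenario")
  expect_output(summary(f), "windows")
})
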