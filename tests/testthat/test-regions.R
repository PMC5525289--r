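test_that("keyframe interpolation is linear, held at the ends, exact at keys", {
  kf <- data.frame(frame = c(0L, 10L), top = c(1, 1), left = c(1, 1),
                   height = c(10, 20), width = c(8, 8))
  reg <- list(name = "r", role = "mid", keyframes = kf)
  expect_equal(region_at(reg, 5)[["height"]], 15)
  expect_equal(region_at(reg, 0)[["height"]], 10)
  expect_equal(region_at(reg, 10)[["height"]], 20)
  expect_equal(region_at(reg, 25)[["height"]], 20)  # held after last key
  single <- list(name = "s", role = "pm",
                 keyframes = kf[1, , drop = FALSE])
  for (f in c(0, 3, 50)) expect_equal(region_at(single, f)[["height"]], 10)
})

test_that("multi-keyframe paths match the per-segment closed form", {
  kf <- data.frame(frame = c(0L, 8L, 20L),
                   top = c(2, 6, 4), left = c(1, 3, 9),
                   height = c(10, 14, 30), width = c(8, 10, 6))
  reg <- list(name = "r", role = "cyto", keyframes = kf)
  for (f in 0:25)
    expect_equal(region_at(reg, f), oracle_region_at(kf, f),
                 tolerance = 1e-12)
})

test_that("background correction subtracts the global outside minimum", {
  set.seed(43)
  base <- array(stats::runif(5 * 1 * 20 * 20, 0, 10), c(5, 1, 20, 20))
  proj0 <- stack_projection(base, "GFP")
  projb <- stack_projection(base + 7.5, "GFP")
  # make the true outside minimum sit inside the outside rectangle
  proj0$data[3, 1, 2, 2] <- 0
  projb$data[3, 1, 2, 2] <- 7.5
  bg <- background_correct(projb, c(1, 1, 4, 4))
  expect_equal(unname(bg$offsets), 7.5)
  expect_equal(bg$projection$data, proj0$data)
  # all-zero stack is unchanged with offset 0
  z <- stack_projection(array(0, c(2, 1, 8, 8)), "GFP")
  bgz <- background_correct(z, c(1, 1, 3, 3))
  expect_equal(unname(bgz$offsets), 0)
  expect_equal(bgz$projection$data, z$data)
})

test_that("the outside rectangle may not overlap a cell region", {
  cfg <- fast_cfg()
  ann <- default_annotation(scene_geometry(), cfg)
  reg <- keyframed_regions(ann$regions, 80, 80, n_frames = 2L)
  proj <- stack_projection(array(0, c(2, 1, 80, 80)), "GFP")
  expect_error(background_correct(proj, c(30, 30, 10, 10), reg),
               "overlaps")
  expect_silent(background_correct(proj, c(1, 1, 8, 8), reg))
})

test_that("the simulator's camera offset is recovered exactly", {
  cfg <- fast_cfg(n_frames = 10L, start_time_min = -40)  # offset 100/plane
  sim <- simulate_cell(cfg, seed = 9)
  bg <- background_correct(z_project(sim$stack), c(1, 1, 8, 8))
  expect_equal(unname(bg$offsets), rep(100 * cfg$n_zplanes, 2))
})

test_that("region sums conserve the whole-crop total exactly", {
  # uniform image, two half-frame regions: each takes half the total
  arr <- array(1, c(2, 1, 10, 10))
  proj <- stack_projection(arr, "GFP")
  halves <- list(
    list(name = "top", role = "mid",
         keyframes = data.frame(frame = 0L, top = 1, left = 1, height = 5,
                                width = 10)),
    list(name = "bottom", role = "cyto",
         keyframes = data.frame(frame = 0L, top = 6, left = 1, height = 5,
                                width = 10)))
  reg <- keyframed_regions(halves, 10, 10, n_frames = 2L)
  tr <- extract_traces(proj, reg)
  expect_true(all(tr$intensity == 50))
  # random integer stack with the canonical partition: exact conservation
  set.seed(47)
  arr2 <- array(sample(0:100, 3 * 2 * 80 * 80, TRUE), c(3, 2, 80, 80))
  proj2 <- stack_projection(arr2, c("GFP", "PDMPO"))
  ann <- default_annotation(scene_geometry(), fast_cfg())
  reg2 <- keyframed_regions(ann$regions, 80, 80, n_frames = 3L)
  tr2 <- extract_traces(proj2, reg2)
  for (tf in 0:2) for (ch in c("GFP", "PDMPO")) {
    expect_identical(
      sum(tr2$intensity[tr2$frame == tf & tr2$channel == ch]),
      sum(arr2[tf + 1, match(ch, c("GFP", "PDMPO")), , ]) + 0)
  }
  # partition violations are rejected at construction
  bad <- halves
  bad[[2]]$keyframes$height <- 4
  expect_error(keyframed_regions(bad, 10, 10, n_frames = 1L), "partition")
})

test_that("region traces track the simulated pools", {
  cfg <- fast_cfg(drift_per_frame = c(0, 0), camera_offset = 0)
  sim <- simulate_cell(cfg, seed = 21, noise = FALSE)
  proj <- z_project(sim$stack)
  ann <- default_annotation(scene_geometry(), cfg)
  reg <- keyframed_regions(ann$regions, 80, 80, n_frames = cfg$n_frames)
  tr <- extract_traces(proj, reg)
  p <- sim$pools
  role_trace <- function(role, tf)
    sum(tr$intensity[tr$role == role & tr$channel == "GFP" &
                       tr$frame == tf]) / cfg$photon_scale
  for (tf in c(0L, 36L, 39L, 44L)) {
    i <- tf + 1L
    expect_equal(role_trace("mid", tf), p$sdv[i] + p$residual[i],
                 tolerance = 0.02 * max(1, p$sdv[i] + p$residual[i]))
    expect_equal(role_trace("pm", tf), p$pm[i], tolerance = 0.02)
    expect_equal(role_trace("cyto", tf), p$endo[i] + p$transport[i],
                 tolerance = 0.025)
  }
})

test_that("normalization sets the pre-cytokinesis total to one and is idempotent", {
  vals <- list(mid = c(1, 1, 2, 2), pm = c(2, 2, 2, 2),
               cyto = c(1, 1, 1, 1), ext = c(0, 0, 0, 0))
  ts <- manual_traces(vals, times = c(0, 3.5, 7, 10.5))
  ts$time_min <- NA_real_
  attr(ts, "normalized") <- FALSE
  n1 <- normalize_traces(ts, cytokinesis_frame = 2L)
  expect_equal(attr(n1, "norm_constant"), 4)
  expect_equal(n1$intensity, ts$intensity / 4)
  n2 <- normalize_traces(n1, cytokinesis_frame = 2L)
  expect_equal(n2$intensity, n1$intensity)
  # mean pre-cytokinesis total is exactly 1 after normalization
  tot <- tapply(n1$intensity[n1$frame < 2], n1$frame[n1$frame < 2], sum)
  expect_equal(mean(tot), 1, tolerance = 1e-12)
})

test_that("synchronization maps the tracer peak to t = 0 with earliest-tie rule", {
  mk <- function(intens) {
    ts <- manual_traces(list(mid = intens), times = rep(NA_real_,
                                                        length(intens)),
                        channel = "PDMPO")
    attr(ts, "synchronized") <- FALSE
    ts
  }
  ts <- mk(c(rep(0, 37), 1, 0.5, 0.4, rep(0.3, 5)))  # peak at frame 37
  sy <- synchronize_traces(ts)
  expect_equal(attr(sy, "peak_frame"), 37L)
  expect_equal(sy$time_min[sy$frame == 36], -3.5)
  # tie: two equal maxima -> earliest wins
  tie <- mk(c(rep(0, 30), 1, rep(0, 9), 1, 0))
  expect_equal(attr(synchronize_traces(tie), "peak_frame"), 30L)
  expect_error(synchronize_traces(mk(rep(1, 10))), "no peak")
})

test_that("synchronization is equivariant under a uniform event delay", {
  intens <- c(rep(0, 10), seq(0, 1, length.out = 10), rep(0.2, 10))
  mk <- function(shift) {
    v <- c(rep(0, shift), intens)[1:30]
    ts <- manual_traces(list(mid = v), times = rep(NA_real_, 30),
                        channel = "PDMPO")
    attr(ts, "synchronized") <- FALSE
    synchronize_traces(ts)
  }
  s0 <- mk(0); s3 <- mk(3)
  expect_equal(attr(s3, "peak_frame"), attr(s0, "peak_frame") + 3L)
})

test_that("cell averaging uses the sample SD and the n >= 2 rule", {
  t1 <- manual_traces(list(mid = rep(0.4, 4)), times = c(0, 3.5, 7, 10.5))
  t2 <- manual_traces(list(mid = rep(0.6, 4)), times = c(0, 3.5, 7, 10.5),
                      cell_id = "c2")
  avg <- average_cells(list(t1, t2))
  expect_equal(avg$mean, rep(0.5, 4))
  expect_equal(avg$sd, rep(stats::sd(c(0.4, 0.6)), 4))
  expect_equal(round(avg$sd[1], 4), 0.1414)
  one <- average_cells(list(t1))
  expect_equal(one$mean, rep(0.4, 4))
  expect_true(all(is.na(one$sd)))
  expect_true(all(one$n == 1))
})
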