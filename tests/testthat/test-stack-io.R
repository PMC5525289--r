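test_that("TIFF write/read round-trips the array and metadata", {
  set.seed(13)
  arr <- array(sample(0:65535, 5 * 9 * 2 * 32 * 32, replace = TRUE),
               dim = c(5, 9, 2, 32, 32))
  st <- timelapse_stack(arr, c("GFP", "PDMPO"), frame_interval_min = 3.5)
  tmp <- tempfile(fileext = ".tif")
  write_stack(st, tmp)
  back <- read_stack(tmp)
  expect_equal(back$data, arr + 0)   # storage mode numeric
  expect_equal(back$channels, c("GFP", "PDMPO"))
  expect_equal(back$frame_interval_min, 3.5)
  unlink(c(tmp, paste0(tmp, ".json")))
})

test_that("a bare single-page TIFF reads as a 1x1x1 stack with a warning", {
  tmp <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(stats::runif(64), 8, 8), tmp,
                  bits.per.sample = 16L)
  expect_warning(st <- read_stack(tmp), "metadata")
  expect_equal(dim(st$data), c(1L, 1L, 1L, 8L, 8L))
  unlink(tmp)
})

test_that("page counts not divisible by z x channels are rejected", {
  tmp <- tempfile(fileext = ".tif")
  pages <- replicate(17, matrix(stats::runif(16), 4, 4), simplify = FALSE)
  tiff::writeTIFF(pages, tmp, bits.per.sample = 16L)
  expect_error(read_stack(tmp, n_zplanes = 9, channels = c("a", "b")),
               "divisible")
  unlink(tmp)
})

test_that("z-projection is an exact sum", {
  # Z = 1: identity
  arr1 <- array(sample(0:100, 3 * 1 * 1 * 6 * 6, TRUE), c(3, 1, 1, 6, 6))
  st1 <- timelapse_stack(arr1, "GFP")
  expect_equal(z_project(st1)$data[, 1, , ], arr1[, 1, 1, , ] + 0)
  # all-ones 9-plane stack projects to the constant 9
  st9 <- timelapse_stack(array(1, c(2, 9, 1, 5, 5)), "GFP")
  expect_true(all(z_project(st9)$data == 9))
  # total intensity conserved exactly for random integers
  arr <- array(sample(0:5000, 4 * 9 * 2 * 12 * 12, TRUE),
               c(4, 9, 2, 12, 12))
  st <- timelapse_stack(arr, c("GFP", "PDMPO"))
  expect_identical(sum(z_project(st)$data), sum(arr))
})

test_that("rotation by multiples of 90 degrees is exact and composable", {
  set.seed(17)
  proj <- stack_projection(array(stats::runif(2 * 1 * 20 * 20),
                                 c(2, 1, 20, 20)), "GFP")
  r90 <- rotate_projection(proj, 90)
  r360 <- rotate_projection(rotate_projection(r90, 90), 180)
  expect_equal(r360$data, proj$data)
  expect_equal(rotate_projection(proj, 180)$data,
               rotate_projection(rotate_projection(proj, 90), 90)$data)
})

test_that("rotation before quantification leaves traces unchanged (180 deg)", {
  cfg <- fast_cfg(n_frames = 8L, start_time_min = -40,
                  drift_per_frame = c(0, 0), camera_offset = 0)
  sim <- simulate_cell(cfg, seed = 7, noise = FALSE)
  proj <- z_project(sim$stack)
  n <- 80L
  ann <- default_annotation(scene_geometry(), fast_cfg())
  reg <- keyframed_regions(ann$regions, n, n, n_frames = cfg$n_frames)
  tr0 <- extract_traces(proj, reg)
  # rotate the movie and the rectangles together
  rot_regions <- lapply(ann$regions, function(r) {
    kf <- r$keyframes
    kf$top <- n + 1L - (kf$top + kf$height - 1L)
    kf$left <- n + 1L - (kf$left + kf$width - 1L)
    r$keyframes <- kf
    r
  })
  reg180 <- keyframed_regions(rot_regions, n, n, n_frames = cfg$n_frames)
  tr180 <- extract_traces(rotate_projection(proj, 180), reg180)
  expect_equal(tr180$intensity, tr0$intensity, tolerance = 1e-12)
})

test_that("annotations round-trip through YAML", {
  cfg <- fast_cfg()
  ann <- default_annotation(scene_geometry(), cfg)
  tmp <- tempfile(fileext = ".yaml")
  write_annotation(ann, tmp)
  back <- read_annotation(tmp)
  expect_equal(back$cell_id, ann$cell_id)
  expect_equal(back$cytokinesis_frame, ann$cytokinesis_frame)
  expect_equal(unname(back$outside_rect), unname(unlist(ann$outside_rect)))
  expect_equal(length(back$regions), length(ann$regions))
  expect_equal(back$regions[[8]]$role, ann$regions[[8]]$role)
  expect_equal(unlist(back$regions[[8]]$keyframes),
               unlist(ann$regions[[8]]$keyframes))
  unlink(tmp)
})
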