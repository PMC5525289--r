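# Rendering of synthetic dual-channel time-lapse stacks.
#
# The scene is a side view of a dividing cylindrical diatom drawn as a
# rounded box: the plasma membrane is a soft rectangular frame, the two
# daughter valve SDVs form a band across the mid-cell cleavage plane,
# mobile transport vesicles are diffuse lobes in the two daughter
# cytoplasms, endosomes are moving Gaussian spots, and (scenario S1 only)
# secreted material appears in extracellular bands. All primitives are
# analytic, so sub-pixel drift shifts the scene smoothly; out-of-focus
# z-planes are emulated by widening the primitives and down-weighting the
# plane. Every component is normalized so that its whole-frame,
# z-summed integral equals its pool value exactly (in expectation when
# noise is on).

#' Scene geometry for the synthetic time-lapse generator
#'
#' Default geometry is an 80 x 80 px field tiled by the canonical
#' quantification regions (see [default_annotation()]): extracellular
#' margins, plasma-membrane strips, two cytoplasm bands and the mid-cell
#' band. Cell-associated primitives keep at least 10 px of extracellular
#' margin on every side.
#'
#' @param ny,nx Image size in pixels.
#' @param pm_sigma Gaussian cross-section SD of the membrane frame, px.
#' @param band_sigma Vertical SD of the mid-cell SDV band, px.
#' @param edge_sigma Softness of box edges, px.
#' @param n_spots Number of endosome spots per daughter cell.
#' @param spot_sigma Gaussian SD of a spot, px.
#' @param spot_step_sd Random-walk step SD of spot centers, px/frame.
#' @param defocus_per_plane Extra blur SD per z-plane away from focus, px.
#' @param z_weight_sigma SD (in planes) of the in-focus intensity profile.
#' @return An object of class `scene_geometry`.
#' @export
scene_geometry <- function(ny = 80L, nx = 80L,
                           pm_sigma = 1.0, band_sigma = 2.0,
                           edge_sigma = 1.5,
                           n_spots = 6L, spot_sigma = 1.3,
                           spot_step_sd = 0.8,
                           defocus_per_plane = 0.3,
                           z_weight_sigma = 1.5) {
  ny <- as.integer(ny); nx <- as.integer(nx)
  if (ny < 64L || nx < 64L) stop("image must be at least 64 x 64 px")
  sy <- ny / 80; sx <- nx / 80  # geometry scales with the field
  g <- list(
    ny = ny, nx = nx,
    box = c(top = 12.5 * sy, bottom = 67.5 * sy,
            left = 12.5 * sx, right = 68.5 * sx),
    mid_y = 40 * sy, band_sigma = band_sigma,
    band_x = c(22 * sx, 59 * sx),
    lobe_y = list(c(22.5 * sy, 27.5 * sy), c(52.5 * sy, 57.5 * sy)),
    lobe_x = c(24 * sx, 57 * sx),
    ext_y = list(c(3 * sy, 6 * sy), c(74 * sy, 77 * sy)),
    ext_x = c(24 * sx, 57 * sx),
    spot_bounds_y = list(c(22.5 * sy, 27.5 * sy), c(52.5 * sy, 57.5 * sy)),
    spot_bounds_x = c(24 * sx, 57 * sx),
    pm_sigma = pm_sigma, edge_sigma = edge_sigma,
    n_spots = as.integer(n_spots), spot_sigma = spot_sigma,
    spot_step_sd = spot_step_sd,
    defocus_per_plane = defocus_per_plane,
    z_weight_sigma = z_weight_sigma)
  # cell-associated shapes keep >= 10 px extracellular margin
  stopifnot(g$box["top"] >= 10, g$box["left"] >= 10,
            ny - g$box["bottom"] >= 10, nx - g$box["right"] >= 10)
  class(g) <- "scene_geometry"
  g
}

# 1-D primitives -------------------------------------------------------------

.gauss_line <- function(coords, center, sigma) {
  exp(-((coords - center)^2) / (2 * sigma^2))
}

.smooth_box <- function(coords, lo, hi, sigma) {
  stats::pnorm((coords - lo) / sigma) - stats::pnorm((coords - hi) / sigma)
}

# per-frame, per-z unnormalized component images (list of nz matrices)
.component_planes <- function(kind, g, nz, shift, spots = NULL) {
  yy <- seq_len(g$ny); xx <- seq_len(g$nx)
  zc <- (nz + 1) / 2
  out <- vector("list", nz)
  wz <- .gauss_line(seq_len(nz), zc, g$z_weight_sigma)
  wz <- wz / sum(wz)
  for (z in seq_len(nz)) {
    blur <- g$defocus_per_plane * abs(z - zc)
    se <- sqrt(g$edge_sigma^2 + blur^2)
    img <- switch(kind,
      pm = {
        sp <- sqrt(g$pm_sigma^2 + blur^2)
        top <- g$box["top"] + shift[1L]; bot <- g$box["bottom"] + shift[1L]
        lef <- g$box["left"] + shift[2L]; rig <- g$box["right"] + shift[2L]
        bx <- .smooth_box(xx, lef, rig, se)
        by <- .smooth_box(yy, top, bot, se)
        outer(.gauss_line(yy, top, sp), bx) +
          outer(.gauss_line(yy, bot, sp), bx) +
          outer(by, .gauss_line(xx, lef, sp)) +
          outer(by, .gauss_line(xx, rig, sp))
      },
      band = {
        sb <- sqrt(g$band_sigma^2 + blur^2)
        outer(.gauss_line(yy, g$mid_y + shift[1L], sb),
              .smooth_box(xx, g$band_x[1L] + shift[2L],
                          g$band_x[2L] + shift[2L], se))
      },
      lobes = {
        bx <- .smooth_box(xx, g$lobe_x[1L] + shift[2L],
                          g$lobe_x[2L] + shift[2L], se)
        outer(.smooth_box(yy, g$lobe_y[[1L]][1L] + shift[1L],
                          g$lobe_y[[1L]][2L] + shift[1L], se), bx) +
          outer(.smooth_box(yy, g$lobe_y[[2L]][1L] + shift[1L],
                            g$lobe_y[[2L]][2L] + shift[1L], se), bx)
      },
      ext = {
        bx <- .smooth_box(xx, g$ext_x[1L] + shift[2L],
                          g$ext_x[2L] + shift[2L], se)
        outer(.smooth_box(yy, g$ext_y[[1L]][1L] + shift[1L],
                          g$ext_y[[1L]][2L] + shift[1L], se), bx) +
          outer(.smooth_box(yy, g$ext_y[[2L]][1L] + shift[1L],
                            g$ext_y[[2L]][2L] + shift[1L], se), bx)
      },
      spots = {
        ss <- sqrt(g$spot_sigma^2 + blur^2)
        img <- matrix(0, g$ny, g$nx)
        for (k in seq_len(nrow(spots))) {
          img <- img + outer(
            .gauss_line(yy, spots[k, 1L] + shift[1L], ss),
            .gauss_line(xx, spots[k, 2L] + shift[2L], ss))
        }
        img
      },
      interior = {
        outer(.smooth_box(yy, g$box["top"] + shift[1L] + 2,
                          g$box["bottom"] + shift[1L] - 2, se),
              .smooth_box(xx, g$box["left"] + shift[2L] + 2,
                          g$box["right"] + shift[2L] - 2, se))
      },
      stop("unknown component kind"))
    out[[z]] <- img * wz[z]
  }
  out
}

# reflected Gaussian random walk for spot centers, one row per spot
.step_spots <- function(spots, g) {
  reflect <- function(v, lo, hi) {
    # reflect into [lo, hi] (assumes step small relative to range)
    v <- ifelse(v < lo, 2 * lo - v, v)
    ifelse(v > hi, 2 * hi - v, v)
  }
  n <- nrow(spots)
  spots[, 1L] <- spots[, 1L] + stats::rnorm(n, 0, g$spot_step_sd)
  spots[, 2L] <- spots[, 2L] + stats::rnorm(n, 0, g$spot_step_sd)
  half <- seq_len(n) <= n / 2
  for (i in seq_len(n)) {
    by <- g$spot_bounds_y[[if (half[i]) 1L else 2L]]
    spots[i, 1L] <- reflect(spots[i, 1L], by[1L], by[2L])
    spots[i, 2L] <- reflect(spots[i, 2L], g$spot_bounds_x[1L],
                            g$spot_bounds_x[2L])
  }
  spots
}

.drift_trajectory <- function(cfg) {
  n <- cfg$n_frames
  d <- cfg$drift_per_frame
  if (is.null(d)) return(matrix(0, n, 2L))
  if (is.matrix(d)) {
    if (nrow(d) != n || ncol(d) != 2L)
      stop("drift matrix must be n_frames x 2")
    return(d)
  }
  if (length(d) != 2L) stop("drift_per_frame must be c(dy, dx) or a matrix")
  cbind((seq_len(n) - 1L) * d[1L], (seq_len(n) - 1L) * d[2L])
}

#' Render a synthetic time-lapse stack from pool trajectories
#'
#' Draws, per frame and z-plane, the plasma-membrane frame (intensity
#' proportional to the pm pool), the mid-cell SDV band (sdv + residual
#' pools, plus biosilica for an N-terminal tag), cytoplasmic transport
#' lobes, moving endosome spots, and extracellular bands; the tracer
#' channel carries the cumulative silica in the mid-cell band with the
#' post-exocytosis quench applied. The configured drift shifts the whole
#' scene. With `noise = TRUE`, Poisson photon noise (at
#' `photon_scale` counts/RFU) and optional Gaussian read noise are applied
#' and the camera offset added; pixel values are integer counts clamped to
#' the 16-bit range. With `noise = FALSE` the expected counts are returned
#' unrounded.
#'
#' @param pools A `pool_trajectory` from [simulate_pools()].
#' @param geometry A `scene_geometry`.
#' @param cfg The `kinetic_config` used for the pools.
#' @param noise Apply the noise model (default `TRUE`).
#' @return List with `stack` (a [timelapse_stack()]) and `truth` (list:
#'   `pools`, `shifts`, `events`, `config`, `geometry`).
#' @export
render_stack <- function(pools, geometry, cfg, noise = TRUE) {
  stopifnot(inherits(pools, "pool_trajectory"),
            inherits(geometry, "scene_geometry"),
            inherits(cfg, "kinetic_config"))
  if (nrow(pools) != cfg$n_frames)
    stop("pool trajectory and config disagree on frame count")
  g <- geometry
  nT <- cfg$n_frames; nz <- cfg$n_zplanes
  channels <- c("GFP", "PDMPO")
  if (cfg$include_chlorophyll) channels <- c(channels, "CHL")
  nc <- length(channels)
  shifts <- .drift_trajectory(cfg)
  scale <- cfg$photon_scale

  arr <- array(0, dim = c(nT, nz, nc, g$ny, g$nx))
  # spot centers: half in each daughter cytoplasm
  n_sp <- 2L * g$n_spots
  spots <- matrix(0, n_sp, 2L)
  for (i in seq_len(n_sp)) {
    by <- g$spot_bounds_y[[if (i <= g$n_spots) 1L else 2L]]
    spots[i, 1L] <- stats::runif(1L, by[1L], by[2L])
    spots[i, 2L] <- stats::runif(1L, g$spot_bounds_x[1L], g$spot_bounds_x[2L])
  }

  add_component <- function(tf, ch, kind, amount, shift, spots = NULL) {
    if (amount <= 0) return(invisible())
    planes <- .component_planes(kind, g, nz, shift, spots)
    tot <- sum(vapply(planes, sum, numeric(1L)))
    f <- amount * scale / tot
    for (z in seq_len(nz))
      arr[tf, z, ch, , ] <<- arr[tf, z, ch, , ] + planes[[z]] * f
    invisible()
  }

  for (tf in seq_len(nT)) {
    if (tf > 1L) spots <- .step_spots(spots, g)
    sh <- shifts[tf, ]
    p <- pools[tf, ]
    band_amt <- p$sdv + p$residual +
      if (cfg$reporter_type == "N-tag") p$biosilica else 0
    add_component(tf, 1L, "pm", p$pm, sh)
    add_component(tf, 1L, "band", band_amt, sh)
    add_component(tf, 1L, "lobes", p$transport, sh)
    add_component(tf, 1L, "spots", p$endo, sh, spots)
    add_component(tf, 1L, "ext", p$extracellular, sh)
    add_component(tf, 2L, "band", p$tracer, sh)
    if (nc == 3L) add_component(tf, 3L, "interior", 0.5, sh)
  }

  if (noise) {
    n_px <- length(arr)
    arr[] <- stats::rpois(n_px, arr)
    if (cfg$read_noise_sd > 0)
      arr[] <- arr + stats::rnorm(n_px, 0, cfg$read_noise_sd)
    arr[] <- round(arr + cfg$camera_offset)
    arr[arr < 0] <- 0
    arr[arr > 65535] <- 65535
  } else {
    arr[] <- arr + cfg$camera_offset
  }

  stack <- timelapse_stack(arr, channels = channels,
                           frame_interval_min = cfg$frame_interval_min)
  truth <- list(pools = pools, shifts = shifts,
                events = attr(pools, "events"),
                config = cfg, geometry = unclass(g))
  list(stack = stack, truth = truth)
}

#' Simulate one cell end to end
#'
#' Convenience wrapper: seeds the RNG, simulates the pool kinetics and
#' renders the stack.
#'
#' @param cfg A `kinetic_config`.
#' @param geometry A `scene_geometry` (default [scene_geometry()]).
#' @param seed Integer seed for this cell's random stream (falls back to
#'   `cfg$seed`).
#' @param noise Apply the noise model.
#' @return As [render_stack()], plus element `pools`.
#' @export
simulate_cell <- function(cfg, geometry = scene_geometry(), seed = NULL,
                          noise = TRUE) {
  seed <- if (!is.null(seed)) seed else cfg$seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  pools <- simulate_pools(cfg)
  out <- render_stack(pools, geometry, cfg, noise = noise)
  out$pools <- pools
  out
}

#' Write simulation ground truth as JSON
#'
#' Sidecar with the config echo, event times, per-frame pool table and the
#' drift trajectory.
#'
#' @param truth The `truth` element returned by [render_stack()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(
    config = truth$config[setdiff(names(truth$config), "seed")],
    events = as.list(truth$events),
    shifts = unname(apply(truth$shifts, 1L, function(r) c(dy = r[1L], dx = r[2L]),
                          simplify = FALSE)),
    pools = as.list(as.data.frame(truth$pools)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
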