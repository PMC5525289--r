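# Time-lapse stack container and TIFF I/O.
#
# Stacks are 5-D arrays indexed [t, z, c, y, x]. Pixel coordinates are
# (row, col); frame indices are 0-based in all user-facing tables, while
# array indexing inside the package is 1-based R convention. The physical
# time axis is attached only at synchronization.

#' Construct a time-lapse stack
#'
#' @param data 5-D numeric array `[t, z, c, y, x]`.
#' @param channels Character vector of unique channel names, one per
#'   channel plane.
#' @param frame_interval_min Frame interval in minutes.
#' @param timestamps Optional per-frame acquisition times (minutes).
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(data, channels, frame_interval_min = 3.5,
                            timestamps = NULL) {
  if (!is.array(data) || length(dim(data)) != 5L)
    stop("'data' must be a 5-D array [t, z, c, y, x]")
  d <- dim(data)
  if (any(d < 1L)) stop("all stack dimensions must be >= 1")
  if (length(channels) != d[3L]) stop("one channel name per channel plane")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  if (!is.null(timestamps) && length(timestamps) != d[1L])
    stop("one timestamp per frame")
  structure(list(data = data, channels = as.character(channels),
                 frame_interval_min = frame_interval_min,
                 timestamps = timestamps),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Time-lapse stack: %d frames x %d z x %d ch (%s), %d x %d px, %.2f min/frame\n",
              d[1L], d[2L], d[3L], paste(x$channels, collapse = ","),
              d[4L], d[5L], x$frame_interval_min))
  invisible(x)
}

#' @export
dim.timelapse_stack <- function(x) dim(x$data)

#' Write a stack as multi-page 16-bit TIFF with a JSON sidecar
#'
#' Pages are ordered frame-major, then z, then channel. Pixel values are
#' clamped to 0..65535 and rounded to integers. Metadata (channel names,
#' z-count, frame interval) goes to `<path>.json`.
#'
#' @param stack A `timelapse_stack`.
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$data)
  pages <- vector("list", d[1L] * d[2L] * d[3L])
  i <- 0L
  for (tf in seq_len(d[1L])) for (z in seq_len(d[2L])) for (ch in seq_len(d[3L])) {
    i <- i + 1L
    m <- stack$data[tf, z, ch, , ]
    m <- round(pmin(pmax(m, 0), 65535))
    pages[[i]] <- m / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(channels = stack$channels, n_zplanes = d[2L],
               n_frames = d[1L],
               frame_interval_min = stack$frame_interval_min,
               timestamps = stack$timestamps)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-page TIFF into a time-lapse stack
#'
#' Metadata is taken from the `<path>.json` sidecar written by
#' [write_stack()] when present; otherwise from the arguments, defaulting
#' to a single z-plane, single unnamed channel (with a warning). The page
#' count must be divisible by `n_zplanes * length(channels)`.
#'
#' @param path TIFF path.
#' @param n_zplanes,channels,frame_interval_min Metadata used when no
#'   sidecar is present.
#' @return A `timelapse_stack` with integer pixel counts.
#' @export
read_stack <- function(path, n_zplanes = NULL, channels = NULL,
                       frame_interval_min = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(n_zplanes)) n_zplanes <- meta$n_zplanes
    if (is.null(channels)) channels <- meta$channels
    if (is.null(frame_interval_min)) frame_interval_min <- meta$frame_interval_min
  }
  if (is.null(n_zplanes) || is.null(channels)) {
    warning("no stack metadata found; assuming 1 z-plane, 1 channel")
    if (is.null(n_zplanes)) n_zplanes <- 1L
    if (is.null(channels)) channels <- "ch1"
  }
  if (is.null(frame_interval_min)) frame_interval_min <- 3.5
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1L]])
  if (any(!vapply(pages, function(p) identical(dim(p), shp), logical(1L))))
    stop("inconsistent page shapes in TIFF")
  nz <- as.integer(n_zplanes); nc <- length(channels)
  if (length(pages) %% (nz * nc) != 0L)
    stop(sprintf("page count %d not divisible by z*channels = %d",
                 length(pages), nz * nc))
  nT <- length(pages) %/% (nz * nc)
  arr <- array(0, dim = c(nT, nz, nc, shp[1L], shp[2L]))
  i <- 0L
  for (tf in seq_len(nT)) for (z in seq_len(nz)) for (ch in seq_len(nc)) {
    i <- i + 1L
    arr[tf, z, ch, , ] <- pages[[i]]
  }
  timelapse_stack(arr, channels = channels,
                  frame_interval_min = frame_interval_min)
}

#' Sum-project a stack along z
#'
#' Intensities of all z-planes are summed (not averaged or maximized):
#' the sum preserves the linear relation between pool amounts and region
#' integrals, and total intensity is conserved exactly for integer input.
#'
#' @param stack A `timelapse_stack`.
#' @return An object of class `stack_projection`: list with `data`
#'   (`[t, c, y, x]` array), `channels`, `frame_interval_min`.
#' @export
z_project <- function(stack) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$data)
  # sum over the z margin
  proj <- apply(stack$data, c(1L, 3L, 4L, 5L), sum)
  stack_projection(proj, stack$channels, stack$frame_interval_min)
}

#' Construct a projection object
#'
#' @param data 4-D array `[t, c, y, x]`.
#' @param channels Channel names.
#' @param frame_interval_min Frame interval in minutes.
#' @return A `stack_projection`.
#' @export
stack_projection <- function(data, channels, frame_interval_min = 3.5) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("'data' must be a 4-D array [t, c, y, x]")
  if (length(channels) != dim(data)[2L]) stop("one channel name per channel")
  structure(list(data = data, channels = as.character(channels),
                 frame_interval_min = frame_interval_min),
            class = "stack_projection")
}

#' @export
print.stack_projection <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Projection: %d frames x %d ch (%s), %d x %d px\n",
              d[1L], d[2L], paste(x$channels, collapse = ","), d[3L], d[4L]))
  invisible(x)
}

# bilinear sampling of one image at (yq, xq) matrices; zero outside
.bilinear_sample <- function(img, yq, xq) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- floor(yq); x0 <- floor(xq)
  fy <- yq - y0; fx <- xq - x0
  get <- function(yy, xx) {
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    v <- numeric(length(yy))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  v <- get(y0, x0) * (1 - fy) * (1 - fx) +
    get(y0 + 1, x0) * fy * (1 - fx) +
    get(y0, x0 + 1) * (1 - fy) * fx +
    get(y0 + 1, x0 + 1) * fy * fx
  matrix(v, ny, nx)
}

#' Rotate a projection about its center
#'
#' Bilinear interpolation with zero fill; multiples of 90 degrees are
#' handled exactly. Used to align cells vertically before quantification.
#'
#' @param proj A `stack_projection`.
#' @param angle_deg Counter-clockwise rotation in degrees.
#' @return A rotated `stack_projection`.
#' @export
rotate_projection <- function(proj, angle_deg) {
  stopifnot(inherits(proj, "stack_projection"))
  a <- angle_deg %% 360
  d <- dim(proj$data)
  rot90 <- function(m, k) {
    k <- k %% 4L
    if (k == 0L) return(m)
    for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
    m
  }
  if (a %% 90 == 0) {
    k <- as.integer(a / 90)
    sample1 <- function(m) rot90(m, k)
    if (k %% 2L == 1L) {
      out <- array(0, dim = c(d[1L], d[2L], d[4L], d[3L]))
    } else out <- array(0, dim = d)
  } else {
    th <- a * pi / 180
    ny <- d[3L]; nx <- d[4L]
    cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    # inverse mapping: sample source at R(-theta) applied to output coords
    yq <- cy + cos(th) * (yy - cy) - sin(th) * (xx - cx)
    xq <- cx + sin(th) * (yy - cy) + cos(th) * (xx - cx)
    sample1 <- function(m) .bilinear_sample(m, yq, xq)
    out <- array(0, dim = d)
  }
  for (tf in seq_len(d[1L])) for (ch in seq_len(d[2L]))
    out[tf, ch, , ] <- sample1(proj$data[tf, ch, , ])
  stack_projection(out, proj$channels, proj$frame_interval_min)
}

#' Crop a projection
#'
#' @param proj A `stack_projection`.
#' @param rect Integer rectangle `c(top, left, height, width)`, 1-based.
#' @return The cropped `stack_projection`.
#' @export
crop_projection <- function(proj, rect) {
  stopifnot(inherits(proj, "stack_projection"), length(rect) == 4L)
  d <- dim(proj$data)
  rows <- rect[1L]:(rect[1L] + rect[3L] - 1L)
  cols <- rect[2L]:(rect[2L] + rect[4L] - 1L)
  if (min(rows) < 1L || max(rows) > d[3L] || min(cols) < 1L ||
      max(cols) > d[4L]) stop("crop rectangle outside image bounds")
  stack_projection(proj$data[, , rows, cols, drop = FALSE],
                   proj$channels, proj$frame_interval_min)
}

#' Read a cell annotation from YAML
#'
#' The annotation carries everything the quantification needs: rotation
#' angle, crop rectangle, outside-cell background rectangle, the keyframed
#' regions, and event frame indices (0-based).
#'
#' @param path YAML file path.
#' @return An object of class `cell_annotation`.
#' @export
read_annotation <- function(path) {
  y <- yaml::read_yaml(path)
  regions <- lapply(y$regions, function(r) {
    kf <- do.call(rbind, lapply(r$keyframes, function(k)
      data.frame(frame = k$frame, top = k$rect[[1L]], left = k$rect[[2L]],
                 height = k$rect[[3L]], width = k$rect[[4L]])))
    list(name = r$name, role = r$role, keyframes = kf)
  })
  cell_annotation(
    cell_id = if (!is.null(y$cell_id)) y$cell_id else "cell",
    rotation_deg = if (!is.null(y$rotation_deg)) y$rotation_deg else 0,
    crop = if (!is.null(y$crop)) unlist(y$crop) else NULL,
    outside_rect = unlist(y$outside_rect),
    cytokinesis_frame = y$cytokinesis_frame,
    regions = regions)
}

#' Write a cell annotation to YAML
#'
#' @param annotation A `cell_annotation`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "cell_annotation"))
  a <- annotation
  y <- list(
    cell_id = a$cell_id, rotation_deg = a$rotation_deg,
    crop = if (!is.null(a$crop)) as.list(unname(a$crop)) else NULL,
    outside_rect = as.list(unname(a$outside_rect)),
    cytokinesis_frame = a$cytokinesis_frame,
    regions = lapply(a$regions, function(r) list(
      name = r$name, role = r$role,
      keyframes = lapply(seq_len(nrow(r$keyframes)), function(i) list(
        frame = r$keyframes$frame[i],
        rect = as.list(unname(unlist(
          r$keyframes[i, c("top", "left", "height", "width")]))))))))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Construct a cell annotation
#'
#' @param cell_id Identifier used in trace tables.
#' @param rotation_deg Rotation (degrees, counter-clockwise) to align the
#'   cell vertically.
#' @param crop Optional crop rectangle `c(top, left, height, width)`.
#' @param outside_rect Outside-cell rectangle for background estimation.
#' @param cytokinesis_frame 0-based frame index of cytokinesis completion;
#'   frames before it define the normalization reference.
#' @param regions List of keyframed regions (each a list with `name`,
#'   `role`, `keyframes` data frame).
#' @param nuclear_division_frame Optional 0-based event frame.
#' @return An object of class `cell_annotation`.
#' @export
cell_annotation <- function(cell_id = "cell", rotation_deg = 0, crop = NULL,
                            outside_rect, cytokinesis_frame, regions,
                            nuclear_division_frame = NULL) {
  for (r in regions) {
    if (is.unsorted(r$keyframes$frame, strictly = TRUE) &&
        nrow(r$keyframes) > 1L)
      stop("keyframe frame indices must be strictly increasing (region ",
           r$name, ")")
  }
  structure(list(cell_id = cell_id, rotation_deg = rotation_deg,
                 crop = crop, outside_rect = outside_rect,
                 cytokinesis_frame = cytokinesis_frame,
                 nuclear_division_frame = nuclear_division_frame,
                 regions = regions),
            class = "cell_annotation")
}

#' Default annotation matching the simulator's scene geometry
#'
#' Tiles the field into the canonical partition: extracellular margins,
#' plasma-membrane strips (left/right columns plus top/bottom bands),
#' two cytoplasm bands and the mid-cell band. Static regions (one keyframe
#' each). The cytokinesis frame is derived from the configured event time.
#'
#' @param geometry A `scene_geometry`.
#' @param cfg The matching `kinetic_config`.
#' @param cell_id Identifier for the trace tables.
#' @return A `cell_annotation`.
#' @export
default_annotation <- function(geometry, cfg, cell_id = "cell") {
  g <- geometry
  ny <- g$ny; nx <- g$nx
  r <- round(c(8, 16, 33, 46, 63, 71) * ny / 80)
  cc <- round(c(8, 16, 64, 72) * nx / 80)
  rect <- function(top, left, height, width)
    data.frame(frame = 0L, top = top, left = left, height = height,
               width = width)
  reg <- function(name, role, top, bottom, left, right)
    list(name = name, role = role,
         keyframes = rect(top, left, bottom - top + 1L, right - left + 1L))
  cw <- c(cc[2L] + 1L, cc[3L])  # center column bounds
  regions <- list(
    reg("ext_left", "ext", 1L, ny, 1L, cc[1L]),
    reg("pm_left", "pm", 1L, ny, cc[1L] + 1L, cc[2L]),
    reg("pm_right", "pm", 1L, ny, cc[3L] + 1L, cc[4L]),
    reg("ext_right", "ext", 1L, ny, cc[4L] + 1L, nx),
    reg("ext_top", "ext", 1L, r[1L], cw[1L], cw[2L]),
    reg("pm_top", "pm", r[1L] + 1L, r[2L], cw[1L], cw[2L]),
    reg("cyto_top", "cyto", r[2L] + 1L, r[3L], cw[1L], cw[2L]),
    reg("mid", "mid", r[3L] + 1L, r[4L], cw[1L], cw[2L]),
    reg("cyto_bottom", "cyto", r[4L] + 1L, r[5L], cw[1L], cw[2L]),
    reg("pm_bottom", "pm", r[5L] + 1L, r[6L], cw[1L], cw[2L]),
    reg("ext_bottom", "ext", r[6L] + 1L, ny, cw[1L], cw[2L]))
  tt <- cfg$start_time_min + cfg$frame_interval_min * (seq_len(cfg$n_frames) - 1L)
  cyto_frame <- which(tt >= cfg$t_cytokinesis)[1L] - 1L
  if (is.na(cyto_frame) || cyto_frame < 1L)
    stop("movie does not include pre-cytokinesis frames")
  cell_annotation(
    cell_id = cell_id, rotation_deg = 0, crop = NULL,
    outside_rect = c(1L, 1L, r[1L], cc[1L]),
    cytokinesis_frame = cyto_frame,
    regions = regions)
}
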