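# Region-based trace extraction: keyframed rectangles, background
# correction, per-region sums, normalization, synchronization, averaging.
#
# Region roles: "mid" (mid-cell band where the valve SDVs form), "pm"
# (plasma-membrane strips), "cyto" (cytoplasm), "ext" (extracellular).
# Rectangles are (top, left, height, width) in pixels, 1-based; keyframe
# frame indices are 0-based like all frame indices in trace tables.

REGION_ROLES <- c("mid", "pm", "cyto", "ext")

#' Construct a keyframed region set
#'
#' Each region carries an ordered list of (frame, rectangle) key pairs;
#' geometry at other frames is linearly interpolated (see [region_at()]).
#' On construction the partition property is validated: at every frame the
#' pixelized regions must be pairwise disjoint and cover the full crop.
#'
#' @param regions List of regions: each a list with `name`, `role` (one of
#'   mid/pm/cyto/ext) and `keyframes` (data frame `frame`, `top`, `left`,
#'   `height`, `width`).
#' @param ny,nx Crop size in pixels.
#' @param n_frames Number of movie frames to validate over.
#' @param validate Check the partition property (default `TRUE`).
#' @return An object of class `keyframed_regions`.
#' @export
keyframed_regions <- function(regions, ny, nx, n_frames = NULL,
                              validate = TRUE) {
  for (r in regions) {
    if (!all(c("name", "role", "keyframes") %in% names(r)))
      stop("each region needs 'name', 'role' and 'keyframes'")
    if (!r$role %in% REGION_ROLES)
      stop("unknown region role: ", r$role)
    if (nrow(r$keyframes) < 1L) stop("region ", r$name, " has no keyframes")
    if (nrow(r$keyframes) > 1L &&
        is.unsorted(r$keyframes$frame, strictly = TRUE))
      stop("keyframes of region ", r$name, " not strictly increasing")
  }
  if (anyDuplicated(vapply(regions, `[[`, "", "name")))
    stop("region names must be unique")
  obj <- structure(list(regions = regions, ny = as.integer(ny),
                        nx = as.integer(nx)),
                   class = "keyframed_regions")
  if (validate) {
    frames <- if (is.null(n_frames)) {
      unique(unlist(lapply(regions, function(r) r$keyframes$frame)))
    } else 0:(n_frames - 1L)
    for (f in frames) {
      cover <- matrix(0L, ny, nx)
      for (r in regions) {
        px <- .rect_pixels(region_at(r, f), ny, nx)
        cover[px$rows, px$cols] <- cover[px$rows, px$cols] + 1L
      }
      if (any(cover != 1L))
        stop("regions do not partition the crop at frame ", f,
             " (coverage ", min(cover), "..", max(cover), ")")
    }
  }
  obj
}

#' Region rectangle at a frame, by linear keyframe interpolation
#'
#' Every rectangle coordinate (top, left, height, width) is interpolated
#' linearly between the flanking keyframes; before the first and after the
#' last keyframe the rectangle is held constant, and at a keyframe it is
#' returned exactly. This is the standard way to track steady cell growth
#' with a handful of hand-drawn key rectangles.
#'
#' @param region A region (list with `keyframes`), e.g. an element of a
#'   [keyframed_regions()] set.
#' @param frame 0-based frame index.
#' @return Numeric `c(top, left, height, width)` (possibly fractional).
#' @export
region_at <- function(region, frame) {
  kf <- region$keyframes
  interp1 <- function(col) {
    stats::approx(kf$frame, kf[[col]], xout = frame, method = "linear",
                  rule = 2L)$y
  }
  if (nrow(kf) == 1L) {
    return(c(top = kf$top, left = kf$left, height = kf$height,
             width = kf$width))
  }
  c(top = interp1("top"), left = interp1("left"),
    height = interp1("height"), width = interp1("width"))
}

# continuous rect -> integer pixel ranges; edges rounded so that adjacent
# regions sharing an edge stay disjoint and tiling
.rect_pixels <- function(rect, ny, nx) {
  r0 <- round(rect[[1L]]); r1 <- round(rect[[1L]] + rect[[3L]]) - 1L
  c0 <- round(rect[[2L]]); c1 <- round(rect[[2L]] + rect[[4L]]) - 1L
  if (r0 < 1L || c0 < 1L || r1 > ny || c1 > nx || r1 < r0 || c1 < c0)
    stop("rectangle outside crop bounds")
  list(rows = r0:r1, cols = c0:c1)
}

#' Background-correct a projected movie
#'
#' For each channel, one scalar -- the global minimum over all frames of
#' the pixels inside the outside-cell rectangle -- is subtracted from every
#' pixel of every frame. No clamping is applied.
#'
#' @param proj A `stack_projection`.
#' @param outside_rect Rectangle `c(top, left, height, width)` fully
#'   outside the cell.
#' @param regions Optional `keyframed_regions`; when given, the outside
#'   rectangle must not intersect any non-extracellular region at any
#'   keyframe, otherwise an error is thrown.
#' @return List with `projection` (corrected) and `offsets` (named per
#'   channel).
#' @export
background_correct <- function(proj, outside_rect, regions = NULL) {
  stopifnot(inherits(proj, "stack_projection"))
  d <- dim(proj$data)
  px <- .rect_pixels(outside_rect, d[3L], d[4L])
  if (!is.null(regions)) {
    for (r in regions$regions) {
      if (r$role == "ext") next
      for (f in r$keyframes$frame) {
        q <- .rect_pixels(region_at(r, f), regions$ny, regions$nx)
        if (length(intersect(px$rows, q$rows)) &&
            length(intersect(px$cols, q$cols)))
          stop("outside-cell rectangle overlaps region ", r$name)
      }
    }
  }
  offsets <- numeric(d[2L])
  out <- proj$data
  for (ch in seq_len(d[2L])) {
    offsets[ch] <- min(proj$data[, ch, px$rows, px$cols])
    out[, ch, , ] <- proj$data[, ch, , ] - offsets[ch]
  }
  names(offsets) <- proj$channels
  list(projection = stack_projection(out, proj$channels,
                                     proj$frame_interval_min),
       offsets = offsets)
}

#' Extract per-region intensity traces
#'
#' Sums the pixel intensities of every region at every frame and channel.
#' Because the regions partition the crop, the per-frame region sums add
#' up to the whole-crop sum exactly.
#'
#' @param proj A background- and drift-corrected `stack_projection`.
#' @param regions A `keyframed_regions` set matching the crop.
#' @param cell_id Identifier recorded in the trace table.
#' @return An object of class `trace_set`: data frame with columns
#'   `cell_id`, `region`, `role`, `channel`, `frame` (0-based),
#'   `time_min` (`NA` until synchronized) and `intensity`. Attributes:
#'   `channels`, `frame_interval_min`, `normalized`, `synchronized`,
#'   `norm_constant`.
#' @export
extract_traces <- function(proj, regions, cell_id = "cell") {
  stopifnot(inherits(proj, "stack_projection"),
            inherits(regions, "keyframed_regions"))
  d <- dim(proj$data)
  if (d[3L] != regions$ny || d[4L] != regions$nx)
    stop("projection and region set disagree on crop size")
  nT <- d[1L]; nC <- d[2L]; nR <- length(regions$regions)
  n <- nT * nC * nR
  region <- character(n); role <- character(n); channel <- character(n)
  frame <- integer(n); intensity <- numeric(n)
  i <- 0L
  for (tf in seq_len(nT)) {
    for (r in regions$regions) {
      px <- .rect_pixels(region_at(r, tf - 1L), regions$ny, regions$nx)
      for (ch in seq_len(nC)) {
        i <- i + 1L
        region[i] <- r$name; role[i] <- r$role
        channel[i] <- proj$channels[ch]; frame[i] <- tf - 1L
        intensity[i] <- sum(proj$data[tf, ch, px$rows, px$cols])
      }
    }
  }
  out <- data.frame(cell_id = cell_id, region = region, role = role,
                    channel = channel, frame = frame, time_min = NA_real_,
                    intensity = intensity, stringsAsFactors = FALSE)
  attr(out, "channels") <- proj$channels
  attr(out, "frame_interval_min") <- proj$frame_interval_min
  attr(out, "normalized") <- FALSE
  attr(out, "synchronized") <- FALSE
  attr(out, "norm_constant") <- NULL
  class(out) <- c("trace_set", "data.frame")
  out
}

# per-frame total of one channel, summed over all regions
.channel_total <- function(traces, channel) {
  sel <- traces$channel == channel
  stats::aggregate(intensity ~ frame, data = traces[sel, , drop = FALSE],
                   FUN = sum)
}

#' Normalize traces to the pre-cytokinesis reporter total
#'
#' The normalization constant is the mean, over all frames before the
#' annotated cytokinesis frame, of the whole-crop reporter sum; all
#' reporter traces are divided by it, so the mean pre-cytokinesis total
#' becomes exactly 1.0 (RFU). The tracer channel is scaled independently
#' to its own movie maximum (reporter normalization never mixes channels).
#'
#' @param traces A `trace_set`.
#' @param cytokinesis_frame 0-based frame index; frames `<` it define the
#'   reference window.
#' @param reporter_channel,tracer_channel Channel names.
#' @return The normalized `trace_set`.
#' @export
normalize_traces <- function(traces, cytokinesis_frame,
                             reporter_channel = "GFP",
                             tracer_channel = "PDMPO") {
  stopifnot(inherits(traces, "trace_set"))
  if (cytokinesis_frame < 1L) stop("cytokinesis_frame must be >= 1")
  tot <- .channel_total(traces, reporter_channel)
  pre <- tot$intensity[tot$frame < cytokinesis_frame]
  if (!length(pre)) stop("no frames before the cytokinesis frame")
  konst <- mean(pre)
  if (!is.finite(konst) || konst <= 0)
    stop("non-positive normalization constant")
  out <- traces
  sel <- out$channel == reporter_channel
  out$intensity[sel] <- out$intensity[sel] / konst
  if (tracer_channel %in% attr(traces, "channels")) {
    trtot <- .channel_total(traces, tracer_channel)
    trmax <- max(trtot$intensity)
    if (trmax > 0) {
      selt <- out$channel == tracer_channel
      out$intensity[selt] <- out$intensity[selt] / trmax
    }
  }
  attr(out, "normalized") <- TRUE
  attr(out, "norm_constant") <- konst
  out
}

#' Synchronize traces on the tracer peak
#'
#' The frame at which the mid-region tracer intensity is maximal (the
#' earliest such frame on ties) defines t = 0 min; all other frames get
#' `time_min = (frame - peak_frame) * frame_interval_min`. In the
#' experiment this is the moment of valve completion: the entrapped-dye
#' signal peaks just before the exocytosis quench.
#'
#' @param traces A `trace_set`.
#' @param tracer_channel Tracer channel name.
#' @param mid_role Role of the mid-cell region(s) (default `"mid"`).
#' @return The `trace_set` with `time_min` filled and attribute
#'   `peak_frame` set.
#' @export
synchronize_traces <- function(traces, tracer_channel = "PDMPO",
                               mid_role = "mid") {
  stopifnot(inherits(traces, "trace_set"))
  sel <- traces$role == mid_role & traces$channel == tracer_channel
  if (!any(sel)) stop("no mid-region tracer trace found")
  tr <- stats::aggregate(intensity ~ frame, data = traces[sel, , drop = FALSE],
                         FUN = sum)
  tr <- tr[order(tr$frame), ]
  if (max(tr$intensity) == min(tr$intensity))
    stop("no peak: mid-region tracer trace is flat")
  peak <- tr$frame[which.max(tr$intensity)]  # which.max takes the earliest
  dt <- attr(traces, "frame_interval_min")
  out <- traces
  out$time_min <- (out$frame - peak) * dt
  attr(out, "synchronized") <- TRUE
  attr(out, "peak_frame") <- peak
  out
}

#' Average synchronized traces across cells
#'
#' Traces are first aggregated per cell by region role (multiple
#' rectangles of one role, e.g. the flanking plasma-membrane strips, are
#' summed), then averaged across cells at each synchronized time point by
#' nearest-frame matching. The sample standard deviation (n-1 denominator)
#' is reported only where at least two cells contribute.
#'
#' @param trace_list List of synchronized (and normally normalized)
#'   `trace_set` objects.
#' @return An object of class `averaged_traces`: data frame `time_min`,
#'   `region` (the role), `channel`, `mean`, `sd` (`NA` where n < 2), `n`.
#' @export
average_cells <- function(trace_list) {
  if (!length(trace_list)) stop("need at least one cell")
  for (ts in trace_list) {
    stopifnot(inherits(ts, "trace_set"))
    if (!isTRUE(attr(ts, "synchronized")))
      stop("all trace sets must be synchronized first")
  }
  dt <- attr(trace_list[[1L]], "frame_interval_min")
  percell <- lapply(trace_list, function(ts) {
    agg <- stats::aggregate(intensity ~ time_min + role + channel,
                            data = ts, FUN = sum)
    # nearest-frame matching: times snapped to the common frame grid
    agg$key <- round(agg$time_min / dt)
    agg
  })
  all <- do.call(rbind, percell)
  grp <- interaction(all$key, all$role, all$channel, drop = TRUE)
  sp <- split(all, grp)
  rows <- lapply(sp, function(g) {
    n <- nrow(g)
    data.frame(time_min = g$key[1L] * dt, region = g$role[1L],
               channel = g$channel[1L], mean = mean(g$intensity),
               sd = if (n >= 2L) stats::sd(g$intensity) else NA_real_,
               n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$channel, out$region, out$time_min), ]
  rownames(out) <- NULL
  if (!any(out$n >= 1L)) stop("no overlapping timepoints")
  attr(out, "frame_interval_min") <- dt
  class(out) <- c("averaged_traces", "data.frame")
  out
}

#' Write traces to CSV
#'
#' Columns: cell_id, region, channel, frame, time_min, intensity.
#'
#' @param traces A `trace_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  utils::write.csv(
    traces[, c("cell_id", "region", "channel", "frame", "time_min",
               "intensity")],
    path, row.names = FALSE)
  invisible(path)
}

#' Write averaged traces to CSV
#'
#' Columns: time_min, region, channel, mean, sd, n.
#'
#' @param avg An `averaged_traces` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_averaged_traces <- function(avg, path) {
  stopifnot(inherits(avg, "averaged_traces"))
  utils::write.csv(as.data.frame(avg), path, row.names = FALSE)
  invisible(path)
}

#' Read averaged traces from CSV
#'
#' @param path CSV written by [write_averaged_traces()].
#' @param frame_interval_min Frame interval of the underlying movies.
#' @return An `averaged_traces` object.
#' @export
read_averaged_traces <- function(path, frame_interval_min = 3.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "region", "channel", "mean", "sd", "n")
  if (!all(need %in% names(df))) stop("missing columns in ", path)
  attr(df, "frame_interval_min") <- frame_interval_min
  class(df) <- c("averaged_traces", "data.frame")
  df
}

#' @export
plot.averaged_traces <- function(x, channel = "GFP", ...) {
  sel <- x$channel == channel
  d <- x[sel, , drop = FALSE]
  roles <- unique(d$region)
  cols <- stats::setNames(grDevices::hcl.colors(max(4L, length(roles)),
                                                "Dark 3")[seq_along(roles)],
                          roles)
  graphics::plot(range(d$time_min), range(d$mean, na.rm = TRUE),
                 type = "n", xlab = "time (min)",
                 ylab = sprintf("%s intensity (RFU)", channel), ...)
  for (r in roles) {
    g <- d[d$region == r, ]
    g <- g[order(g$time_min), ]
    ok <- !is.na(g$sd)
    if (any(ok))
      graphics::polygon(c(g$time_min[ok], rev(g$time_min[ok])),
                        c(g$mean[ok] - g$sd[ok], rev(g$mean[ok] + g$sd[ok])),
                        col = grDevices::adjustcolor(cols[r], 0.2),
                        border = NA)
    graphics::lines(g$time_min, g$mean, col = cols[r], lwd = 2)
  }
  graphics::legend("topleft", legend = roles, col = cols[roles], lwd = 2,
                   bty = "n")
  invisible(x)
}
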