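# Shared fixtures: fast simulator configs and small images.

# reduced movie (events unchanged, fewer trailing frames / z-planes) for
# unit tests; the acceptance suite runs the full default conditions
fast_cfg <- function(...) {
  args <- list(n_frames = 45L, n_zplanes = 5L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(kinetic_config, args)
}

# short movie with the tracer present from frame 0 (silica already
# depositing), for registration tests that need a stationary landmark
drift_cfg <- function(n_frames = 25L, drift = c(0.2, 0.1), ...) {
  kinetic_config(n_frames = n_frames, n_zplanes = 5L,
                 start_time_min = -60, drift_per_frame = drift, ...)
}

# smooth random test image: sum of a few Gaussian blobs
blob_image <- function(ny = 48L, nx = 48L, k = 5L) {
  img <- matrix(0, ny, nx)
  for (i in seq_len(k)) {
    cy <- stats::runif(1, 10, ny - 10); cx <- stats::runif(1, 10, nx - 10)
    s <- stats::runif(1, 1.5, 3)
    img <- img + stats::runif(1, 0.5, 2) *
      outer(exp(-(seq_len(ny) - cy)^2 / (2 * s^2)),
            exp(-(seq_len(nx) - cx)^2 / (2 * s^2)))
  }
  img
}

# shift an image by (dy, dx) with periodic boundary via Fourier phase
fourier_shift <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  ky <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1L):1)) / ny
  kx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1L):1)) / nx
  ph <- exp(-2i * pi * outer(ky * dy, rep(1, nx))) *
    exp(-2i * pi * outer(rep(1, ny), kx * dx))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (ny * nx)
}

# minimal synchronized trace_set built from per-role value vectors
manual_traces <- function(values, times, channel = "GFP", cell_id = "c1",
                          dt = 3.5) {
  rows <- do.call(rbind, lapply(names(values), function(role) {
    data.frame(cell_id = cell_id, region = role, role = role,
               channel = channel, frame = seq_along(times) - 1L,
               time_min = times, intensity = values[[role]],
               stringsAsFactors = FALSE)
  }))
  attr(rows, "channels") <- channel
  attr(rows, "frame_interval_min") <- dt
  attr(rows, "normalized") <- TRUE
  attr(rows, "synchronized") <- TRUE
  class(rows) <- c("trace_set", "data.frame")
  rows
}

manual_averaged <- function(values, times, channel = "GFP", dt = 3.5) {
  avg <- average_cells(list(manual_traces(values, times, channel, dt = dt)))
  avg
}

write_blast_tab <- function(path, rows) {
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  path
}

blast_row <- function(sseqid, evalue, qseqid = "q1") {
  c(qseqid, sseqid, "55.0", "400", "150", "5", "1", "420", "1", "410",
    format(evalue), "350")
}
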