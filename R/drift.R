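# Sub-pixel drift estimation by cross-correlation image registration.
#
# The integer-pixel shift is the argmax of the FFT cross-correlation of
# mean-subtracted images; the sub-pixel refinement evaluates the
# cross-correlation on an upsampled grid (spacing 1/upsample px) around
# the integer peak with an explicit matrix DFT, so no large upsampled FFT
# is ever formed.

#' Estimate the translation between two images
#'
#' Returns the shift `(dy, dx)` of `moving` relative to `reference`
#' (i.e. `moving(y, x) ~ reference(y - dy, x - dx)`), maximizing the
#' cross-correlation of the mean-subtracted images, refined to
#' `1/upsample` pixel.
#'
#' @param reference,moving 2-D numeric matrices of identical shape.
#' @param upsample Integer upsampling factor (1 = integer-pixel only).
#' @return Numeric `c(dy, dx)` in pixels.
#' @examples
#' img <- matrix(0, 32, 32); img[10:12, 14:16] <- 1
#' estimate_shift(img, img)
#' @export
estimate_shift <- function(reference, moving, upsample = 20L) {
  if (!is.matrix(reference) || !is.matrix(moving))
    stop("images must be matrices")
  if (!identical(dim(reference), dim(moving)))
    stop("image shapes differ")
  upsample <- as.integer(upsample)
  if (upsample < 1L) stop("'upsample' must be >= 1")
  if (all(reference == 0) || all(moving == 0)) {
    warning("all-zero image; returning zero shift")
    return(c(dy = 0, dx = 0))
  }
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  ny <- nrow(a); nx <- ncol(a)
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  X <- Fb * Conj(Fa)  # correlation spectrum: peak of IFFT at (dy, dx)
  cc <- Re(stats::fft(X, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  wrap <- function(i, n) {
    v <- i - 1L
    if (v > n / 2) v - n else v
  }
  dy0 <- wrap(pk[1L], ny); dx0 <- wrap(pk[2L], nx)
  if (upsample == 1L) return(c(dy = dy0, dx = dx0))
  # refine on a (2*upsample+1)^2 grid of spacing 1/upsample around the peak
  ky <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1L):1)) / ny
  kx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1L):1)) / nx
  dys <- dy0 + seq(-1, 1, length.out = 2L * upsample + 1L)
  dxs <- dx0 + seq(-1, 1, length.out = 2L * upsample + 1L)
  Ey <- exp(2i * pi * outer(dys, ky))        # (grid, ky)
  Ex <- exp(2i * pi * outer(kx, dxs))        # (kx, grid)
  cc_up <- Re(Ey %*% X %*% Ex)
  pk2 <- which(cc_up == max(cc_up), arr.ind = TRUE)[1L, ]
  dy <- dys[pk2[1L]]; dx <- dxs[pk2[2L]]
  # parabolic interpolation through the peak removes the 1/upsample
  # quantization (important when small per-frame shifts are accumulated)
  step <- 1 / upsample
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den < 0) 0.5 * (cm - cp) / den else 0
  }
  i <- pk2[1L]; j <- pk2[2L]
  if (i > 1L && i < nrow(cc_up))
    dy <- dy + step * para(cc_up[i - 1L, j], cc_up[i, j], cc_up[i + 1L, j])
  if (j > 1L && j < ncol(cc_up))
    dx <- dx + step * para(cc_up[i, j - 1L], cc_up[i, j], cc_up[i, j + 1L])
  c(dy = dy, dx = dx)
}

#' Shift an image by a (possibly fractional) translation
#'
#' Sinc (Fourier) interpolation on a zero-padded canvas:
#' `output(y, x) = input(y - dy, x - dx)` with constant-zero padding
#' outside the original support. Unlike bilinear resampling, the sinc
#' kernel is symmetric at every fractional offset, so repeated
#' estimate-and-correct rounds do not acquire an interpolation-skew bias,
#' and the total intensity is conserved.
#'
#' @param img 2-D numeric matrix.
#' @param dy,dx Shift in pixels.
#' @return Shifted matrix of the same shape.
#' @export
apply_shift <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  if (dy == 0 && dx == 0) return(img)
  m <- ceiling(max(abs(dy), abs(dx))) + 2L
  py <- ny + 2L * m; px <- nx + 2L * m
  pad <- matrix(0, py, px)
  pad[m + seq_len(ny), m + seq_len(nx)] <- img
  ky <- c(0:(py %/% 2), -((py - py %/% 2 - 1L):1)) / py
  kx <- c(0:(px %/% 2), -((px - px %/% 2 - 1L):1)) / px
  ph <- exp(-2i * pi * outer(ky * dy, rep(1, px))) *
    exp(-2i * pi * outer(rep(1, py), kx * dx))
  sh <- Re(stats::fft(stats::fft(pad) * ph, inverse = TRUE)) / (py * px)
  sh[m + seq_len(ny), m + seq_len(nx)]
}

#' Correct stage drift across a projected movie
#'
#' Estimates the shift of every frame of the named channel relative to
#' frame 0 and applies the negated shifts to all channels. The default
#' procedure (`reference = "previous"`) is built for live recordings whose
#' scene content evolves (the SDV band appears and disappears):
#' \enumerate{
#'   \item per-frame shifts are estimated between consecutive frames and
#'     accumulated -- adjacent frames are nearly identical and register
#'     reliably even while the content changes;
#'   \item the aligned frames that carry signal are summed into a
#'     noise-reduced reference, every signal frame is re-registered
#'     directly against it (which stops per-step errors from accumulating
#'     into a random walk), and the reference is rebuilt a few times;
#'   \item because stage drift is slow compared to the frame interval, the
#'     trajectory is regularized by robust local-linear smoothing
#'     (`stats::loess`, `family = "symmetric"`) and re-anchored so the
#'     frame-0 shift is exactly zero. Smoothing is skipped for movies
#'     shorter than 12 frames.
#' }
#' `reference = "first"` registers every frame directly against frame 0
#' with no refinement (appropriate for stationary scenes). Correcting an
#' already-corrected movie yields residual shifts below the registration
#' resolution.
#'
#' @param proj A `stack_projection`; run [background_correct()] first, so
#'   that shifting a frame does not drag a bright camera-offset edge
#'   across the field.
#' @param channel Registration channel name (default: the silica tracer
#'   `"PDMPO"` when present, else the first channel -- the entrapped-tracer
#'   signal is the most stationary landmark once present).
#' @param upsample Sub-pixel upsampling factor (default 20 = 0.05 px).
#' @param reference `"previous"` (sequential + iterative refinement;
#'   default) or `"first"` (direct to frame 0).
#' @param fallback_channel Optional second channel used for steps where
#'   the primary channel carries no signal yet (e.g. the reporter channel
#'   while the tracer is still dark early in a recording).
#' @param signal_floor A frame "has signal" in the primary channel when
#'   the spatial SD of its pixels exceeds this fraction of the movie-wide
#'   maximum spatial SD (structure-based: a dark or flat frame carries no
#'   registration landmark).
#' @param refine_iters Reference rebuild/re-registration iterations.
#' @param smooth_span `loess` span for the trajectory regularization;
#'   `NULL` disables smoothing.
#' @return List with `projection` (corrected) and `shifts` (an object of
#'   class `shift_trajectory`: data frame `frame`, `dy`, `dx`, relative to
#'   frame 0).
#' @export
correct_drift <- function(proj, channel = NULL, upsample = 20L,
                          reference = c("previous", "first"),
                          fallback_channel = NULL, signal_floor = 0.05,
                          refine_iters = 4L, smooth_span = 0.5) {
  stopifnot(inherits(proj, "stack_projection"))
  reference <- match.arg(reference)
  if (is.null(channel))
    channel <- if ("PDMPO" %in% proj$channels) "PDMPO" else proj$channels[1L]
  ci <- match(channel, proj$channels)
  if (is.na(ci)) stop("channel not found: ", channel)
  fi <- if (is.null(fallback_channel)) NA_integer_ else
    match(fallback_channel, proj$channels)
  if (!is.null(fallback_channel) && is.na(fi))
    stop("channel not found: ", fallback_channel)
  d <- dim(proj$data)
  nT <- d[1L]
  sv <- vapply(seq_len(nT),
               function(tf) stats::sd(proj$data[tf, ci, , ]), numeric(1L))
  has_signal <- if (max(sv) > 0) sv > signal_floor * max(sv)
    else rep(TRUE, nT)
  shifts <- matrix(0, nT, 2L)
  if (reference == "first") {
    for (tf in seq_len(nT)[-1L])
      shifts[tf, ] <- estimate_shift(proj$data[1L, ci, , ],
                                     proj$data[tf, ci, , ], upsample)
  } else {
    # pass 1: chained neighbor registration
    for (tf in seq_len(nT)[-1L]) {
      use <- if (has_signal[tf - 1L] && has_signal[tf]) ci
        else if (!is.na(fi)) fi else NA_integer_
      s <- if (is.na(use)) c(0, 0) else
        estimate_shift(proj$data[tf - 1L, use, , ],
                       proj$data[tf, use, , ], upsample)
      shifts[tf, ] <- shifts[tf - 1L, ] + s
    }
    sig <- which(has_signal)
    do_smooth <- !is.null(smooth_span) && nT >= 12L
    if (length(sig) >= 3L) {
      fr <- seq_len(nT)
      for (it in seq_len(refine_iters)) {
        # pass 2: absolute registration against the aligned sum reference
        ref <- 0
        for (tf in sig)
          ref <- ref + apply_shift(proj$data[tf, ci, , ],
                                   -shifts[tf, 1L], -shifts[tf, 2L])
        raw <- shifts
        dabs <- matrix(NA_real_, nT, 2L)
        for (tf in sig)
          dabs[tf, ] <- estimate_shift(ref, proj$data[tf, ci, , ], upsample)
        ts <- sig[1L]
        raw[sig, ] <- sweep(dabs[sig, , drop = FALSE], 2L,
                            dabs[ts, ] - shifts[ts, ])
        # pass 3: drift is slow -> robust local-linear regularization
        if (do_smooth) {
          for (ax in 1:2) {
            if (stats::sd(raw[, ax]) < 1e-6) next  # already flat
            lo <- stats::loess(raw[, ax] ~ fr, span = smooth_span,
                               degree = 1L, family = "symmetric")
            raw[, ax] <- stats::predict(lo, fr)
          }
        }
        shifts <- sweep(raw, 2L, raw[1L, ])
        if (!do_smooth) break  # without smoothing one refinement suffices
      }
    }
  }
  out <- proj$data
  for (tf in seq_len(nT)[-1L]) {
    s <- shifts[tf, ]
    if (all(s == 0)) next
    for (ch in seq_len(d[2L]))
      out[tf, ch, , ] <- apply_shift(proj$data[tf, ch, , ], -s[1L], -s[2L])
  }
  traj <- data.frame(frame = seq_len(nT) - 1L,
                     dy = shifts[, 1L], dx = shifts[, 2L])
  attr(traj, "channel") <- channel
  attr(traj, "upsample") <- upsample
  class(traj) <- c("shift_trajectory", "data.frame")
  list(projection = stack_projection(out, proj$channels,
                                     proj$frame_interval_min),
       shifts = traj)
}

#' @export
print.shift_trajectory <- function(x, ...) {
  cat(sprintf("Shift trajectory: %d frames, channel %s, 1/%d px resolution\n",
              nrow(x), attr(x, "channel"), attr(x, "upsample")))
  cat(sprintf("  max |dy| %.2f px, max |dx| %.2f px\n",
              max(abs(x$dy)), max(abs(x$dx))))
  invisible(x)
}
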