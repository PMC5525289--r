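# Independent oracles used to validate the implementation paths.

# Affine-gap global alignment by memoized recursion over (i, j, state),
# structurally independent of the package's iterative DP. Objective is
# lexicographic (score, identities, -columns), gap length L costs
# open + ext * L.
oracle_align <- function(a, b, submat, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(hash = TRUE)
  better <- function(u, v) {
    if (is.null(v)) return(u)
    if (u[1] != v[1]) return(if (u[1] > v[1]) u else v)
    if (u[2] != v[2]) return(if (u[2] > v[2]) u else v)
    if (u[3] < v[3]) u else v
  }
  # value = c(score, identities, columns) of the best completion from
  # (i consumed of a, j consumed of b, state); state: 0 start/match,
  # 1 in gap consuming a, 2 in gap consuming b
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i == n && j == m) {
      memo[[key]] <- c(0, 0, 0)
      return(memo[[key]])
    }
    best <- NULL
    if (i < n && j < m) {
      v <- rec(i + 1, j + 1, 0)
      best <- better(v + c(submat[av[i + 1], bv[j + 1]],
                           as.integer(av[i + 1] == bv[j + 1]), 1), best)
    }
    if (i < n) {
      v <- rec(i + 1, j, 1)
      cost <- if (state == 1) ext else open + ext
      best <- better(v + c(-cost, 0, 1), best)
    }
    if (j < m) {
      v <- rec(i, j + 1, 2)
      cost <- if (state == 2) ext else open + ext
      best <- better(v + c(-cost, 0, 1), best)
    }
    memo[[key]] <- best
    best
  }
  r <- rec(0, 0, 0)
  list(score = r[1], identities = r[2], columns = r[3],
       percent_identity = 100 * r[2] / r[3])
}

# dense-grid sub-pixel registration oracle: shift the moving image back by
# candidate offsets (Fourier phase shift) and maximize the plain overlap
# correlation with the reference
oracle_shift <- function(ref, mov, center, halfwidth = 0.1, step = 0.01) {
  a <- ref - mean(ref)
  cand <- expand.grid(dy = seq(center[1] - halfwidth, center[1] + halfwidth,
                               by = step),
                      dx = seq(center[2] - halfwidth, center[2] + halfwidth,
                               by = step))
  score <- vapply(seq_len(nrow(cand)), function(i) {
    b <- fourier_shift(mov, -cand$dy[i], -cand$dx[i])
    sum(a * (b - mean(b)))
  }, numeric(1))
  unlist(cand[which.max(score), ])
}

# per-segment linear interpolation of a keyframed rectangle
oracle_region_at <- function(keyframes, frame) {
  kf <- keyframes[order(keyframes$frame), ]
  interp <- function(col) {
    if (frame <= kf$frame[1]) return(kf[[col]][1])
    nk <- nrow(kf)
    if (frame >= kf$frame[nk]) return(kf[[col]][nk])
    i <- max(which(kf$frame <= frame))
    f0 <- kf$frame[i]; f1 <- kf$frame[i + 1]
    w <- (frame - f0) / (f1 - f0)
    (1 - w) * kf[[col]][i] + w * kf[[col]][i + 1]
  }
  c(top = interp("top"), left = interp("left"),
    height = interp("height"), width = interp("width"))
}

random_peptide <- function(n, letters = c("A","C","D","E","F","G","H","I",
                                          "K","L","M","N","P","Q","R","S",
                                          "T","V","W","Y")) {
  paste0(sample(letters, n, replace = TRUE), collapse = "")
}
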