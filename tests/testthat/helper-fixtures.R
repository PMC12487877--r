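# shared fixture builders; all coordinates 0-based (x = col, y = row)

gaussian_frame <- function(h, w, cx, cy, sigma, amp = 100, offset = 0,
                           sigma_y = sigma) {
  xs <- matrix(rep(0:(w - 1), each = h), h)
  ys <- matrix(rep(0:(h - 1), w), h)
  offset + amp * exp(-((xs - cx)^2 / (2 * sigma^2) +
                         (ys - cy)^2 / (2 * sigma_y^2)))
}

stack_of <- function(...) {
  frames <- list(...)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  out <- array(0, c(length(frames), h, w))
  for (i in seq_along(frames)) out[i, , ] <- frames[[i]]
  out
}

# brute-force full 2-D autocorrelation by direct lag summation (small frames)
autocorr_brute <- function(fr) {
  h <- nrow(fr); w <- ncol(fr)
  out <- matrix(0, 2 * h - 1, 2 * w - 1)
  for (dy in -(h - 1):(h - 1)) {
    for (dx in -(w - 1):(w - 1)) {
      s <- 0
      for (r in 1:h) {
        for (cc in 1:w) {
          r2 <- r + dy; c2 <- cc + dx
          if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
            s <- s + fr[r, cc] * fr[r2, c2]
          }
        }
      }
      out[dy + h, dx + w] <- s
    }
  }
  out
}
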