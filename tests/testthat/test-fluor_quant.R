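test_that("rolling background subtraction removes constants and keeps spikes", {
  const <- array(7, c(10, 5, 5))
  expect_equal(subtract_rolling_background(const, window = 4),
               array(0, c(10, 5, 5)))
  # baseline 10 with a one-frame spike of +100 at one pixel
  st <- array(10, c(9, 4, 4))
  st[5, 2, 3] <- 110
  out <- subtract_rolling_background(st, window = 9, stat = "median")
  expect_equal(out[5, 2, 3], 100)
  expect_equal(sum(out != 0), 1L)
  # window larger than the stack equals single-block subtraction
  set.seed(1)
  st2 <- array(runif(100 * 4 * 4, 0, 50), c(100, 4, 4))
  expect_equal(subtract_rolling_background(st2, window = 1500),
               subtract_rolling_background(st2, window = 100))
})

test_that("block background matches a brute-force per-block median oracle", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(5:20, 1); h <- 3; w <- 4; win <- sample(2:7, 1)
    st <- array(sample(0:40, n * h * w, replace = TRUE), c(n, h, w))
    got <- subtract_rolling_background(st, window = win, stat = "median")
    exp_out <- st
    starts <- seq(1, n, by = win)
    for (s in starts) {
      idx <- s:min(s + win - 1, n)
      for (r in 1:h) for (cc in 1:w) {
        bg <- median(st[idx, r, cc])
        exp_out[idx, r, cc] <- pmax(st[idx, r, cc] - bg, 0)
      }
    }
    expect_equal(got, exp_out)
  }
})

test_that("median background subtraction is idempotent within one block", {
  set.seed(5)
  st <- array(sample(0:30, 7 * 3 * 3, replace = TRUE), c(7, 3, 3))
  once <- subtract_rolling_background(st, window = 7, stat = "median")
  twice <- subtract_rolling_background(once, window = 7, stat = "median")
  expect_equal(twice, once)
})

test_that("frame-max traces honor masks and flag empty ones", {
  fr <- matrix(0, 6, 6); fr[3, 4] <- 42
  st <- stack_of(fr, matrix(0, 6, 6))
  tr <- frame_max_trace(st)
  expect_equal(tr$value, c(42, 0))
  expect_equal(tr$frame, c(0L, 1L))
  # mask excludes the bright pixel
  m <- matrix(TRUE, 6, 6); m[3, 4] <- FALSE
  expect_equal(frame_max_trace(st, mask = m)$value[1], 0)
  # masked and unmasked agree when the spot lies inside the mask
  m2 <- matrix(FALSE, 6, 6); m2[2:4, 3:5] <- TRUE
  expect_equal(frame_max_trace(st, mask = m2)$value[1], 42)
  expect_warning(tr3 <- frame_max_trace(st, mask = matrix(FALSE, 6, 6)), "empty mask")
  expect_true(all(is.na(tr3$value)))
})

test_that("frame max recovers generator spot amplitude after subtraction", {
  cfg <- sim_config(seed = 8, n_cycles = 40, read_noise_sd = 1,
                    motion_amplitude = 15)
  sim <- simulate_recording(cfg)
  dm <- demultiplex(sim$recording)
  fluor <- subtract_rolling_background(dm$fluorescence, window = 1500)
  tr <- frame_max_trace(fluor)
  expect_lt(abs(mean(tr$value) - cfg$amplitude) / cfg$amplitude, 0.15)
})

test_that("session summaries use mean and linear-interpolation 95th percentile", {
  s <- summarize_session(tibble::tibble(value = 0:100))
  expect_equal(s$p95_value, 95)
  expect_equal(s$mean_value, 50)
  s2 <- summarize_session(rep(3.5, 10))
  expect_equal(c(s2$mean_value, s2$p95_value), c(3.5, 3.5))
  set.seed(2)
  v <- runif(57, 0, 10)
  s3 <- summarize_session(v)
  # sort-based linear interpolation oracle: quantile at h = (n-1)p + 1
  sv <- sort(v); hpos <- (length(v) - 1) * 0.95 + 1
  oracle <- sv[floor(hpos)] + (hpos - floor(hpos)) * (sv[ceiling(hpos)] - sv[floor(hpos)])
  expect_equal(s3$p95_value, oracle)
  expect_error(summarize_session(numeric(0)), "empty")
})

test_that("mean-ratio SNR behaves like the published summary", {
  a <- tibble::tibble(mean_value = c(25.0, 25.2))
  b <- tibble::tibble(mean_value = c(10, 10))
  expect_equal(snr_mean_ratio(a, b), 2.51)
  expect_equal(snr_mean_ratio(b, b), 1.0)
  expect_error(snr_mean_ratio(a, tibble::tibble(mean_value = 0)), "positive")
  # simulation: configured amplitude ratio recovered within sampling error
  set.seed(3)
  qd <- rnorm(200, 50, 2); ctrl <- rnorm(200, 10, 1)
  expect_lt(abs(snr_mean_ratio(qd, ctrl) - 5), 0.2)
})

test_that("spatial-SD SNR has its closed forms and matches a brute oracle", {
  expect_equal(snr_spatial_sd(array(9, c(3, 4, 4))), 0)
  chk <- matrix(c(0, 2), 4, 4)  # half 0 / half 2
  expect_equal(snr_spatial_sd(stack_of(chk)), 1.0)
  set.seed(7)
  st <- array(runif(5 * 6 * 6, 0, 100), c(5, 6, 6))
  oracle <- mean(vapply(1:5, function(i) {
    v <- as.vector(st[i, , ]); sqrt(mean((v - mean(v))^2))
  }, numeric(1)))
  expect_equal(snr_spatial_sd(st), oracle)
})

test_that("longevity crosses at the first sub-threshold day and censors otherwise", {
  s <- tibble::tibble(day = c(0, 1, 2), value = c(5, 4, 3))
  ctrl <- rep(3.5, 100)  # 99th percentile = 3.5
  r <- longevity(s, ctrl)
  expect_equal(r$crossing_day, 2)
  expect_false(r$censored)
  r2 <- longevity(tibble::tibble(day = 0:2, value = c(9, 8, 7)), ctrl)
  expect_true(r2$censored)
  expect_true(is.na(r2$crossing_day))
  expect_equal(r2$last_day, 2)
  expect_error(longevity(s, numeric(0)), "control")
})

test_that("longevity is monotone in the control threshold and exact on decays", {
  # analytic exponential crossing: value = 100 * 2^(-day/2), threshold 12.5
  days <- 0:10
  s <- tibble::tibble(day = days, value = 100 * 2^(-days / 2))
  r <- longevity(s, rep(12.4, 100))
  expect_equal(r$crossing_day, 7)  # first day with value < 12.4 is day 7
  # raising the threshold never increases the crossing day
  prev <- Inf
  for (thr in c(5, 12.4, 30, 80)) {
    cd <- longevity(s, rep(thr, 100))$crossing_day
    cd <- ifelse(is.na(cd), Inf, cd)
    expect_lte(cd, prev)
    prev <- cd
  }
})

test_that("autocorrelation maps are unit at center, symmetric, delta-correct", {
  fr <- matrix(0, 7, 9); fr[4, 5] <- 3
  ac <- spatial_autocorrelation(stack_of(fr), stride = 1)
  expect_equal(dim(ac$map), c(13L, 17L))
  expect_equal(ac$map[7, 9], 1)
  expect_equal(sum(abs(ac$map)), 1)  # delta frame: zero everywhere else
  set.seed(12)
  fr2 <- matrix(runif(7 * 9), 7, 9)
  ac2 <- spatial_autocorrelation(stack_of(fr2), stride = 1)
  expect_equal(ac2$map, ac2$map[13:1, 17:1])  # 180-degree rotation symmetry
  expect_equal(max(abs(ac2$map)), ac2$map[7, 9])
})

test_that("FFT autocorrelation equals the brute-force lag sum", {
  set.seed(21)
  fr <- matrix(runif(6 * 5), 6, 5)
  ac <- spatial_autocorrelation(stack_of(fr), stride = 1)
  brute <- autocorr_brute(fr)
  expect_equal(ac$map, brute / brute[6, 5], tolerance = 1e-10)
})

test_that("all-zero frames are skipped with a warning", {
  fr <- matrix(0, 5, 5); fr2 <- fr; fr2[3, 3] <- 1
  expect_warning(ac <- spatial_autocorrelation(stack_of(fr, fr2), stride = 1),
                 "zero")
  expect_equal(ac$n_frames_used, 1L)
  expect_error(spatial_autocorrelation(stack_of(fr), stride = 1), "zero")
})

test_that("autocorrelation of a Gaussian spot has spread sigma * sqrt(2)", {
  for (sgm in c(1, 2, 4)) {
    fr <- gaussian_frame(65, 65, 32, 32, sgm, amp = 100)
    ac <- spatial_autocorrelation(stack_of(fr), stride = 1)
    sp <- estimate_spread(ac)
    expect_true(sp$converged)
    expect_lt(abs(sp$spread_x - sgm * sqrt(2)) / (sgm * sqrt(2)), 0.05)
    expect_lt(abs(sp$spread_y - sgm * sqrt(2)) / (sgm * sqrt(2)), 0.05)
  }
})

test_that("spread estimation recovers exact Gaussian maps and flags flat ones", {
  m <- gaussian_frame(41, 41, 20, 20, 3, amp = 1, sigma_y = 5)
  sp <- estimate_spread(m)
  expect_lt(abs(sp$spread_x - 3), 1e-3)
  expect_lt(abs(sp$spread_y - 5), 1e-3)
  flat <- estimate_spread(matrix(1, 21, 21))
  expect_true(flat$degenerate)
})
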