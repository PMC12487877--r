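test_that("validity thresholds interpolate between the published anchors", {
  thr <- validity_thresholds(c(0.7, 0.85, 1.0), qc_config())
  expect_equal(thr$min_fluor_peak, c(75, 50, 25))
  expect_equal(thr$max_center_distance, c(5, 10, 15))
  # scores below the anchor clamp to the anchor thresholds
  lo <- validity_thresholds(c(0.21, 0.5, 0.69), qc_config())
  expect_equal(lo$min_fluor_peak, rep(75, 3))
  expect_equal(lo$max_center_distance, rep(5, 3))
  # knee variant anchors at 0.5
  knee <- validity_thresholds(c(0.5, 0.75, 1.0), qc_config(knee = TRUE))
  expect_equal(knee$min_fluor_peak, c(75, 50, 25))
  expect_equal(knee$max_center_distance, c(5, 10, 15))
  expect_error(validity_thresholds(1.5), "0, 1")
})

test_that("drop budget scales 0 at 3 keypoints to 3 at 10, floored between", {
  expect_equal(drop_budget(c(0, 1, 3)), c(0L, 0L, 0L))
  expect_equal(drop_budget(c(10, 12)), c(3L, 3L))
  expect_equal(drop_budget(7), 1L)  # floor(3 * 4 / 7)
  expect_equal(drop_budget(4:9), as.integer(floor(3 * (4:9 - 3) / 7)))
})

test_that("jump filter uses a strict 30 px threshold on either neighbor", {
  mk <- function(step) tibble::tibble(
    frame = 0:2, camera = "c0", node = "n",
    x = c(0, step, step), y = 0, score = 1
  )
  expect_false(any(jump_filter(mk(30))$excluded_jump))
  flags <- jump_filter(mk(31))$excluded_jump
  expect_equal(flags, c(TRUE, TRUE, FALSE))  # both sides of the step flagged
  # a bounded random walk never flags
  set.seed(9)
  walk <- tibble::tibble(frame = 0:49, camera = "c0", node = "n",
                         x = cumsum(runif(50, -20, 20)),
                         y = cumsum(runif(50, -20, 20)), score = 1)
  expect_false(any(jump_filter(walk)$excluded_jump))
})

test_that("pairwise distance filter flags strictly beyond 300 px", {
  mk <- function(d) tibble::tibble(camera = "c0", frame = 0L, node = c("a", "b"),
                                   x = c(0, d), y = 0)
  expect_false(pairwise_distance_filter(mk(300))$excluded_pairwise)
  expect_true(pairwise_distance_filter(mk(301))$excluded_pairwise)
  # all-pairs brute-force oracle on random frames
  set.seed(14)
  for (rep in 1:5) {
    df <- tibble::tibble(camera = "c0", frame = 0L, node = letters[1:8],
                         x = runif(8, 0, 400), y = runif(8, 0, 400))
    got <- pairwise_distance_filter(df, 300)$excluded_pairwise
    expect_equal(got, max(dist(cbind(df$x, df$y))) > 300)
  }
})

test_that("PCA stage finds the low-rank pose dimension and flags orthogonal outliers", {
  # exactly rank-2 pose data in 20 dims
  set.seed(6)
  nodes <- paste0("n", 1:10)
  base <- matrix(runif(20, 0, 100), 1)
  m1 <- matrix(rnorm(20), 1); m2 <- matrix(rnorm(20), 1)
  poses <- base[rep(1, 60), ] + outer(sin(1:60), m1[1, ]) * 40 +
    outer(cos(2 * (1:60)), m2[1, ]) * 25
  tab <- tibble::tibble(
    frame = rep(0:59, each = 10), camera = "c0",
    node = rep(nodes, 60),
    x = as.vector(t(poses[, 1:10])), y = as.vector(t(poses[, 11:20]))
  )
  res <- pca_outlier_filter(tab, qc_config())
  expect_equal(unname(attr(res, "n_components")), 2L)
  expect_false(any(res$excluded_pca))
  # identical frames: zero error, zero flags
  tab2 <- tab; tab2$x <- rep(1:10, 60); tab2$y <- rep(1:10, 60)
  res2 <- pca_outlier_filter(tab2, qc_config())
  expect_false(any(res2$excluded_pca))
  expect_true(all(res2$recon_error < 1e-12))
  # one frame with a large residual orthogonal to the rank-2 structure
  tab3 <- tab
  i <- which(tab3$frame == 30 & tab3$node == "n4")
  tab3$y[i] <- tab3$y[i] + 50
  res3 <- pca_outlier_filter(tab3, qc_config())
  expect_equal(res3$frame[res3$excluded_pca], 30)
  # insufficient complete frames: skipped with a warning
  expect_warning(
    res4 <- pca_outlier_filter(tab[tab$frame == 0, ], qc_config()),
    "fewer than 2"
  )
  expect_equal(nrow(res4), 0L)
})

test_that("validity filter combines fluorescence and distance evidence", {
  tab <- tibble::tibble(
    score = c(1.0, 0.7, 0.7, 1.0),
    peak_value = c(30, 30, 80, 30),
    center_dist = c(10, 2, 6, NA)
  )
  v <- validity_filter(tab, qc_config())
  expect_equal(v$valid, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(v$invalid_fluor[2])   # peak 30 < 75 at score 0.7
  expect_true(v$invalid_distance[3])  # distance 6 > 5 at score 0.7
  expect_true(v$invalid_distance[4])  # missing evidence
})

test_that("the cascade passes a clean dataset untouched", {
  bm <- simulate_qc_benchmark(seed = 23, inject = FALSE)
  expect_equal(nrow(bm$record_labels), 0L)
  expect_equal(nrow(bm$frame_labels), 0L)
  rep <- run_cascade(bm$keypoints)
  expect_equal(nrow(rep$surviving), nrow(bm$keypoints))
  expect_true(all(rep$counts$n == 0))
})

test_that("the cascade flags every injected violation with its reason and nothing else", {
  bm <- simulate_qc_benchmark(seed = 29)
  rep <- run_cascade(bm$keypoints)
  r <- rep$records; f <- rep$frames
  lab <- bm$record_labels; fl <- bm$frame_labels
  key <- function(df) sort(paste(df$frame, df$node))
  expect_equal(key(r[r$excluded_jump, ]), key(lab[lab$reason == "jump", ]))
  expect_equal(key(r[r$invisible & !r$excluded_jump & !r$excluded_pca, ]),
               key(lab[lab$reason == "invisible", ]))
  expect_equal(key(r[r$invalid_fluor, ]), key(lab[lab$reason == "invalid_fluor", ]))
  expect_equal(key(r[r$invalid_distance, ]),
               key(lab[lab$reason == "invalid_distance", ]))
  expect_equal(sort(f$frame[f$excluded_pca_frame]),
               sort(fl$frame[fl$reason == "pca"]))
  expect_equal(sort(f$frame[f$excluded_drop_budget]),
               sort(fl$frame[fl$reason == "drop_budget"]))
  expect_equal(sort(f$frame[f$excluded_pairwise]),
               sort(fl$frame[fl$reason == "pairwise"]))
  # surviving records carry no exclusion flags
  s <- rep$surviving
  expect_true(all(s$valid))
  expect_false(any(s$excluded_jump | s$excluded_pca | s$invisible |
                     s$invalid_fluor | s$invalid_distance | s$frame_excluded))
})

test_that("the knee configuration skips PCA and anchors scaling at 0.5", {
  cfg <- qc_config(knee = TRUE)
  expect_false(cfg$pca_enabled)
  expect_equal(cfg$low_anchor_score, 0.5)
  tab <- tibble::tibble(
    frame = rep(0:9, each = 2), camera = "c0",
    node = rep(c("knee_l", "knee_r"), 10),
    x = rep(c(100, 140), 10), y = 50, score = 0.9,
    peak_value = 150, center_dist = 1
  )
  rep <- run_cascade(tab, cfg)
  expect_false(rep$stages$applied[rep$stages$stage == "pca"])
  expect_equal(nrow(rep$surviving), 20L)
})

test_that("loosening any threshold never shrinks the surviving set", {
  bm <- simulate_qc_benchmark(seed = 41)
  base <- nrow(run_cascade(bm$keypoints)$surviving)
  looser <- list(
    qc_config(visibility_score = 0.01),
    qc_config(fluor_peak_at_low_anchor = 5, fluor_peak_at_score1 = 5),
    qc_config(max_dist_at_low_anchor = 50, max_dist_at_score1 = 50),
    qc_config(budget_max_drops = 10L),
    qc_config(max_pair_distance = 1e5),
    qc_config(pca_outlier_mads = 100)
  )
  for (cfg in looser) {
    expect_gte(nrow(run_cascade(bm$keypoints, cfg)$surviving), base)
  }
  # max_jump interacts with the PCA stage (an unflagged teleport completes a
  # frame, which PCA then excludes wholesale), so its monotonicity holds per
  # stage and at cascade level with PCA off
  expect_lte(sum(jump_filter(bm$keypoints, 100)$excluded_jump),
             sum(jump_filter(bm$keypoints, 30)$excluded_jump))
  b0 <- nrow(run_cascade(bm$keypoints, qc_config(pca_enabled = FALSE))$surviving)
  b1 <- nrow(run_cascade(bm$keypoints, qc_config(pca_enabled = FALSE,
                                                 max_jump = 100))$surviving)
  expect_gte(b1, b0)
})

test_that("cascade output is deterministic and camera-permutation invariant", {
  bm <- simulate_qc_benchmark(seed = 47)
  kp <- bm$keypoints
  set.seed(3)
  kp2 <- kp[sample.int(nrow(kp)), ]  # shuffled record order
  r1 <- run_cascade(kp)
  r2 <- run_cascade(kp2)
  key <- function(s) sort(paste(s$frame, s$camera, s$node))
  expect_identical(key(r1$surviving), key(r2$surviving))
  expect_identical(r1$counts, r2$counts)
})
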