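# Savitzky-Golay and Douglas-Peucker back ends, the interval state machine,
# and the interactive/automatic schemes.

test_that("Savitzky-Golay reproduces polynomials and pins endpoints", {
  t <- seq(0, 1, length.out = 41)
  cubic <- cbind(1 + 2 * t - t^2 + 0.5 * t^3, -t + t^3, 2 * t^2)
  out <- smooth_segment(cubic, window = 9, order = 3)
  expect_equal(out, cubic, tolerance = 1e-9)

  set.seed(99)
  noisy <- matrix(rnorm(90), ncol = 3)
  sm <- smooth_segment(noisy, window = 9, order = 2)
  expect_identical(sm[1, ], noisy[1, ])
  expect_identical(sm[30, ], noisy[30, ])
})

test_that("smoothing a white-noise signal reduces its variance", {
  set.seed(7)
  sig <- cbind(rnorm(101), 0, 0)
  out <- smooth_segment(sig, window = 11, order = 2)
  expect_lt(var(out[, 1]), var(sig[, 1]))
})

test_that("short segments shrink the window or pass through unchanged", {
  m5 <- matrix(rnorm(15), ncol = 3)
  out5 <- smooth_segment(m5, window = 9, order = 2)  # window shrinks to 5
  expect_equal(dim(out5), dim(m5))
  m2 <- matrix(rnorm(6), ncol = 3)
  expect_identical(smooth_segment(m2, window = 9, order = 2), m2)
  expect_error(smooth_segment(m5, window = 4, order = 2), "odd")
  expect_error(smooth_segment(m5, window = 3, order = 3), "exceed")
})

test_that("Douglas-Peucker keeps endpoints, subsets, and respects tolerance", {
  line <- cbind(0:9, 0, 0)
  dp <- decimate_segment(line, 0.1)
  expect_identical(dp$kept, c(1L, 10L))

  set.seed(4)
  m <- apply(matrix(rnorm(150), ncol = 3), 2, cumsum)
  all_kept <- decimate_segment(m, 0)
  expect_identical(all_kept$kept, 1:50)

  # audit: every dropped vertex within tolerance of the output polyline
  for (seed in c(3, 8)) {
    traj <- synthetic_trajectory("random_walk", n_steps = 50, seed = seed)
    mm <- traj_mat(traj)
    dp <- decimate_segment(mm, 1.0)
    expect_true(all(dp$kept %in% 1:50))
    expect_true(!is.unsorted(dp$kept))
    dropped <- setdiff(1:50, dp$kept)
    for (i in dropped) {
      k <- dp$kept
      d <- min(vapply(seq_len(length(k) - 1), function(j)
        ligandpath:::point_segment_distance(mm[i, , drop = FALSE],
                                            mm[k[j], ], mm[k[j + 1], ]),
        numeric(1)))
      expect_lte(d, 1.0 + 1e-12)
    }
  }
})

test_that("simplification states stay contiguous and merge equal levels", {
  s <- ligandpath:::state_new(100)
  s <- ligandpath:::state_apply(s, 20, 40, 2)
  expect_equal(s$start, c(0L, 20L, 40L))
  expect_equal(s$level, c(0L, 2L, 0L))
  s <- ligandpath:::state_apply(s, 40, 60, 2)       # merges with [20,40)
  expect_equal(nrow(s), 3L)
  expect_equal(s$end[2], 60L)
  s <- ligandpath:::state_apply(s, 0, 100, 0)
  expect_equal(nrow(s), 1L)
  expect_equal(s$level, 0L)
})

test_that("interactive level 0 on a raw trajectory is the identity", {
  traj <- synthetic_trajectory("random_walk", 120, seed = 2)
  r <- simplify_interactive(traj, 0, 120, 0)
  expect_equal(traj_mat(r$trajectory), traj_mat(traj))
  expect_equal(nrow(r$state), 1L)
  expect_equal(r$state$level, 0L)
})

test_that("lowering a level forces recomputation that matches from scratch", {
  traj <- synthetic_trajectory("random_walk", 200, seed = 6)
  cache <- new_simplify_cache()
  simplify_interactive(traj, 0, 200, 2, cache)
  r <- simplify_interactive(traj, 0, 200, 1, cache)
  expect_false(r$incremental)
  scratch <- apply_simplification(traj, r$state, "smooth")
  expect_identical(traj_mat(r$trajectory), traj_mat(scratch))
})

test_that("half-range edits equal the whole-range edit away from the joint", {
  n <- 200
  traj <- synthetic_trajectory("random_walk", n, seed = 13)
  cache <- new_simplify_cache()
  simplify_interactive(traj, 0, n / 2, 1, cache)
  halves <- simplify_interactive(traj, n / 2, n, 1, cache)
  whole <- simplify_interactive(traj, 0, n, 1)
  mh <- traj_mat(halves$trajectory)
  mw <- traj_mat(whole$trajectory)
  # the merged state materialises as one full-range pass: any discrepancy
  # must be confined to a smoothing window around the joint
  away <- c(1:(n / 2 - 5), (n / 2 + 6):n)
  expect_equal(mh[away, ], mw[away, ], tolerance = 1e-12)
})

test_that("incremental updates are bitwise-equal to from-scratch results", {
  n <- 400
  traj <- synthetic_trajectory("random_walk", n, seed = 21)
  cache <- new_simplify_cache()
  set.seed(77)
  n_incremental <- 0
  for (i in 1:60) {
    a <- sample(0:(n - 10), 1)
    b <- a + sample(5:(n - a), 1)
    lv <- sample(0:4, 1)
    r <- simplify_interactive(traj, a, b, lv, cache)
    if (r$incremental) {
      n_incremental <- n_incremental + 1
      scratch <- apply_simplification(traj, r$state, "smooth")
      expect_identical(traj_mat(r$trajectory), traj_mat(scratch))
    }
    # occasionally re-edit the same interval to exercise the incremental path
    if (i %% 3 == 0) {
      r2 <- simplify_interactive(traj, a, b, lv + 1, cache)
      if (r2$incremental) {
        n_incremental <- n_incremental + 1
        scratch2 <- apply_simplification(traj, r2$state, "smooth")
        expect_identical(traj_mat(r2$trajectory), traj_mat(scratch2))
      }
    }
  }
  expect_gt(n_incremental, 5)
})

test_that("the vertex-preserving back end always yields vertex subsets", {
  traj <- synthetic_trajectory("random_walk", 150, seed = 31)
  cache <- new_simplify_cache()
  m <- traj_mat(traj)
  for (edit in list(c(0, 150, 1), c(30, 90, 2), c(30, 90, 3), c(0, 150, 2))) {
    r <- simplify_interactive(traj, edit[1], edit[2], edit[3], cache,
                              backend = "dp")
    idx <- match(r$trajectory$step, traj$step)
    expect_false(anyNA(idx))
    expect_identical(traj_mat(r$trajectory), m[idx, , drop = FALSE])
  }
})

test_that("interval bounds and cache misuse are rejected", {
  traj <- synthetic_trajectory("random_walk", 50, seed = 1)
  expect_error(simplify_interactive(traj, -1, 10, 1), "out of bounds")
  expect_error(simplify_interactive(traj, 10, 10, 1), "out of bounds")
  expect_error(simplify_interactive(traj, 0, 51, 1), "out of bounds")
  expect_error(simplify_interactive(traj, 0, 50, -1), "non-negative")
})

test_that("automatic simplification terminates immediately on straight motion", {
  r <- simplify_auto(line_traj(100))
  expect_true(r$converged)
  expect_equal(max(r$trace$iteration), 0L)
  expect_equal(max(r$state$level), 0L)
  expect_identical(traj_mat(r$trajectory), traj_mat(line_traj(100)))
})

test_that("automatic simplification improves a pure-noise trajectory", {
  noise <- synthetic_trajectory("noise", n_steps = 200, seed = 42, sigma = 0.5)
  r <- simplify_auto(noise)
  expect_true(r$converged)
  expect_lt(r$final_complexity, r$initial_complexity)
  # smoothing never changes the point count
  expect_equal(nrow(r$trajectory), 200L)
})

test_that("automatic simplification concentrates levels on the noisy third", {
  hk <- synthetic_trajectory("helix_knot", n_steps = 300, seed = 7)
  r <- simplify_auto(hk)
  nr <- attr(hk, "noisy_range")
  lv <- ligandpath:::state_levels(r$state)
  noisy <- (nr[1] + 1):nr[2]
  clean <- setdiff(seq_len(300), noisy)
  expect_gt(mean(lv[noisy]), mean(lv[clean]))
  # interior of the clean thirds (outside the neighbourhood spill-over of the
  # noisy boundary) is never simplified at all
  interior <- setdiff(clean, c((nr[1] - 8):(nr[1] + 1), (nr[2] - 1):(nr[2] + 8)))
  expect_equal(max(lv[interior]), 0L)
})

test_that("the automatic trace shrinks the complex set and obeys the stop rule", {
  for (fixture in list(synthetic_trajectory("noise", 200, 42, 0.5),
                       synthetic_trajectory("helix_knot", 300, 7))) {
    r <- simplify_auto(fixture)
    tr <- r$trace
    expect_true(all(diff(tr$n_complex_steps) <= 0))
    expect_false(r$hit_cap)
    # total complexity is non-increasing across iterations except possibly
    # at the last one: any rise makes the improvement negative, which is
    # below eps and terminates the loop immediately
    rises <- which(diff(tr$total_complexity) > 1e-9)
    expect_true(all(rises >= nrow(tr) - 1))
    if (r$converged && max(tr$iteration) > 0 &&
        tr$n_complex_steps[nrow(tr)] > 0) {
      expect_lt(tr$delta[nrow(tr)], r$params$eps)
    }
  }
})

test_that("dp-backend automatic simplification keeps a vertex subset", {
  noise <- synthetic_trajectory("noise", 200, 42, 0.5)
  r <- simplify_auto(noise, backend = "dp")
  m <- traj_mat(noise)
  idx <- match(r$trajectory$step, noise$step)
  expect_false(anyNA(idx))
  expect_identical(traj_mat(r$trajectory), m[idx, , drop = FALSE])
  expect_lt(r$final_complexity, r$initial_complexity)
})
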