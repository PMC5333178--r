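# Complexity measures, checked against brute-force re-implementations that
# enumerate every segment tuple in the neighbourhood directly.

# independent oracle: angular complexity by full enumeration
brute_complexity <- function(m, nu) {
  n <- nrow(m)
  seg <- m[-1, , drop = FALSE] - m[-n, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  arc <- c(0, cumsum(len))
  vapply(seq_len(n), function(i) {
    total <- 0
    for (j in seq_len(n - 2)) {       # tuple of segments j and j+1
      pts <- c(j, j + 1, j + 2)       # their three vertices
      if (all(abs(arc[pts] - arc[i]) < nu)) {
        u <- seg[j, ]; v <- seg[j + 1, ]
        du <- len[j]; dv <- len[j + 1]
        a <- if (du * dv < 1e-12) 0 else
          acos(min(1, max(-1, sum(u * v) / (du * dv))))
        total <- total + (du + dv)^2 * a
      }
    }
    total
  }, numeric(1))
}

# independent oracle: path/chord ratio by direct neighbourhood extraction
brute_complexity_dp <- function(m, nu) {
  n <- nrow(m)
  seg_len <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-n, , drop = FALSE])^2))
  arc <- c(0, cumsum(seg_len))
  vapply(seq_len(n), function(i) {
    inside <- which(abs(arc - arc[i]) < nu)
    lo <- min(inside); hi <- max(inside)
    if (hi == lo) return(1)
    path <- arc[hi] - arc[lo]
    chord <- sqrt(sum((m[hi, ] - m[lo, ])^2))
    if (chord < 1e-9) 1e6 else path / chord
  }, numeric(1))
}

test_that("angular complexity matches analytic values on collinear and elbow cases", {
  expect_equal(complexity(line_traj(25), nu = 3)$complexity, rep(0, 25))
  expect_equal(complexity(line_traj(5, spacing = 0.2), nu = 100)$complexity,
               rep(0, 5))

  prof <- complexity(elbow_traj(), nu = 10)
  expect_equal(prof$complexity[2], 2 * pi, tolerance = 1e-12)

  # neighbourhood too small to hold a tuple
  expect_equal(complexity(elbow_traj(), nu = 0.1)$complexity, rep(0, 3))
})

test_that("path/chord complexity matches analytic values", {
  p <- complexity_dp(line_traj(12), nu = 2.5)
  expect_equal(p$complexity, rep(1, 12))
  expect_false(any(p$degenerate))

  expect_equal(complexity_dp(elbow_traj(), nu = 10)$complexity[2], sqrt(2),
               tolerance = 1e-12)
})

test_that("a closed sub-loop yields the degenerate-chord sentinel", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  # a polyline that returns exactly to its start: with a neighbourhood wide
  # enough to span it, P_s == P_e for every vertex
  closed <- ligand_trajectory(rbind(cbind(cos(th), sin(th), 0), c(1, 0, 0)))
  prof2 <- complexity_dp(closed, nu = 100)
  expect_true(any(prof2$degenerate))
  expect_equal(prof2$complexity[prof2$degenerate][1], 1e6)
})

test_that("both measures agree with brute-force enumeration on random walks", {
  for (seed in c(3, 17, 91)) {
    traj <- synthetic_trajectory("random_walk", n_steps = 60, seed = seed)
    m <- traj_mat(traj)
    for (nu in c(0.8, 2, 5)) {
      expect_equal(complexity(traj, nu)$complexity, brute_complexity(m, nu),
                   tolerance = 1e-12)
      expect_equal(complexity_dp(traj, nu)$complexity,
                   brute_complexity_dp(m, nu), tolerance = 1e-12)
    }
  }
})

test_that("complexity is invariant under rigid motion and c_DP >= 1", {
  traj <- synthetic_trajectory("random_walk", n_steps = 80, seed = 5)
  m <- traj_mat(traj)
  R <- fixed_rotation()
  moved <- ligand_trajectory(m %*% t(R) + matrix(c(3, -7, 11), 80, 3, byrow = TRUE))
  expect_equal(complexity(moved, 2)$complexity, complexity(traj, 2)$complexity,
               tolerance = 1e-9)
  pdp <- complexity_dp(traj, 2)
  expect_true(all(pdp$complexity[!pdp$degenerate] >= 1 - 1e-12))
})

test_that("complexity rejects degenerate input", {
  expect_error(complexity(ligand_trajectory(rbind(c(0, 0, 0), c(1, 0, 0))), 2),
               "at least 3")
  expect_error(complexity(elbow_traj(), nu = 0), "positive")
})
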