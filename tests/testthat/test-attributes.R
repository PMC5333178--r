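# Attribute derivations, each validated against a direct re-computation.

# independent stuckness oracle: explicit double loop over the window
brute_stuckness <- function(m, x, n) {
  N <- nrow(m)
  idx <- max(0, x - n):min(N - 1, x + n) + 1
  w <- m[idx, , drop = FALSE]
  best <- 0
  for (i in seq_len(nrow(w)))
    for (j in seq_len(nrow(w)))
      best <- max(best, sqrt(sum((w[i, ] - w[j, ])^2)))
  path <- 0
  for (i in seq_len(nrow(w) - 1))
    path <- path + sqrt(sum((w[i + 1, ] - w[i, ])^2))
  if (path < 1e-9) NA_real_ else best / path
}

test_that("stuckness is 1 for straight motion and 0.125 for 0/1 alternation", {
  line <- line_traj(30)
  expect_equal(stuckness(line, 15, 4), 1, tolerance = 1e-12)
  expect_equal(stuckness(line, 0, 4), 1, tolerance = 1e-12)  # shrunk window

  alt <- ligand_trajectory(cbind(rep(c(0, 1), 10), 0, 0))
  expect_equal(stuckness(alt, 9, 4), 0.125, tolerance = 1e-12)

  frozen <- ligand_trajectory(matrix(1, 5, 3))
  s <- stuckness_series(frozen, n = 2)
  expect_true(all(s$frozen))
  expect_true(all(is.na(s$straightness)))
  expect_equal(s$stuckness, rep(1, 5))
})

test_that("stuckness agrees with the brute-force oracle on random windows", {
  set.seed(123)
  traj <- synthetic_trajectory("random_walk", 300, seed = 55)
  m <- traj_mat(traj)
  xs <- sample(0:299, 1000, replace = TRUE)
  ns <- sample(1:8, 1000, replace = TRUE)
  for (i in seq_along(xs)) {
    expect_equal(stuckness(traj, xs[i], ns[i]), brute_stuckness(m, xs[i], ns[i]),
                 tolerance = 1e-12)
  }
})

test_that("stuckness is invariant under rigid motion and uniform scaling", {
  traj <- synthetic_trajectory("random_walk", 60, seed = 9)
  m <- traj_mat(traj)
  R <- fixed_rotation()
  moved <- ligand_trajectory(3.7 * (m %*% t(R)) +
                               matrix(c(5, -2, 9), 60, 3, byrow = TRUE))
  s0 <- stuckness_series(traj)$straightness
  s1 <- stuckness_series(moved)$straightness
  expect_equal(s1, s0, tolerance = 1e-9)
  expect_true(all(s0 <= 1 + 1e-12 & s0 > 0, na.rm = TRUE))
})

test_that("active-site position is the mass-weighted centre of the residues", {
  sc <- small_scenario()
  # direct re-summation oracle
  keys <- paste0(sc$frames$atoms$chain, ":", sc$frames$atoms$resid)
  want <- paste0(sc$active_site$chain, ":", sc$active_site$resid)
  idx <- which(keys %in% want)
  m <- frame_coords(sc$frames, 0)[idx, , drop = FALSE]
  masses <- c(C = 12.011, N = 14.007, O = 15.999)[sc$frames$atoms$element[idx]]
  oracle <- colSums(m * masses) / sum(masses)
  expect_equal(active_site_position(sc$frames, sc$active_site, 0), oracle,
               tolerance = 1e-12)

  # symmetric two-atom case: equal masses average to the midpoint
  atoms <- tibble::tibble(name = c("C1", "C2"), element = "C",
                          resname = "ALA", resid = 1L, chain = "A")
  fs <- frame_set(atoms, rbind(c(0, 0, 0), c(2, 0, 0)), n_frames = 1)
  spec <- active_site_spec(tibble::tibble(chain = "A", resid = 1))
  expect_equal(active_site_position(fs, spec, 0), c(1, 0, 0))

  bad <- active_site_spec(tibble::tibble(chain = "Z", resid = 999))
  expect_error(active_site_position(fs, bad, 0), "Z:999")
})

test_that("distance, direction and speed follow their defining rules", {
  atoms <- tibble::tibble(name = "C1", element = "C", resname = "ALA",
                          resid = 1L, chain = "A")
  fs <- frame_set(atoms, matrix(0, 1, 3), n_frames = 4, dt = 2)
  spec <- active_site_spec(tibble::tibble(chain = "A", resid = 1))
  traj <- ligand_trajectory(rbind(c(0, 0, 0), c(3, 4, 0), c(6, 8, 0), c(6, 8, 0)))
  d <- distance_series(traj, fs, spec)
  expect_equal(d$dist_active_site, c(0, 5, 10, 10))

  expect_equal(direction_series(c(5, 4, 3, 2)), rep("toward", 4))
  expect_equal(direction_series(c(1, 2, 3)), rep("away", 3))
  # plateau between a decrease and an increase inherits "toward"
  expect_equal(direction_series(c(3, 2, 2, 2, 4)),
               c("toward", "toward", "toward", "away", "away"))
  # leading tie defaults to "away"
  expect_equal(direction_series(c(2, 2, 1)), c("away", "toward", "toward"))

  sp <- speed_series(traj, dt = 2)
  expect_equal(sp$speed, c(2.5, 2.5, 0, 0))
  still <- speed_series(ligand_trajectory(matrix(1, 5, 3)), dt = 2)
  expect_equal(still$speed, rep(0, 5))
})

test_that("total path length equals the integral of the speed", {
  sc <- small_scenario()
  sp <- speed_series(sc$ligand, dt = sc$frames$dt)
  m <- traj_mat(sc$ligand)
  path <- sum(sqrt(rowSums((m[-1, ] - m[-nrow(m), ])^2)))
  expect_equal(sum(sp$speed[-nrow(sp)]) * sc$frames$dt, path, tolerance = 1e-9)
})

test_that("free space follows the containing-sphere and fallback rules", {
  traj <- ligand_trajectory(rbind(c(0, 0, 0), c(0, 0, 0)))
  tun <- tunnel_profile(tibble::tibble(
    frame = c(0, 0, 1),
    x = c(0.3, 0.9, 5), y = 0, z = 0,
    r = c(1.5, 3, 1)))
  # two containing spheres: nearest centre wins
  fs0 <- free_space_from_tunnel(tun, traj, 0)
  expect_equal(fs0$free_space, 1.5)
  expect_false(fs0$outside_tunnel)
  # no containing sphere: nearest sphere radius, flagged
  fs1 <- free_space_from_tunnel(tun, traj, 1)
  expect_equal(fs1$free_space, 1)
  expect_true(fs1$outside_tunnel)
})

test_that("the temporal tunnel matches symmetry and brute-force scans", {
  # ten atoms on a sphere of radius 3 around the ligand
  th <- seq_len(10) * 2 * pi / 10
  shell <- cbind(3 * cos(th), 3 * sin(th), 0)
  atoms <- tibble::tibble(name = "C1", element = "C", resname = "ALA",
                          resid = 1:10, chain = "A")
  fs <- frame_set(atoms, shell, n_frames = 1)
  traj <- ligand_trajectory(matrix(0, 1, 3))
  tt <- temporal_tunnel(fs, traj)
  expect_equal(c(tt$x, tt$y, tt$z), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(tt$r, 3, tolerance = 1e-12)

  # an 11th atom closer to the ligand shifts the centre and sets the radius
  atoms11 <- tibble::tibble(name = "C1", element = "C", resname = "ALA",
                            resid = 1:11, chain = "A")
  shell11 <- rbind(shell, c(1, 0, 0))
  fs11 <- frame_set(atoms11, shell11, n_frames = 1)
  tt11 <- temporal_tunnel(fs11, traj)
  d10 <- sqrt(rowSums(shell11^2))
  nearest <- order(d10)[1:10]
  ctr <- colMeans(shell11[nearest, ])
  expect_equal(c(tt11$x, tt11$y, tt11$z), ctr, tolerance = 1e-12)
  expect_equal(tt11$r, sqrt(min(rowSums(sweep(shell11, 2, ctr)^2))),
               tolerance = 1e-12)

  expect_error(temporal_tunnel(fs, ligand_trajectory(matrix(0, 2, 3))),
               "differ")
})

test_that("temporal tunnel radius equals the exhaustive minimum on the fixture", {
  sc <- small_scenario()
  tt <- temporal_tunnel(sc$frames, sc$ligand)
  m <- frame_coords(sc$frames, 0)   # static protein
  for (i in seq(1, nrow(tt), by = 16)) {
    ctr <- c(tt$x[i], tt$y[i], tt$z[i])
    expect_equal(tt$r[i], sqrt(min(rowSums(sweep(m, 2, ctr)^2))),
                 tolerance = 1e-12)
  }
})

test_that("lining residues use clamped vdW-surface distances", {
  atoms <- tibble::tibble(name = c("H1", "C1"), element = c("H", "C"),
                          resname = c("ILE", "GLY"), resid = c(1L, 2L),
                          chain = "A")
  fs <- frame_set(atoms, rbind(c(3, 0, 0), c(10, 0, 0)), n_frames = 1)
  lig <- matrix(c(0, 0, 0), 1, 3)   # default ligand radius 1.70
  lin <- lining_residues(fs, lig, 0, k = 3)
  # centre distance 3.0 minus hydrogen (1.20) and ligand (1.70) radii
  expect_equal(lin$distance[1], 3 - 1.20 - 1.70, tolerance = 1e-12)
  expect_equal(lin$residue, c("A:1", "A:2"))  # k=3 but only 2 residues
  expect_equal(nrow(lin), 2L)

  # clamping: overlapping atoms have surface distance 0, never negative
  fs2 <- frame_set(atoms[2, ], matrix(c(1, 0, 0), 1, 3), n_frames = 1)
  lin2 <- lining_residues(fs2, lig, 0)
  expect_equal(lin2$distance, 0)
})

test_that("lining, hydrophobicity and charge match exhaustive scans", {
  sc <- small_scenario()
  tab <- small_attributes()
  kd <- kyte_doolittle()
  atoms <- sc$frames$atoms
  m <- frame_coords(sc$frames, 0)
  keys <- paste0(atoms$chain, ":", atoms$resid)
  p <- traj_mat(sc$ligand)
  for (i in seq(1, nrow(tab), by = 7)) {
    d <- sqrt(colSums((t(m) - p[i, ])^2)) - atoms$radius - 1.70
    d <- pmax(d, 0)
    res_min <- tapply(d, keys, min)
    ord <- order(res_min)[1:3]
    expect_equal(unlist(tab[i, paste0("lining_resid_", 1:3)], use.names = FALSE),
                 names(res_min)[ord])
    expect_equal(unlist(tab[i, paste0("lining_dist_", 1:3)], use.names = FALSE),
                 as.numeric(res_min[ord]), tolerance = 1e-12)
    # hydrophobicity: mean scale value over residues within 2 A
    sel <- names(res_min)[res_min <= 2]
    if (length(sel) == 0) {
      expect_true(is.na(tab$hydrophobicity[i]))
    } else {
      rn <- atoms$resname[match(sel, keys)]
      expect_equal(tab$hydrophobicity[i], mean(kd[rn]), tolerance = 1e-12)
    }
    # charge: mean partial charge over atoms within 2 A
    sel_a <- which(d <= 2)
    if (length(sel_a) == 0) {
      expect_true(is.na(tab$charge[i]))
    } else {
      expect_equal(tab$charge[i], mean(atoms$charge[sel_a]), tolerance = 1e-12)
    }
  }
})

test_that("hydrophobicity profile handles single, empty and paired lining sets", {
  atoms <- tibble::tibble(name = "C1", element = "C", resname = "ILE",
                          resid = 1L, chain = "A")
  fs <- frame_set(atoms, matrix(c(3, 0, 0), 1, 3), n_frames = 1)
  lig <- matrix(0, 1, 3)
  expect_equal(hydrophobicity_profile(fs, lig, 0, cutoff = 2), 4.5)  # ILE
  # residue far beyond the cutoff: empty lining set stays missing
  fs_far <- frame_set(atoms, matrix(c(10, 0, 0), 1, 3), n_frames = 1)
  expect_true(is.na(hydrophobicity_profile(fs_far, lig, 0, cutoff = 2)))

  atoms2 <- tibble::tibble(name = c("C1", "C2"), element = "C",
                           resname = c("ALA", "ARG"), resid = 1:2, chain = "A")
  fs2 <- frame_set(atoms2, rbind(c(3, 0, 0), c(-3, 0, 0)), n_frames = 1)
  expect_equal(hydrophobicity_profile(fs2, lig, 0, cutoff = 2),
               (1.8 + (-4.5)) / 2)
})

test_that("charge profile averages in-range atoms and reports missing sets", {
  atoms <- tibble::tibble(name = c("C1", "C2"), element = "C",
                          resname = "ALA", resid = 1:2, chain = "A",
                          charge = c(0.5, -0.5))
  fs <- frame_set(atoms, rbind(c(3, 0, 0), c(-3, 0, 0)), n_frames = 1)
  lig <- matrix(0, 1, 3)
  expect_equal(charge_profile(fs, lig, 0, cutoff = 2), 0)
  fs_far <- frame_set(atoms, rbind(c(10, 0, 0), c(-10, 0, 0)), n_frames = 1)
  expect_true(is.na(charge_profile(fs_far, lig, 0, cutoff = 2)))
  fs_nochg <- frame_set(atoms[, setdiff(names(atoms), "charge")],
                        rbind(c(3, 0, 0), c(-3, 0, 0)), n_frames = 1)
  expect_true(is.na(charge_profile(fs_nochg, lig, 0)))
})

test_that("residue turnover is the symmetric-difference size", {
  expect_equal(residue_turnover(c("A", "B", "C"), c("A", "B", "C")), 0L)
  expect_equal(residue_turnover(c("A", "B", "C"), c("A", "B", "D")), 2L)
  expect_equal(residue_turnover(c("A", "B", "C"), c("D", "E", "F")), 6L)
  expect_equal(residue_turnover(character(0), c("A")), 1L)
})

test_that("positional classification follows the priority rules", {
  sc <- small_scenario()
  # at the active-site centre: active_site wins regardless of burial
  a0 <- active_site_position(sc$frames, sc$active_site, 0)
  traj1 <- ligand_trajectory(matrix(a0, 1, 3),
                             steps = 0)
  fs1 <- frame_set(sc$frames$atoms, frame_coords(sc$frames, 0), n_frames = 1)
  expect_equal(classify_position(fs1, traj1, sc$active_site, x = 0),
               "active_site")
  # 100 A away from everything: outside
  far <- ligand_trajectory(matrix(c(200, 200, 200), 1, 3))
  expect_equal(classify_position(fs1, far, sc$active_site, x = 0), "outside")
})

test_that("classification recovers the generator's phase plan", {
  sc <- default_scenario()
  tab <- default_attributes()
  agree <- mean(tab$category == sc$ground_truth$expected_category)
  expect_gte(agree, 0.9)
})

test_that("sliding-window smoothing clips ends and skips missing values", {
  expect_equal(sliding_window(c(4, 8, 15), 1), c(4, 8, 15))
  expect_equal(sliding_window(rep(3, 10), 5), rep(3, 10))
  ramp <- 0:10
  sm <- sliding_window(ramp, 3)
  expect_equal(sm[2:10], as.numeric(1:9))       # interior unchanged
  expect_equal(sm[1], mean(c(0, 1)))            # clipped end
  expect_equal(sm[11], mean(c(9, 10)))
  withna <- c(1, NA, 3)
  expect_equal(sliding_window(withna, 3), c(1, 2, 3))
  expect_true(is.na(sliding_window(c(NA, NA, NA), 3)[2]))
})

test_that("bar aggregation partitions steps with the remainder rule", {
  v <- c(rep(1, 10), rep(3, 10))
  b <- aggregate_bars(v, 2)
  expect_equal(b$mean, c(1, 3))
  expect_equal(b$start, c(0L, 10L))

  b7 <- aggregate_bars(1:7, 2)
  expect_equal(b7$end - b7$start, c(4L, 3L))

  ident <- aggregate_bars(1:5, 5)
  expect_equal(ident$mean, as.numeric(1:5))

  # more bins than steps: one step per bin, extras dropped
  over <- aggregate_bars(1:3, 10)
  expect_equal(nrow(over), 3L)

  cats <- c("outside", "outside", "active_site", "surface")
  bc <- aggregate_bars(rep(1, 4), 1, cats)
  expect_equal(bc$category, "outside")                 # modal wins
  bc2 <- aggregate_bars(rep(1, 4), 2, c("inside", "active_site", "a", "a"))
  expect_equal(bc2$category[1], "active_site")         # tie -> priority order
})
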