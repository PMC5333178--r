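# Deterministic synthetic protein + ligand scenarios.
#
# The generator emulates the statistical and geometric structure the
# analysis assumes - not physics. The protein is a static ball of 3-atom
# pseudo-residues with a cleared cylindrical channel along +z leading to a
# small central cavity ringed by the active-site residues. The ligand is a
# single pseudo-atom whose path follows a labelled phase plan:
#
#   outside     random walk well beyond the protein surface
#   surface     drift along the surface towards the channel entrance
#   transit     persistent (ballistic) motion up and down the channel
#   stuck       Ornstein-Uhlenbeck oscillation around a channel point
#   active_site approach to and oscillation at the channel end
#
# Gaussian jitter is added everywhere. Every step carries its ground-truth
# phase label, so classification and stuckness can be validated against a
# known segmentation.

#' Scenario specification
#'
#' Parameters of the synthetic protein + ligand generator. The defaults are
#' the package's standard validation scenario: 2000 steps over five phases
#' (outside 500, surface 300, transit 400, stuck 500, active site 300),
#' a ~800-atom protein ball of radius 15 A with a channel of radius 2.5 A,
#' stuck-phase oscillation amplitude 0.8 A, transit step length 0.7 A and
#' positional jitter 0.1 A.
#'
#' @param seed Random seed (integer).
#' @param n_steps Total step count; must equal the summed phase durations.
#' @param phases Data frame with columns `label` (one of outside, surface,
#'   transit, stuck, active_site) and `duration` (steps).
#' @param n_atoms Approximate protein atom count (rounded to whole 3-atom
#'   residues, plus the 3 active-site residues).
#' @param inner_radius,outer_radius Radial range of protein atom centres (A).
#' @param channel_radius Void radius of the channel along +z (A); must
#'   exceed the ligand radius (1.7 A).
#' @param jitter Gaussian positional jitter sigma added to every step (A).
#' @param step_length Transit step length (A/step).
#' @param stuck_amplitude Stuck-phase oscillation amplitude (A).
#' @param dt Frame spacing (fs).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 42, n_steps = 2000,
                          phases = NULL,
                          n_atoms = 800, inner_radius = 3, outer_radius = 15,
                          channel_radius = 2.5, jitter = 0.1,
                          step_length = 0.7, stuck_amplitude = 0.8, dt = 2) {
  if (is.null(phases)) {
    phases <- tibble(
      label = c("outside", "surface", "transit", "stuck", "active_site"),
      duration = c(500L, 300L, 400L, 500L, 300L))
    total <- sum(phases$duration)
    if (n_steps != total) {
      # rescale the default plan to the requested length
      phases$duration <- pmax(1L, as.integer(round(phases$duration * n_steps / total)))
      phases$duration[nrow(phases)] <- n_steps - sum(phases$duration[-nrow(phases)])
    }
  }
  phases <- as_tibble(phases)
  ok_labels <- c("outside", "surface", "transit", "stuck", "active_site")
  if (!all(phases$label %in% ok_labels))
    abort(paste0("phase labels must be one of: ", paste(ok_labels, collapse = ", ")))
  if (sum(phases$duration) != n_steps)
    abort("phase durations must sum to n_steps")
  if (any(phases$duration < 1)) abort("phase durations must be positive")
  if (jitter < 0) abort("jitter sigma must be non-negative")
  if (channel_radius <= 1.7)
    abort("channel radius must exceed the ligand radius (1.7 A)")
  if (channel_radius >= outer_radius)
    abort("infeasible geometry: channel radius must be below the outer radius")
  if (inner_radius >= outer_radius) abort("inner radius must be below outer radius")
  structure(list(seed = as.integer(seed), n_steps = as.integer(n_steps),
                 phases = phases, n_atoms = as.integer(n_atoms),
                 inner_radius = inner_radius, outer_radius = outer_radius,
                 channel_radius = channel_radius, jitter = jitter,
                 step_length = step_length, stuck_amplitude = stuck_amplitude,
                 dt = dt),
            class = "scenario_spec")
}

#' Generate a labelled synthetic protein + ligand scenario
#'
#' Deterministic for a fixed seed (Mersenne-Twister / inversion sampling).
#' Optionally writes the standard input files: multi-model PDB
#' (protein + ligand), PQR with channel-lining charges, active-site YAML and
#' ground-truth JSON.
#'
#' @param spec A [scenario_spec()] (or arguments forwarded to it).
#' @param outdir Optional directory; when given, input files are written.
#' @return A list of class `md_scenario` with elements `frames`
#'   ([frame_set()], static protein), `ligand` ([ligand_trajectory()]),
#'   `ligand_atoms` (`frame_set` of the single ligand atom), `active_site`
#'   ([active_site_spec()]), `ground_truth` (tibble: `step`, `phase`,
#'   `expected_category`), `active_center`, `spec` and `files`.
#' @export
generate_scenario <- function(spec = scenario_spec(), outdir = NULL) {
  if (!inherits(spec, "scenario_spec")) abort("spec must be a scenario_spec()")
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  prot <- build_protein(spec)
  active_center <- prot$active_center
  lig <- build_ligand_path(spec, active_center)

  frames <- frame_set(prot$atoms, prot$coords, dt = spec$dt,
                      n_frames = spec$n_steps)
  ligand <- ligand_trajectory(lig$positions)
  ligand_atoms <- frame_set(
    tibble(name = "C1", element = "C", resname = "LIG",
           resid = max(prot$atoms$resid) + 1L, chain = "A",
           charge = 0, radius = 1.70),
    lapply(seq_len(spec$n_steps), function(i) lig$positions[i, , drop = FALSE]),
    dt = spec$dt)

  phase_to_category <- c(outside = "outside", surface = "surface",
                         transit = "inside", stuck = "inside",
                         active_site = "active_site")
  ground_truth <- tibble(step = 0:(spec$n_steps - 1), phase = lig$phase,
                         expected_category = unname(phase_to_category[lig$phase]))

  active_site <- active_site_spec(tibble(chain = "A", resid = prot$active_resids))

  files <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files$trajectory <- file.path(outdir, "trajectory.pdb")
    write_frameset_pdb(frames, files$trajectory, ligand_atoms = ligand_atoms)
    files$charges <- file.path(outdir, "protein.pqr")
    write_pqr(frames, files$charges)
    files$active_site <- file.path(outdir, "active_site.yaml")
    write_active_site(active_site, files$active_site)
    files$ground_truth <- file.path(outdir, "ground_truth.json")
    jsonlite::write_json(
      list(phases = spec$phases, ground_truth = ground_truth,
           active_center = active_center, seed = spec$seed),
      files$ground_truth, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }

  structure(
    list(frames = frames, ligand = ligand, ligand_atoms = ligand_atoms,
         active_site = active_site, ground_truth = ground_truth,
         active_center = active_center, spec = spec, files = files),
    class = "md_scenario")
}

# ---- protein construction -------------------------------------------------

build_protein <- function(spec) {
  n_res <- max(4L, spec$n_atoms %/% 3L)
  clear_r <- spec$channel_radius + 1.5   # atom centres cleared off the channel
  cavity_r <- 4.2                        # cleared central cavity

  # residue centres: uniform in the shell, rejecting channel and cavity
  centers <- matrix(NA_real_, n_res, 3)
  got <- 0
  while (got < n_res) {
    k <- (n_res - got) * 3
    u <- matrix(rnorm(k * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- (runif(k) * (spec$outer_radius^3 - spec$inner_radius^3) +
              spec$inner_radius^3)^(1 / 3)
    cand <- u * rad
    lat <- sqrt(cand[, 1]^2 + cand[, 2]^2)
    ok <- !(cand[, 3] > 0 & lat < clear_r) & sqrt(rowSums(cand^2)) > cavity_r
    cand <- cand[ok, , drop = FALSE]
    take <- min(nrow(cand), n_res - got)
    if (take > 0) {
      centers[(got + 1):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }

  # active-site residues: a 3-residue ring around the cavity, below the
  # channel mouth so their atoms do not block it
  ring_ang <- c(90, 210, 330) * pi / 180
  as_centers <- cbind(3.4 * cos(ring_ang), 3.4 * sin(ring_ang), -1.6)
  centers <- rbind(centers, as_centers)
  n_res_all <- nrow(centers)

  aa20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")
  resnames <- aa20[((seq_len(n_res_all) - 1) %% 20) + 1]
  elements <- c("C", "N", "O")

  # three atoms per residue around its centre
  offsets <- matrix(rnorm(n_res_all * 9, sd = 0.8), ncol = 3)
  atom_xyz <- centers[rep(seq_len(n_res_all), each = 3), ] + offsets

  # channel-lining residues carry alternating +/-0.3 charges
  lat_c <- sqrt(centers[, 1]^2 + centers[, 2]^2)
  lining <- centers[, 3] > 1 & lat_c < clear_r + 2.5
  res_charge <- rep(0, n_res_all)
  lin_idx <- which(lining)
  if (length(lin_idx) > 0)
    res_charge[lin_idx] <- 0.3 * (-1)^(seq_along(lin_idx))

  atoms <- tibble(
    name = paste0(rep(elements, n_res_all), "1"),
    element = rep(elements, n_res_all),
    resname = rep(resnames, each = 3),
    resid = rep(seq_len(n_res_all), each = 3),
    chain = "A",
    charge = rep(res_charge, each = 3),
    radius = vdw_radius(rep(elements, n_res_all))
  )

  active_resids <- (n_res_all - 2):n_res_all
  as_atom_idx <- which(atoms$resid %in% active_resids)
  w <- atomic_mass(atoms$element[as_atom_idx])
  active_center <- colSums(atom_xyz[as_atom_idx, , drop = FALSE] * w) / sum(w)

  list(atoms = atoms, coords = atom_xyz, active_center = active_center,
       active_resids = active_resids)
}

# ---- ligand path ----------------------------------------------------------

build_ligand_path <- function(spec, active_center) {
  durations <- spec$phases$duration
  labels <- spec$phases$label
  outer <- spec$outer_radius

  pos <- matrix(NA_real_, spec$n_steps, 3)
  phase <- character(spec$n_steps)
  cur <- c(0, 0, outer + 11)   # default start: above the channel entrance
  row <- 0L

  for (ph in seq_along(labels)) {
    dur <- durations[ph]
    lab <- labels[ph]
    seg <- switch(
      lab,
      outside = walk_outside(cur, dur, spec),
      surface = walk_surface(cur, dur, spec),
      transit = walk_transit(cur, dur, spec),
      stuck = walk_stuck(cur, dur, spec),
      active_site = walk_active(cur, dur, spec, active_center)
    )
    pos[(row + 1):(row + dur), ] <- seg
    phase[(row + 1):(row + dur)] <- lab
    row <- row + dur
    cur <- seg[dur, ]
  }

  if (spec$jitter > 0)
    pos <- pos + matrix(rnorm(length(pos), sd = spec$jitter), ncol = 3)

  list(positions = pos, phase = phase)
}

# random walk constrained to a radial band [rmin, rmax]
banded_walk <- function(start, dur, step_sd, rmin, rmax) {
  out <- matrix(NA_real_, dur, 3)
  p <- clamp_radial(start, rmin, rmax)
  for (i in seq_len(dur)) {
    p <- clamp_radial(p + rnorm(3, sd = step_sd), rmin, rmax)
    out[i, ] <- p
  }
  out
}

clamp_radial <- function(p, rmin, rmax) {
  r <- sqrt(sum(p^2))
  if (r < 1e-12) return(c(rmin, 0, 0))
  if (r < rmin) p * rmin / r else if (r > rmax) p * rmax / r else p
}

walk_outside <- function(cur, dur, spec) {
  outer <- spec$outer_radius
  banded_walk(cur, dur, spec$step_length / sqrt(3), outer + 9.5, outer + 15)
}

# drift along the surface band towards the channel entrance direction (+z)
walk_surface <- function(cur, dur, spec) {
  outer <- spec$outer_radius
  r_target <- outer + 2.5
  u0 <- cur / sqrt(sum(cur^2))
  uz <- c(0, 0, 1)
  ang <- acos(min(1, max(-1, sum(u0 * uz))))
  axis <- pracma_cross(u0, uz)
  if (sqrt(sum(axis^2)) < 1e-9) axis <- c(1, 0, 0) else axis <- axis / sqrt(sum(axis^2))
  out <- matrix(NA_real_, dur, 3)
  r0 <- sqrt(sum(cur^2))
  ramp <- min(dur, 40L)
  for (i in seq_len(dur)) {
    frac <- min(1, i / max(1, dur - 20L))        # great-circle progress
    u <- rotate_about(u0, axis, ang * frac)
    r <- if (i <= ramp) r0 + (r_target - r0) * i / ramp else r_target
    out[i, ] <- u * r + rnorm(3, sd = 0.15)
  }
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotate_about <- function(v, axis, theta) {
  # Rodrigues rotation
  v * cos(theta) + pracma_cross(axis, v) * sin(theta) +
    axis * sum(axis * v) * (1 - cos(theta))
}

# persistent (ballistic) motion along the channel axis with reflection:
# straight 0.7 A steps within a 9-step window, while the ligand shuttles
# up and down the channel
walk_transit <- function(cur, dur, spec) {
  z_lo <- 4.5; z_hi <- 9
  s <- spec$step_length
  # ballistic z motion: descend from the entrance, then shuttle between the
  # channel bottom and mid-channel (reflection), so 9-step windows are
  # straight while the ligand travels up and down the channel repeatedly
  z <- numeric(dur)
  zc <- cur[3]
  vz <- -s
  entered <- FALSE
  for (i in seq_len(dur)) {
    zc <- zc + vz
    if (zc < z_lo) { zc <- z_lo + (z_lo - zc); vz <- -vz }
    if (zc < z_hi) entered <- TRUE
    if (entered && zc > z_hi) { zc <- z_hi - (zc - z_hi); vz <- -vz }
    z[i] <- zc
  }
  # end the phase near the channel bottom so the stuck phase that follows
  # sits deep in the channel, close to the active site (the backward-scan
  # window is wider than the 2s lattice spacing, so a match always exists)
  target <- z_lo + 0.9
  for (L in 0:min(dur - 1, 25)) {
    j <- dur - L
    if (abs(z[j] - (target + L * s)) <= 1.05 * s) {
      if (L > 0) z[(j + 1):dur] <- z[j] - s * seq_len(L)
      break
    }
  }
  # lateral jitter constrained to the channel void
  out <- matrix(NA_real_, dur, 3)
  lat <- cur[1:2]
  lim <- spec$channel_radius - 1.7
  for (i in seq_len(dur)) {
    lat <- lat * 0.85 + rnorm(2, sd = 0.12)
    lr <- sqrt(sum(lat^2))
    if (lr > lim) lat <- lat * lim / lr
    out[i, ] <- c(lat, z[i])
  }
  out
}

# Ornstein-Uhlenbeck oscillation around the current point
ou_walk <- function(center, start, dur, sd_axis, theta = 0.25) {
  sigma <- sd_axis * sqrt(2 * theta - theta^2)
  out <- matrix(NA_real_, dur, 3)
  p <- start
  for (i in seq_len(dur)) {
    p <- p + theta * (center - p) + rnorm(3, sd = sigma)
    out[i, ] <- p
  }
  out
}

walk_stuck <- function(cur, dur, spec) {
  ou_walk(center = cur, start = cur, dur = dur,
          sd_axis = spec$stuck_amplitude / sqrt(3))
}

walk_active <- function(cur, dur, spec, active_center) {
  approach <- min(24L, dur %/% 3L)
  out <- matrix(NA_real_, dur, 3)
  if (approach > 0) {
    for (i in seq_len(approach)) {
      frac <- i / approach
      out[i, ] <- cur + (active_center - cur) * frac + rnorm(3, sd = 0.08)
    }
  }
  rest <- dur - approach
  if (rest > 0) {
    start <- if (approach > 0) out[approach, ] else cur
    osc <- ou_walk(center = active_center, start = start, dur = rest,
                   sd_axis = 0.35)
    # stay well inside the active-site radius
    for (i in seq_len(rest)) {
      dvec <- osc[i, ] - active_center
      dl <- sqrt(sum(dvec^2))
      if (dl > 2.5) osc[i, ] <- active_center + dvec * 2.5 / dl
    }
    out[(approach + 1):dur, ] <- osc
  }
  out
}

# ---- simple trajectory fixtures ------------------------------------------

#' Synthetic single-trajectory fixtures
#'
#' Small labelled trajectories without a protein, used to exercise the
#' simplification machinery: pure jitter around a fixed point, a smooth
#' helix with a noisy middle third, and an unconstrained random walk.
#'
#' @param kind `"noise"`, `"helix_knot"` or `"random_walk"`.
#' @param n_steps Number of points (default 200).
#' @param seed Random seed.
#' @param sigma Noise sigma in Angstrom (default 0.5).
#' @param step Random-walk per-axis step sigma (default 0.5).
#' @return A [ligand_trajectory()]. For `"helix_knot"` the attribute
#'   `noisy_range` gives the 0-based half-open step range of the noisy third.
#' @export
synthetic_trajectory <- function(kind = c("noise", "helix_knot", "random_walk"),
                                 n_steps = 200, seed = 42, sigma = 0.5,
                                 step = 0.5) {
  kind <- match.arg(kind)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  if (kind == "noise") {
    m <- matrix(rnorm(n_steps * 3, sd = sigma), ncol = 3)
    return(ligand_trajectory(m))
  }
  if (kind == "random_walk") {
    m <- apply(matrix(rnorm(n_steps * 3, sd = step), ncol = 3), 2, cumsum)
    return(ligand_trajectory(m))
  }
  # helix with a noisy middle third
  t <- seq_len(n_steps)
  ang <- 0.1 * t
  m <- cbind(2 * cos(ang), 2 * sin(ang), 0.35 * t)
  third <- floor(n_steps / 3)
  noisy <- (third + 1):(2 * third)
  m[noisy, ] <- m[noisy, ] + matrix(rnorm(length(noisy) * 3, sd = sigma), ncol = 3)
  traj <- ligand_trajectory(m)
  attr(traj, "noisy_range") <- c(third, 2 * third)  # half-open, 0-based
  traj
}
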