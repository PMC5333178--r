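# Per-time-step attribute derivation.
#
# All per-step geometry is frame-local (no superposition): distances are
# measured inside each frame. Residue-ligand distances default to
# vdW-surface distance (centre distance minus both radii, clamped at 0); a
# centre-to-centre mode is available. Missing values propagate as NA - a
# missing charge table yields a missing charge profile, never zero.

#' Stuckness of the ligand at one time step
#'
#' The straightness ratio in a temporal window of `2n + 1` consecutive
#' positions around step `x`: the maximal pairwise Euclidean distance in the
#' window divided by the summed consecutive step lengths. The ratio is 1 for
#' perfectly straight monotone motion and drops towards 0 when the ligand
#' oscillates in place; the displayed *stuckness* is `1 - s`. At the
#' trajectory ends the window is shrunk. A frozen window (path length below
#' 1e-9 A) has no defined ratio: `NA` is returned (the stuckness display
#' value is then 1, maximally stuck).
#'
#' @param traj A [ligand_trajectory()] (>= 2 points).
#' @param x 0-based time-step index.
#' @param n Half-window size in steps (default 4).
#' @return The straightness ratio `s` in (0, 1], or `NA` for a frozen window.
#' @seealso [stuckness_series()] for all steps at once.
#' @export
stuckness <- function(traj, x, n = 4) {
  if (nrow(traj) < 2) abort("stuckness needs a trajectory of at least 2 points")
  if (n < 1) abort("half-window n must be >= 1")
  m <- traj_matrix(traj)
  stuckness_window(m, as.integer(x), as.integer(n))
}

stuckness_window <- function(m, x, n) {
  N <- nrow(m)
  lo <- max(0L, x - n) + 1L          # 1-based rows
  hi <- min(N - 1L, x + n) + 1L
  w <- m[lo:hi, , drop = FALSE]
  if (nrow(w) < 2) return(NA_real_)
  steps <- sqrt(rowSums((w[-1, , drop = FALSE] - w[-nrow(w), , drop = FALSE])^2))
  path <- sum(steps)
  if (path < 1e-9) return(NA_real_)
  max(stats::dist(w)) / path
}

#' Stuckness series over all time steps
#'
#' @inheritParams stuckness
#' @return A tibble with columns `step`, `straightness` (the raw ratio `s`,
#'   `NA` when frozen), `stuckness` (`1 - s`, or 1 when frozen) and `frozen`.
#' @export
stuckness_series <- function(traj, n = 4) {
  if (nrow(traj) < 2) abort("stuckness needs a trajectory of at least 2 points")
  if (n < 1) abort("half-window n must be >= 1")
  m <- traj_matrix(traj)
  N <- nrow(m)
  s <- vapply(0:(N - 1), function(x) stuckness_window(m, x, as.integer(n)),
              numeric(1))
  frozen <- is.na(s)
  tibble(step = traj$step, straightness = s,
         stuckness = ifelse(frozen, 1, 1 - s), frozen = frozen)
}

#' Active-site position
#'
#' The active site is located at the mass-weighted centre of all atoms of
#' its defining residues, evaluated per frame.
#'
#' @param frames A [frame_set()].
#' @param spec An [active_site_spec()].
#' @param x 0-based frame index, or `NULL` for all frames.
#' @return For a single `x`, a length-3 numeric vector; otherwise a tibble
#'   with columns `step`, `x`, `y`, `z`.
#' @export
active_site_position <- function(frames, spec, x = NULL) {
  idx <- resolve_active_site(frames, spec)
  w <- atomic_mass(frames$atoms$element[idx])
  com <- function(f) {
    m <- frame_coords(frames, f)[idx, , drop = FALSE]
    colSums(m * w) / sum(w)
  }
  if (!is.null(x)) return(com(x))
  pos <- t(vapply(0:(frames$n_frames - 1), com, numeric(3)))
  tibble(step = 0:(frames$n_frames - 1), x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Distance of the ligand from the active site
#'
#' Euclidean distance between the ligand reference point and the
#' active-site centre of mass, per time step.
#'
#' @param traj A [ligand_trajectory()].
#' @param frames A [frame_set()] (same frame count).
#' @param spec An [active_site_spec()].
#' @return A tibble with columns `step` and `dist_active_site` (Angstrom).
#' @export
distance_series <- function(traj, frames, spec) {
  if (nrow(traj) != frames$n_frames)
    abort("trajectory length and frame count differ")
  a <- active_site_position(frames, spec)
  p <- traj_matrix(traj)
  d <- sqrt(rowSums((p - as.matrix(a[, c("x", "y", "z")]))^2))
  tibble(step = traj$step, dist_active_site = d)
}

#' Direction of ligand movement relative to the active site
#'
#' The sign of the discrete derivative of the distance series: a step is
#' `"toward"` when the distance to the active site decreases to the next
#' step and `"away"` when it increases. Exact ties inherit the previous
#' label (the first step defaults to `"away"`), and the last step inherits
#' its predecessor.
#'
#' @param distances Numeric vector of per-step distances (or a tibble with a
#'   `dist_active_site` column).
#' @return Character vector (`"toward"`/`"away"`) of the same length.
#' @export
direction_series <- function(distances) {
  if (is.data.frame(distances)) distances <- distances$dist_active_site
  N <- length(distances)
  if (N < 2) abort("direction needs at least 2 steps")
  diffs <- diff(distances)
  lab <- rep(NA_character_, N)
  lab[seq_len(N - 1)] <- ifelse(diffs < 0, "toward",
                                ifelse(diffs > 0, "away", NA_character_))
  if (is.na(lab[1])) lab[1] <- "away"
  for (i in 2:N) if (is.na(lab[i])) lab[i] <- lab[i - 1]
  lab
}

#' Ligand speed series
#'
#' The distance between consecutive reference positions divided by the
#' frame spacing; the last step repeats its predecessor.
#'
#' @param traj A [ligand_trajectory()] (>= 2 points).
#' @param dt Frame spacing in femtoseconds (default 2).
#' @return A tibble with columns `step` and `speed` (Angstrom / fs).
#' @export
speed_series <- function(traj, dt = 2) {
  if (nrow(traj) < 2) abort("speed needs at least 2 steps")
  if (dt <= 0) abort("dt must be positive")
  m <- traj_matrix(traj)
  v <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)) / dt
  tibble(step = traj$step, speed = c(v, v[length(v)]))
}

#' Temporal tunnel
#'
#' When no computed tunnel is available, the free space around the ligand
#' is approximated per time step by a single sphere: its centre is the
#' unweighted mean position of the ten protein atoms closest to the ligand
#' reference point, and its radius is the minimum distance from that centre
#' to any protein atom.
#'
#' @param frames A [frame_set()] with >= 10 protein atoms.
#' @param traj The ligand [ligand_trajectory()].
#' @return A [tunnel_profile()] with source `"temporal"` (one sphere per step).
#' @export
temporal_tunnel <- function(frames, traj) {
  if (nrow(frames$atoms) < 10)
    abort("the temporal tunnel needs at least 10 protein atoms")
  if (nrow(traj) != frames$n_frames)
    abort("trajectory length and frame count differ")
  p <- traj_matrix(traj)
  rows <- lapply(seq_len(nrow(traj)), function(i) {
    m <- frame_coords(frames, traj$step[i])
    d <- sqrt(rowSums(sweep(m, 2, p[i, ])^2))
    nearest <- order(d)[1:10]
    ctr <- colMeans(m[nearest, , drop = FALSE])
    rad <- sqrt(min(rowSums(sweep(m, 2, ctr)^2)))
    c(ctr, rad)
  })
  rows <- do.call(rbind, rows)
  tunnel_profile(tibble(frame = traj$step, x = rows[, 1], y = rows[, 2],
                        z = rows[, 3], r = rows[, 4]),
                 source = "temporal")
}

#' Free-space radius at one time step
#'
#' Looks up the tunnel sphere the ligand sits in at step `x`: among the
#' spheres of that frame containing the reference point, the one whose
#' centre is nearest is chosen and its radius returned. When no sphere
#' contains the point, the nearest sphere's radius is returned with
#' `outside_tunnel = TRUE`. When the frame is absent from the profile the
#' temporal tunnel is used for that step (requires `frames`).
#'
#' @param tunnel A [tunnel_profile()].
#' @param traj The ligand [ligand_trajectory()].
#' @param x 0-based time-step index.
#' @param frames Optional [frame_set()] for the temporal-tunnel fallback.
#' @return One-row tibble: `step`, `free_space` (A), `free_space_source`,
#'   `outside_tunnel`.
#' @export
free_space_from_tunnel <- function(tunnel, traj, x, frames = NULL) {
  i <- match(x, traj$step)
  if (is.na(i)) abort(paste0("step ", x, " not in trajectory"))
  p <- traj_matrix(traj)[i, ]
  sph <- tunnel[tunnel$frame == x, , drop = FALSE]
  if (nrow(sph) == 0) {
    if (is.null(frames))
      abort(paste0("tunnel profile has no spheres for step ", x,
                   " and no frames given for the temporal fallback"))
    inform(paste0("tunnel profile has no spheres for step ", x,
                  "; falling back to the temporal tunnel"))
    tt <- temporal_tunnel_at(frames, p, x)
    return(tibble(step = x, free_space = tt$r,
                  free_space_source = "temporal", outside_tunnel = FALSE))
  }
  dc <- sqrt((sph$x - p[1])^2 + (sph$y - p[2])^2 + (sph$z - p[3])^2)
  contains <- dc <= sph$r
  if (any(contains)) {
    j <- which(contains)[which.min(dc[contains])]
    tibble(step = x, free_space = sph$r[j],
           free_space_source = attr(tunnel, "source") %||% "imported",
           outside_tunnel = FALSE)
  } else {
    j <- which.min(dc)
    tibble(step = x, free_space = sph$r[j],
           free_space_source = attr(tunnel, "source") %||% "imported",
           outside_tunnel = TRUE)
  }
}

# one temporal-tunnel sphere for an arbitrary point
temporal_tunnel_at <- function(frames, p, x) {
  m <- frame_coords(frames, x)
  d <- sqrt(rowSums(sweep(m, 2, p)^2))
  nearest <- order(d)[1:10]
  ctr <- colMeans(m[nearest, , drop = FALSE])
  list(center = ctr, r = sqrt(min(rowSums(sweep(m, 2, ctr)^2))))
}

#' Free-space series over all steps
#'
#' @inheritParams free_space_from_tunnel
#' @param tunnel A [tunnel_profile()], or `NULL` to use the temporal tunnel
#'   throughout (requires `frames`).
#' @return A tibble with columns `step`, `free_space`, `free_space_source`,
#'   `outside_tunnel`.
#' @export
free_space_series <- function(traj, tunnel = NULL, frames = NULL) {
  if (is.null(tunnel)) {
    if (is.null(frames)) abort("free_space_series needs a tunnel or frames")
    tunnel <- temporal_tunnel(frames, traj)
  }
  purrr::map_dfr(traj$step, function(x)
    free_space_from_tunnel(tunnel, traj, x, frames = frames))
}

# ---- lining residues and profiles ----------------------------------------

# per-frame scan shared by lining/hydrophobicity/charge/classification:
# returns per-atom and per-residue surface distances to the ligand atoms
frame_scan <- function(frames, lig_m, lig_r, x, groups, mode = "surface") {
  m <- frame_coords(frames, x)
  atom_d <- rep(Inf, nrow(m))
  for (j in seq_len(nrow(lig_m))) {
    d <- sqrt(rowSums(sweep(m, 2, lig_m[j, ])^2))
    if (mode == "surface") d <- d - frames$atoms$radius - lig_r[j]
    atom_d <- pmin(atom_d, d)
  }
  if (mode == "surface") atom_d <- pmax(atom_d, 0)
  res_d <- vapply(groups$idx, function(ix) min(atom_d[ix]), numeric(1))
  list(atom = atom_d, residue = res_d)
}

residue_groups <- function(frames) {
  keys <- residue_keys(frames)
  idx <- split(seq_along(keys), factor(keys, levels = unique(keys)))
  first <- vapply(idx, `[`, integer(1), 1)
  list(idx = idx, key = names(idx), resname = frames$atoms$resname[first])
}

# ligand atom coordinates + radii at step x
ligand_atoms_at <- function(ligand_atoms, traj, x) {
  if (!is.null(ligand_atoms)) {
    list(m = frame_coords(ligand_atoms, x), r = ligand_atoms$atoms$radius)
  } else {
    i <- match(x, traj$step)
    list(m = traj_matrix(traj)[i, , drop = FALSE], r = .vdw_default)
  }
}

#' Lining residues at one time step
#'
#' The residues closest to the ligand. The residue-ligand distance is the
#' minimum over all (residue atom, ligand atom) pairs of the vdW-surface
#' distance (centre distance minus both radii, clamped at 0); set
#' `mode = "center"` for plain centre-to-centre distances. The `k` closest
#' residues are returned sorted by distance; `cutoff` (lining-set
#' semantics, used by the profile attributes) is not applied here unless
#' given.
#'
#' @param frames A [frame_set()].
#' @param ligand_atoms Ligand atom coordinates at step `x`: an n x 3 matrix,
#'   or a `frame_set` of the ligand atoms (its frame `x` is used).
#' @param x 0-based time-step index.
#' @param k Number of residues to return (default 3).
#' @param cutoff Optional distance cutoff in Angstrom (default `Inf`).
#' @param mode `"surface"` (default) or `"center"`.
#' @return A tibble with columns `step`, `rank`, `residue` (chain:resid
#'   key), `resname` and `distance`, at most `k` rows sorted ascending.
#' @export
lining_residues <- function(frames, ligand_atoms, x, k = 3, cutoff = Inf,
                            mode = c("surface", "center")) {
  mode <- match.arg(mode)
  groups <- residue_groups(frames)
  la <- normalize_ligand_atoms(ligand_atoms, x)
  scan <- frame_scan(frames, la$m, la$r, x, groups, mode)
  lining_from_scan(scan$residue, groups, x, k, cutoff)
}

normalize_ligand_atoms <- function(ligand_atoms, x) {
  if (inherits(ligand_atoms, "frame_set")) {
    list(m = frame_coords(ligand_atoms, x), r = ligand_atoms$atoms$radius)
  } else {
    m <- matrix(as.numeric(ligand_atoms), ncol = 3)
    list(m = m, r = rep(.vdw_default, nrow(m)))
  }
}

lining_from_scan <- function(res_d, groups, x, k, cutoff) {
  ord <- order(res_d)
  sel <- ord[res_d[ord] <= cutoff]
  sel <- head(sel, k)
  tibble(step = x, rank = seq_along(sel), residue = groups$key[sel],
         resname = groups$resname[sel], distance = unname(res_d[sel]))
}

#' Hydrophobicity profile at one time step
#'
#' The unweighted mean hydrophobicity-scale value over the residues lining
#' the ligand (surface distance <= `cutoff`). An empty lining set yields
#' `NA`; residues missing from the scale are skipped with a warning.
#'
#' @inheritParams lining_residues
#' @param cutoff Lining distance in Angstrom (default 2).
#' @param scale Named numeric vector keyed by three-letter residue code
#'   (default [kyte_doolittle()]).
#' @return A single numeric value (scale units) or `NA`.
#' @export
hydrophobicity_profile <- function(frames, ligand_atoms, x, cutoff = 2,
                                   scale = kyte_doolittle()) {
  groups <- residue_groups(frames)
  la <- normalize_ligand_atoms(ligand_atoms, x)
  scan <- frame_scan(frames, la$m, la$r, x, groups, "surface")
  hydrophobicity_from_scan(scan$residue, groups, cutoff, scale)
}

hydrophobicity_from_scan <- function(res_d, groups, cutoff, scale) {
  sel <- which(res_d <= cutoff)
  if (length(sel) == 0) return(NA_real_)
  vals <- scale[toupper(groups$resname[sel])]
  if (anyNA(vals)) {
    warn(paste0("residue(s) absent from the hydrophobicity scale, skipped: ",
                paste(unique(groups$resname[sel][is.na(vals)]), collapse = ", ")))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NA_real_)
  }
  mean(vals)
}

#' Charge profile at one time step
#'
#' The mean partial charge over protein atoms whose surface distance to any
#' ligand atom is at most `cutoff`. Requires per-atom charges; `NA` when the
#' in-range set is empty.
#'
#' @inheritParams hydrophobicity_profile
#' @return Mean partial charge (elementary charges) or `NA`.
#' @export
charge_profile <- function(frames, ligand_atoms, x, cutoff = 2) {
  if (all(is.na(frames$atoms$charge))) return(NA_real_)
  groups <- residue_groups(frames)
  la <- normalize_ligand_atoms(ligand_atoms, x)
  scan <- frame_scan(frames, la$m, la$r, x, groups, "surface")
  charge_from_scan(scan$atom, frames$atoms$charge, cutoff)
}

charge_from_scan <- function(atom_d, charges, cutoff) {
  sel <- which(atom_d <= cutoff & !is.na(charges))
  if (length(sel) == 0) return(NA_real_)
  mean(charges[sel])
}

#' Residue turnover between two lining sets
#'
#' The number of residues that differ between two consecutive lining sets
#' (size of the symmetric set difference). With sets of at most 3 residues
#' the turnover is at most 6.
#'
#' @param lining_a,lining_b Character vectors of residue keys (or lining
#'   tibbles with a `residue` column).
#' @return Non-negative integer count.
#' @export
residue_turnover <- function(lining_a, lining_b) {
  a <- if (is.data.frame(lining_a)) lining_a$residue else lining_a
  b <- if (is.data.frame(lining_b)) lining_b$residue else lining_b
  a <- unique(a[!is.na(a)]); b <- unique(b[!is.na(b)])
  length(setdiff(a, b)) + length(setdiff(b, a))
}

# ---- positional classification -------------------------------------------

#' Classification thresholds
#'
#' Tunable thresholds of the four-way positional classification
#' (outside / surface / inside / active site). The taxonomy itself is
#' qualitative; these numeric defaults are package choices exposed here.
#'
#' @param active_site Active-site radius in Angstrom: steps with
#'   `d_AS <= active_site` are `active_site` (default 4).
#' @param outside_clearance Minimum vdW-surface distance to any protein atom
#'   beyond which the ligand counts as `outside` (default 5 A).
#' @param burial_contacts Number of protein atoms within the contact shell
#'   needed to count as `inside` (default 40).
#' @param contact_shell Contact shell radius around the reference point in
#'   Angstrom (default 8).
#' @return A list of class `category_thresholds`.
#' @export
category_thresholds <- function(active_site = 4, outside_clearance = 5,
                                burial_contacts = 40, contact_shell = 8) {
  vals <- c(active_site, outside_clearance, burial_contacts, contact_shell)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("all classification thresholds must be positive")
  structure(list(active_site = active_site,
                 outside_clearance = outside_clearance,
                 burial_contacts = burial_contacts,
                 contact_shell = contact_shell),
            class = "category_thresholds")
}

# category from precomputed per-step quantities; priority order
# active_site > outside > inside > surface
classify_from_scan <- function(d_as, min_surf, n_contacts, th) {
  if (d_as <= th$active_site) return("active_site")
  if (min_surf > th$outside_clearance) return("outside")
  if (n_contacts >= th$burial_contacts) return("inside")
  "surface"
}

#' Positional category of the ligand
#'
#' Assigns each step one of four categories describing where the ligand is
#' relative to the protein: `active_site` when within the active-site radius
#' of the active-site centre; otherwise `outside` when the minimum
#' vdW-surface distance to any protein atom exceeds the clearance;
#' otherwise `inside` when enough protein atoms fall within the contact
#' shell of the reference point; otherwise `surface`.
#'
#' @param frames A [frame_set()].
#' @param traj The ligand [ligand_trajectory()].
#' @param spec An [active_site_spec()].
#' @param thresholds A [category_thresholds()].
#' @param x 0-based step index, or `NULL` for all steps.
#' @param ligand_atoms Optional `frame_set` of ligand atoms (surface
#'   distances then use the real atoms rather than the reference point).
#' @return For a single `x`, one category string; otherwise a tibble with
#'   columns `step` and `category`.
#' @export
classify_position <- function(frames, traj, spec,
                              thresholds = category_thresholds(),
                              x = NULL, ligand_atoms = NULL) {
  d <- distance_series(traj, frames, spec)$dist_active_site
  groups <- residue_groups(frames)
  p <- traj_matrix(traj)
  one <- function(i) {
    xi <- traj$step[i]
    la <- ligand_atoms_at(ligand_atoms, traj, xi)
    scan <- frame_scan(frames, la$m, la$r, xi, groups, "surface")
    m <- frame_coords(frames, xi)
    contacts <- sum(rowSums(sweep(m, 2, p[i, ])^2) <= thresholds$contact_shell^2)
    classify_from_scan(d[i], min(scan$atom), contacts, thresholds)
  }
  if (!is.null(x)) return(one(match(x, traj$step)))
  tibble(step = traj$step,
         category = vapply(seq_len(nrow(traj)), one, character(1)))
}

# ---- smoothing and aggregation -------------------------------------------

#' Sliding-window smoothing
#'
#' Assigns to each step the mean of its centred neighbourhood; the window is
#' clipped at the series ends and missing values are excluded (a window of
#' only missing values stays missing).
#'
#' @param series Numeric vector.
#' @param w Odd window size >= 1.
#' @return Numeric vector of the same length.
#' @export
sliding_window <- function(series, w) {
  if (w < 1 || w %% 2 == 0) abort("window size must be a positive odd count")
  if (w == 1) return(series)
  n <- length(series)
  h <- (w - 1) / 2
  vapply(seq_len(n), function(i) {
    win <- series[max(1, i - h):min(n, i + h)]
    win <- win[!is.na(win)]
    if (length(win) == 0) NA_real_ else mean(win)
  }, numeric(1))
}

#' Aggregate a series into uniform bars
#'
#' Partitions the steps into `n_bins` near-equal half-open index ranges (any
#' remainder spread over the leading bins) and reports the mean of the
#' non-missing values per bin, plus the modal category when one is given
#' (ties broken by the classification priority order).
#'
#' @param series Numeric vector of per-step values.
#' @param n_bins Number of bars (>= 1). When `n_bins` exceeds the number of
#'   steps, the first `length(series)` bins hold one step each and empty
#'   bins are dropped.
#' @param category Optional character vector of per-step categories.
#' @return A tibble with columns `bin`, `start`, `end` (half-open 0-based
#'   step range), `mean` and (when categories are given) `category`.
#' @export
aggregate_bars <- function(series, n_bins, category = NULL) {
  if (n_bins < 1) abort("n_bins must be >= 1")
  n <- length(series)
  n_bins <- min(n_bins, n)
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  ends <- cumsum(sizes)
  starts <- c(0L, ends[-n_bins])
  out <- purrr::map_dfr(seq_len(n_bins), function(b) {
    idx <- (starts[b] + 1):ends[b]
    vals <- series[idx]
    vals <- vals[!is.na(vals)]
    row <- tibble(bin = b - 1L, start = starts[b], end = ends[b],
                  mean = if (length(vals) == 0) NA_real_ else mean(vals))
    if (!is.null(category)) row$category <- modal_category(category[idx])
    row
  })
  out
}

# modal category; ties resolved by classification priority
modal_category <- function(cats) {
  tab <- table(cats)
  winners <- names(tab)[tab == max(tab)]
  ordered <- intersect(.categories, winners)
  if (length(ordered) > 0) ordered[1] else winners[1]
}

# ---- master derivation ----------------------------------------------------

#' Derive all per-step attributes of a ligand trajectory
#'
#' Runs every attribute derivation in one pass over the frames and returns
#' the combined per-time-step attribute table: stuckness (and the raw
#' straightness ratio), distance and direction to the active site, free
#' space (imported tunnel or temporal tunnel), the three closest lining
#' residues, hydrophobicity and charge profiles, speed, residue turnover
#' and the positional category.
#'
#' @param frames Protein [frame_set()].
#' @param ligand The ligand [ligand_trajectory()].
#' @param active_site An [active_site_spec()].
#' @param ligand_atoms Optional `frame_set` of the ligand's atoms; when
#'   absent the reference point with a default carbon radius stands in.
#' @param tunnel Optional imported [tunnel_profile()]; the temporal tunnel
#'   is derived when absent.
#' @param stuck_n Stuckness half-window (default 4 steps).
#' @param lining_k Number of closest lining residues reported (default 3).
#' @param cutoff Lining distance cutoff in Angstrom for the hydrophobicity
#'   and charge profiles (default 2).
#' @param thresholds [category_thresholds()] for the positional category.
#' @param scale Hydrophobicity scale (default [kyte_doolittle()]).
#' @return A tibble of class `attribute_table`, one row per time step.
#' @export
derive_attributes <- function(frames, ligand, active_site,
                              ligand_atoms = NULL, tunnel = NULL,
                              stuck_n = 4, lining_k = 3, cutoff = 2,
                              thresholds = category_thresholds(),
                              scale = kyte_doolittle()) {
  N <- nrow(ligand)
  if (N != frames$n_frames)
    abort("ligand trajectory length and frame count differ")

  stuck <- stuckness_series(ligand, n = stuck_n)
  dist <- distance_series(ligand, frames, active_site)
  direction <- direction_series(dist)
  speed <- speed_series(ligand, dt = frames$dt)
  fs <- free_space_series(ligand, tunnel = tunnel, frames = frames)

  has_charges <- !all(is.na(frames$atoms$charge))
  if (!has_charges)
    inform("no partial charges available; the charge profile is reported as missing")

  groups <- residue_groups(frames)
  p <- traj_matrix(ligand)

  lining_list <- vector("list", N)
  hydro <- numeric(N)
  chg <- rep(NA_real_, N)
  min_surf <- numeric(N)
  contacts <- integer(N)

  for (i in seq_len(N)) {
    xi <- ligand$step[i]
    la <- ligand_atoms_at(ligand_atoms, ligand, xi)
    scan <- frame_scan(frames, la$m, la$r, xi, groups, "surface")
    lining_list[[i]] <- lining_from_scan(scan$residue, groups, xi, lining_k, Inf)
    hydro[i] <- hydrophobicity_from_scan(scan$residue, groups, cutoff, scale)
    if (has_charges) chg[i] <- charge_from_scan(scan$atom, frames$atoms$charge, cutoff)
    min_surf[i] <- min(scan$atom)
    m <- frame_coords(frames, xi)
    contacts[i] <- sum(rowSums(sweep(m, 2, p[i, ])^2) <= thresholds$contact_shell^2)
  }

  category <- vapply(seq_len(N), function(i)
    classify_from_scan(dist$dist_active_site[i], min_surf[i], contacts[i],
                       thresholds), character(1))

  turnover <- integer(N)
  for (i in seq_len(N - 1))
    turnover[i] <- residue_turnover(lining_list[[i]], lining_list[[i + 1]])
  if (N >= 2) turnover[N] <- turnover[N - 1]

  lin_wide <- lining_wide(lining_list, lining_k)

  out <- tibble(
    step = ligand$step,
    time_fs = ligand$step * frames$dt,
    x = p[, 1], y = p[, 2], z = p[, 3],
    straightness = stuck$straightness,
    stuckness = stuck$stuckness,
    frozen = stuck$frozen,
    dist_active_site = dist$dist_active_site,
    direction = direction,
    speed = speed$speed,
    free_space = fs$free_space,
    free_space_source = fs$free_space_source,
    outside_tunnel = fs$outside_tunnel,
    hydrophobicity = hydro,
    charge = chg,
    turnover = turnover,
    category = category
  )
  out <- bind_cols(out, lin_wide)
  structure(out, lining = bind_rows(lining_list),
            class = c("attribute_table", class(tibble())))
}

# wide lining columns: lining_resid_1..k, lining_dist_1..k
lining_wide <- function(lining_list, k) {
  purrr::map_dfr(lining_list, function(l) {
    res <- c(l$residue, rep(NA_character_, k))[1:k]
    dst <- c(l$distance, rep(NA_real_, k))[1:k]
    row <- as.list(setNames(res, paste0("lining_resid_", 1:k)))
    row <- c(row, as.list(setNames(dst, paste0("lining_dist_", 1:k))))
    as_tibble(row)
  })
}

#' Per-step lining table of an attribute table
#'
#' Long-format lining residues (`step`, `rank`, `residue`, `resname`,
#' `distance`) computed alongside [derive_attributes()].
#'
#' @param table An `attribute_table`.
#' @return A tibble.
#' @export
lining_table <- function(table) {
  lin <- attr(table, "lining")
  if (is.null(lin)) abort("this table carries no lining information")
  lin
}
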