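# Core containers.
#
# A frame_set is a topology + coordinates pair, the usual layout of MD
# analysis libraries: per-atom metadata once (atom order is invariant across
# frames) plus one coordinate matrix per frame. Static systems store a single
# matrix shared by all frames. Ligand trajectories and tunnel profiles are
# plain tibbles with a class tag so plot/print methods can dispatch.

#' Construct a frame set
#'
#' Bundles per-atom metadata with per-frame coordinates. Atom count and
#' ordering must be identical in every frame; time steps are indexed 0-based
#' downstream.
#'
#' @param atoms Data frame with one row per atom and columns `name`
#'   (atom name), `element`, `resname` (three-letter code), `resid`
#'   (residue sequence id), `chain`, and optionally `charge` (elementary
#'   charges) and `radius` (vdW radius, Angstrom; filled from the built-in
#'   element table when absent).
#' @param coords A list of n_frames numeric matrices (n_atoms x 3, Angstrom),
#'   or a single matrix for a protein that does not move (`static = TRUE`
#'   is then implied); columns x, y, z.
#' @param dt Time spacing between frames in femtoseconds (default 2).
#' @param n_frames Frame count; required when `coords` is a single static
#'   matrix, otherwise inferred.
#' @return An object of class `frame_set`.
#' @export
frame_set <- function(atoms, coords, dt = 2, n_frames = NULL) {
  atoms <- as_tibble(atoms)
  req <- c("name", "element", "resname", "resid", "chain")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0)
    abort(paste0("atoms is missing column(s): ", paste(missing_cols, collapse = ", ")))
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"radius" %in% names(atoms)) atoms$radius <- vdw_radius(atoms$element)
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    abort("dt must be a single positive number (femtoseconds)")

  static <- is.matrix(coords)
  if (static) {
    if (is.null(n_frames)) abort("n_frames is required for a static coordinate matrix")
    check_coord_matrix(coords, nrow(atoms), "coords")
  } else {
    if (!is.list(coords) || length(coords) == 0)
      abort("coords must be a matrix or a non-empty list of matrices")
    for (i in seq_along(coords))
      check_coord_matrix(coords[[i]], nrow(atoms), paste0("frame ", i - 1))
    if (is.null(n_frames)) n_frames <- length(coords)
    if (n_frames != length(coords))
      abort("n_frames does not match the number of coordinate matrices")
  }

  structure(
    list(atoms = atoms, coords = coords, dt = dt,
         n_frames = as.integer(n_frames), static = static),
    class = "frame_set"
  )
}

check_coord_matrix <- function(m, n_atoms, what) {
  if (!is.matrix(m) || ncol(m) != 3)
    abort(paste0(what, ": coordinates must be an n x 3 matrix"))
  if (nrow(m) != n_atoms)
    abort(paste0(what, ": atom count ", nrow(m), " differs from topology (",
                 n_atoms, ") - inconsistent trajectory"))
  if (!all(is.finite(m)))
    abort(paste0(what, ": non-finite coordinates"))
  invisible(m)
}

#' Number of frames in a frame set
#' @param frames A `frame_set`.
#' @return Integer frame count.
#' @export
n_frames <- function(frames) {
  stopifnot(inherits(frames, "frame_set"))
  frames$n_frames
}

#' Coordinates of one frame
#'
#' @param frames A `frame_set`.
#' @param step 0-based time-step index.
#' @return n_atoms x 3 numeric matrix (Angstrom).
#' @export
frame_coords <- function(frames, step) {
  stopifnot(inherits(frames, "frame_set"))
  step <- as.integer(step)
  if (step < 0 || step >= frames$n_frames)
    abort(paste0("step ", step, " out of range [0, ", frames$n_frames, ")"))
  if (frames$static) frames$coords else frames$coords[[step + 1]]
}

#' @export
print.frame_set <- function(x, ...) {
  cat("<frame_set> ", x$n_frames, " frame(s), ", nrow(x$atoms), " atoms, dt = ",
      x$dt, " fs", if (x$static) " (static coordinates)", "\n", sep = "")
  cat("residues: ", length(unique(residue_keys(x))), "; charges: ",
      if (all(is.na(x$atoms$charge))) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.frame_set <- function(x, ...) {
  frames <- 0:(x$n_frames - 1)
  purrr::map_dfr(frames, function(f) {
    m <- frame_coords(x, f)
    bind_cols(tibble(frame = f), x$atoms,
              tibble(x = m[, 1], y = m[, 2], z = m[, 3]))
  })
}

# "chain:resid" key identifying a residue, stable across frames
residue_keys <- function(frames) {
  paste0(frames$atoms$chain, ":", frames$atoms$resid)
}

#' Construct a ligand trajectory
#'
#' The ordered reference positions of the ligand, one 3D point per time
#' step. This is the object annotated by the attribute derivations and
#' simplified by the multi-scale schemes.
#'
#' @param positions n x 3 numeric matrix or data frame with columns x, y, z.
#' @param steps Integer 0-based time-step indices (default `0:(n-1)`).
#' @param provenance `"raw"` or `"simplified"`.
#' @return A tibble of class `ligand_trajectory` with columns `step`, `x`,
#'   `y`, `z`.
#' @export
ligand_trajectory <- function(positions, steps = NULL, provenance = "raw") {
  if (is.data.frame(positions)) {
    if (!all(c("x", "y", "z") %in% names(positions)))
      abort("positions data frame needs columns x, y, z")
    if (is.null(steps) && "step" %in% names(positions)) steps <- positions$step
    m <- as.matrix(positions[, c("x", "y", "z")])
  } else {
    m <- as.matrix(positions)
    if (ncol(m) != 3) abort("positions must be n x 3")
  }
  if (!all(is.finite(m))) abort("ligand positions must be finite")
  n <- nrow(m)
  if (is.null(steps)) steps <- 0:(n - 1)
  if (length(steps) != n) abort("steps length must match position count")
  out <- tibble(step = as.integer(steps), x = m[, 1], y = m[, 2], z = m[, 3])
  structure(out, provenance = match.arg(provenance, c("raw", "simplified")),
            class = c("ligand_trajectory", class(tibble())))
}

# n x 3 matrix view of a ligand trajectory (or any x/y/z data frame)
traj_matrix <- function(traj) {
  unname(as.matrix(traj[, c("x", "y", "z")]))
}

#' Construct a tunnel profile
#'
#' Per-time-step sphere sets describing the void space available to the
#' ligand, either imported from a tunnel-computation tool (CAVER-style) or
#' derived as the temporal tunnel.
#'
#' @param spheres Data frame with columns `frame` (0-based), `x`, `y`, `z`
#'   (sphere centre, Angstrom) and `r` (radius, Angstrom, non-negative).
#' @param source `"imported"` or `"temporal"`. A temporal profile must have
#'   exactly one sphere per time step.
#' @return A tibble of class `tunnel_profile`.
#' @export
tunnel_profile <- function(spheres, source = c("imported", "temporal")) {
  source <- match.arg(source)
  spheres <- as_tibble(spheres)
  req <- c("frame", "x", "y", "z", "r")
  if (!all(req %in% names(spheres)))
    abort("tunnel spheres need columns frame, x, y, z, r")
  spheres <- spheres[, req]
  if (nrow(spheres) > 0) {
    if (!all(vapply(spheres, is.numeric, logical(1))))
      abort("tunnel sphere columns must be numeric")
    if (any(!is.finite(as.matrix(spheres))))
      abort("tunnel spheres contain non-finite values")
    if (any(spheres$r < 0)) abort("tunnel sphere radii must be non-negative")
    if (source == "temporal" && anyDuplicated(spheres$frame) > 0)
      abort("a temporal tunnel has exactly one sphere per time step")
  }
  spheres$frame <- as.integer(spheres$frame)
  structure(arrange(spheres, frame),
            source = source,
            class = c("tunnel_profile", class(tibble())))
}

#' Construct an active-site specification
#'
#' The active site is defined by a set of residues; its per-frame position
#' is the centre of mass of all their atoms (see
#' [active_site_position()]).
#'
#' @param residues Data frame with columns `chain` and `resid`.
#' @return A tibble of class `active_site_spec`.
#' @export
active_site_spec <- function(residues) {
  residues <- as_tibble(residues)
  if (!all(c("chain", "resid") %in% names(residues)))
    abort("active-site residues need columns chain, resid")
  if (nrow(residues) == 0) abort("active site needs at least one residue")
  residues <- residues[, c("chain", "resid")]
  residues$chain <- as.character(residues$chain)
  residues$resid <- as.integer(residues$resid)
  structure(dplyr::distinct(residues),
            class = c("active_site_spec", class(tibble())))
}

# check that every active-site residue resolves in the frame set
resolve_active_site <- function(frames, spec) {
  keys <- residue_keys(frames)
  want <- paste0(spec$chain, ":", spec$resid)
  missing <- setdiff(want, unique(keys))
  if (length(missing) > 0)
    abort(paste0("active-site residue(s) not found in structure: ",
                 paste(missing, collapse = ", ")))
  which(keys %in% want)
}
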