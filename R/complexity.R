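# Local trajectory complexity.
#
# Both measures are evaluated in an arc-length neighbourhood of each vertex:
# the neighbourhood of x contains all vertices y whose distance *along* the
# polyline to x is below nu. A segment belongs to the neighbourhood when both
# of its endpoints do; a tuple (u, v) of consecutive segments belongs when
# both segments do.
#
# The smoothing measure sums (|u| + |v|)^2 * alpha(u, v) over consecutive
# segment tuples in the neighbourhood, with alpha the angle (radians) between
# the segment directions; a straight polyline therefore scores exactly 0 and
# the units are rad * A^2. The vertex-preserving (Douglas-Peucker) measure is
# the path-length / chord-length ratio of the neighbourhood, dimensionless
# and >= 1 wherever the chord is non-degenerate.

#' Trajectory complexity (smoothing measure)
#'
#' For every vertex x, sums `(|u| + |v|)^2 * alpha(u, v)` over all pairs of
#' consecutive segments (u, v) lying entirely within the arc-length
#' neighbourhood of radius `nu` around x, where `alpha` is the angle between
#' the segment directions in radians. Vertices whose neighbourhood holds
#' fewer than two segments score 0.
#'
#' @param traj A [ligand_trajectory()] or data frame with x, y, z (>= 3 points).
#' @param nu Neighbourhood radius in Angstrom of arc length (default 2).
#' @return A tibble of class `complexity_profile` with columns `step`,
#'   `complexity` and `degenerate` (always `FALSE` for this measure);
#'   attributes `measure = "angular"` and `nu`.
#' @examples
#' elbow <- ligand_trajectory(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
#' complexity(elbow, nu = 10)$complexity[2]  # 2 * pi
#' @export
complexity <- function(traj, nu = 2) {
  geom <- complexity_geometry(traj, nu)
  n <- geom$n

  # per-junction tuple value: junction j sits between segments j and j+1
  # (1-based); value = (|u| + |v|)^2 * angle
  tuple_val <- if (n >= 3) {
    (geom$seg_len[-(n - 1)] + geom$seg_len[-1])^2 * geom$angles
  } else {
    numeric(0)
  }
  tuple_cum <- c(0, cumsum(tuple_val))

  val <- vapply(seq_len(n), function(i) {
    lo <- geom$lo[i]; hi <- geom$hi[i]
    # segments lo..(hi-1) are inside; tuples (junctions) lo..(hi-2)
    first <- lo; last <- hi - 2
    if (last < first) return(0)
    tuple_cum[last + 1] - tuple_cum[first]
  }, numeric(1))

  new_complexity_profile(profile_steps(traj, n), val,
                         degenerate = rep(FALSE, n),
                         measure = "angular", nu = nu)
}

#' Trajectory complexity (vertex-preserving measure)
#'
#' For every vertex x, the ratio of the summed segment lengths inside the
#' arc-length neighbourhood of radius `nu` to the straight-line distance
#' between the first and last vertex of that neighbourhood. The ratio is 1
#' on straight polylines and at least 1 wherever the chord is
#' non-degenerate; a chord shorter than 1e-9 A (a closed sub-loop) yields
#' the sentinel value 1e6 with `degenerate = TRUE`.
#'
#' @inheritParams complexity
#' @return A tibble of class `complexity_profile` with attributes
#'   `measure = "path_chord"` and `nu`.
#' @examples
#' elbow <- ligand_trajectory(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
#' complexity_dp(elbow, nu = 10)$complexity[2]  # sqrt(2)
#' @export
complexity_dp <- function(traj, nu = 2) {
  geom <- complexity_geometry(traj, nu)
  n <- geom$n
  m <- geom$m
  sentinel <- 1e6

  val <- numeric(n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    lo <- geom$lo[i]; hi <- geom$hi[i]
    if (hi <= lo) {            # no segment in the neighbourhood
      val[i] <- 1
      next
    }
    path <- geom$arc[hi] - geom$arc[lo]
    chord <- sqrt(sum((m[hi, ] - m[lo, ])^2))
    if (chord < 1e-9) {
      val[i] <- sentinel
      degen[i] <- TRUE
    } else {
      val[i] <- path / chord
    }
  }

  new_complexity_profile(profile_steps(traj, n), val, degenerate = degen,
                         measure = "path_chord", nu = nu)
}

profile_steps <- function(traj, n) {
  if (is.data.frame(traj) && "step" %in% names(traj)) traj$step else 0:(n - 1)
}

# shared geometry: segment lengths, junction angles, arc lengths and the
# neighbourhood vertex range [lo, hi] (1-based inclusive) of every vertex
complexity_geometry <- function(traj, nu) {
  if (is.data.frame(traj)) {
    m <- as.matrix(traj[, c("x", "y", "z")])
  } else {
    m <- as.matrix(traj)
  }
  n <- nrow(m)
  if (n < 3) abort("complexity needs a trajectory of at least 3 points")
  if (!is.numeric(nu) || length(nu) != 1 || !is.finite(nu) || nu <= 0)
    abort("nu must be a single positive length (Angstrom)")

  seg <- m[-1, , drop = FALSE] - m[-n, , drop = FALSE]
  seg_len <- sqrt(rowSums(seg^2))
  arc <- c(0, cumsum(seg_len))

  angles <- if (n >= 3) segment_angles(seg, seg_len) else numeric(0)

  # two-pointer sweep: vertices j with |arc[j] - arc[i]| < nu
  lo <- integer(n); hi <- integer(n)
  l <- 1; h <- 1
  for (i in seq_len(n)) {
    while (arc[i] - arc[l] >= nu) l <- l + 1
    if (h < i) h <- i
    while (h < n && arc[h + 1] - arc[i] < nu) h <- h + 1
    lo[i] <- l; hi[i] <- h
  }

  list(m = m, n = n, seg_len = seg_len, arc = arc, angles = angles,
       lo = lo, hi = hi)
}

# angle between consecutive segment directions, radians; zero-length
# segments have no direction and contribute angle 0
segment_angles <- function(seg, seg_len) {
  ns <- nrow(seg)
  u <- seg[-ns, , drop = FALSE]
  v <- seg[-1, , drop = FALSE]
  lu <- seg_len[-ns]
  lv <- seg_len[-1]
  dot <- rowSums(u * v)
  denom <- lu * lv
  cosa <- ifelse(denom < 1e-24, 1, pmin(1, pmax(-1, dot / denom)))
  acos(cosa)
}

new_complexity_profile <- function(steps, value, degenerate, measure, nu) {
  structure(
    tibble(step = as.integer(steps), complexity = value, degenerate = degenerate),
    measure = measure, nu = nu,
    class = c("complexity_profile", class(tibble()))
  )
}

#' @export
autoplot.complexity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = step, y = .data$complexity)) +
    ggplot2::geom_line(colour = "#3465a4") +
    ggplot2::labs(
      x = "time step",
      y = if (identical(attr(object, "measure"), "angular"))
        "complexity c(x) [rad Å²]" else "complexity c_DP(x)",
      title = paste0("Trajectory complexity (ν = ", attr(object, "nu"), " Å)")
    ) +
    ggplot2::theme_minimal()
}
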