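# Multi-scale trajectory simplification.
#
# A simplification state is a contiguous, non-overlapping partition of the
# time-step range [0, N) into half-open intervals, each carrying a
# non-negative integer simplification level (0 = raw; adjacent intervals with
# equal level are merged). Two back ends realise a level:
#
#   * smoothing: level k applies k successive Savitzky-Golay passes (fixed
#     window/order) to the interval's raw points, first and last point of the
#     interval pinned so the global polyline stays continuous. Output point
#     count equals input point count.
#   * non-smoothing (vertex-preserving): level k runs Douglas-Peucker on the
#     interval's raw points with tolerance base * 2^(k-1); the output is a
#     subset of the input vertices.
#
# The canonical ("from scratch") materialisation applies each interval's
# level to the raw points of that interval independently; it is a pure
# function of (raw trajectory, state). The interactive scheme keeps the last
# materialised trajectory in a cache and updates it incrementally when that
# is exactly equivalent to the canonical result (see simplify_interactive).

# ---- Savitzky-Golay back end -------------------------------------------

#' Savitzky-Golay smoothing of a 3D point segment
#'
#' Per-coordinate Savitzky-Golay filtering with the first and last point of
#' the segment returned unchanged, so neighbouring intervals stay connected.
#' Segments shorter than the window shrink it to the largest valid odd size;
#' segments shorter than 3 points are returned unchanged.
#'
#' @param points n x 3 numeric matrix (or data frame with x, y, z).
#' @param window Odd window length (> `order`), default 9.
#' @param order Polynomial order, default 2.
#' @return n x 3 numeric matrix.
#' @export
smooth_segment <- function(points, window = 9, order = 2) {
  m <- segment_matrix(points)
  n <- nrow(m)
  if (window < 1 || window %% 2 == 0) abort("window must be a positive odd count")
  if (order < 0 || window <= order) abort("window must exceed the polynomial order")
  w <- min(window, n)
  if (w %% 2 == 0) w <- w - 1
  if (w < 3) return(m)
  p <- min(order, w - 1)
  out <- apply(m, 2, function(col) signal::sgolayfilt(col, p = p, n = w))
  out[1, ] <- m[1, ]
  out[n, ] <- m[n, ]
  out
}

# ---- Douglas-Peucker back end ------------------------------------------

#' Douglas-Peucker decimation of a 3D point segment
#'
#' Classic Douglas-Peucker with point-to-segment distance: output vertices
#' are a subset of the input including both endpoints, and every discarded
#' vertex lies within `tolerance` of the output polyline.
#'
#' @param points n x 3 numeric matrix (>= 2 points) or data frame with x, y, z.
#' @param tolerance Maximum allowed deviation in Angstrom (>= 0).
#' @return A list with `points` (kept vertices, matrix) and `kept` (1-based
#'   indices of the kept input vertices, increasing).
#' @export
decimate_segment <- function(points, tolerance) {
  m <- segment_matrix(points)
  n <- nrow(m)
  if (n < 2) abort("decimation needs at least 2 points")
  if (!is.numeric(tolerance) || length(tolerance) != 1 || tolerance < 0)
    abort("tolerance must be a single non-negative length")
  kept <- douglas_peucker_idx(m, tolerance)
  list(points = m[kept, , drop = FALSE], kept = kept)
}

# iterative (stack-based) DP returning kept 1-based indices
douglas_peucker_idx <- function(m, tol) {
  n <- nrow(m)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack) > 0) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- rng[1]; b <- rng[2]
    if (b - a < 2) next
    idx <- (a + 1):(b - 1)
    d <- point_segment_distance(m[idx, , drop = FALSE], m[a, ], m[b, ])
    j <- which.max(d)
    if (d[j] > tol) {
      split <- idx[j]
      keep[split] <- TRUE
      stack[[length(stack) + 1]] <- c(a, split)
      stack[[length(stack) + 1]] <- c(split, b)
    }
  }
  which(keep)
}

# distance from each row of p (k x 3) to the segment [a, b]
point_segment_distance <- function(p, a, b) {
  p <- matrix(p, ncol = 3)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-24) {
    return(sqrt(rowSums(sweep(p, 2, a)^2)))
  }
  t <- pmin(1, pmax(0, (sweep(p, 2, a) %*% ab) / len2))
  proj <- sweep(t %*% t(ab), 2, a, "+")
  sqrt(rowSums((p - proj)^2))
}

segment_matrix <- function(points) {
  if (is.data.frame(points)) {
    as.matrix(points[, c("x", "y", "z")])
  } else {
    m <- as.matrix(points)
    if (ncol(m) != 3) abort("points must be n x 3")
    m
  }
}

# ---- simplification state ----------------------------------------------

state_new <- function(n) {
  tibble(start = 0L, end = as.integer(n), level = 0L)
}

# overlay one (start, end, level) interval onto a state, then merge
state_apply <- function(state, new_start, new_end, new_level) {
  new_start <- as.integer(new_start)
  new_end <- as.integer(new_end)
  new_level <- as.integer(new_level)
  pieces <- list()
  for (i in seq_len(nrow(state))) {
    a <- state$start[i]; b <- state$end[i]; lvl <- state$level[i]
    if (a < min(b, new_start))
      pieces[[length(pieces) + 1]] <-
        tibble(start = a, end = min(b, new_start), level = lvl)
    if (max(a, new_end) < b)
      pieces[[length(pieces) + 1]] <-
        tibble(start = max(a, new_end), end = b, level = lvl)
  }
  pieces[[length(pieces) + 1]] <-
    tibble(start = new_start, end = new_end, level = new_level)
  state_merge(arrange(bind_rows(pieces), start))
}

# merge adjacent intervals with equal level
state_merge <- function(state) {
  if (nrow(state) <= 1) return(state)
  grp <- cumsum(c(TRUE, state$level[-1] != state$level[-nrow(state)]))
  state |>
    mutate(.grp = grp) |>
    group_by(.data$.grp) |>
    summarise(start = min(start), end = max(end), level = level[1],
              .groups = "drop") |>
    select(start, end, level)
}

# per-step level vector (length N) implied by a state
state_levels <- function(state) {
  n <- max(state$end)
  lv <- integer(n)
  for (i in seq_len(nrow(state))) {
    if (state$end[i] > state$start[i])
      lv[(state$start[i] + 1):state$end[i]] <- state$level[i]
  }
  lv
}

validate_state <- function(state, n) {
  if (!all(c("start", "end", "level") %in% names(state)))
    abort("a simplification state needs columns start, end, level")
  state <- arrange(as_tibble(state), start)
  if (nrow(state) == 0 || state$start[1] != 0 || state$end[nrow(state)] != n ||
      any(state$start[-1] != state$end[-nrow(state)]) ||
      any(state$end <= state$start) || any(state$level < 0))
    abort("simplification state must be a contiguous partition of [0, N) with levels >= 0")
  state_merge(mutate(state, start = as.integer(start), end = as.integer(end),
                     level = as.integer(level)))
}

# ---- canonical materialisation -----------------------------------------

#' Materialise a simplification state
#'
#' Applies a simplification state to a raw trajectory from scratch: every
#' interval's level is realised on the interval's raw points independently
#' (Savitzky-Golay passes with pinned endpoints for the smoothing back end;
#' Douglas-Peucker at the level-mapped tolerance for the vertex-preserving
#' back end). This is the canonical result that the interactive scheme's
#' incremental path must reproduce exactly.
#'
#' @param traj_in Raw [ligand_trajectory()].
#' @param state Simplification state: tibble with `start`, `end` (half-open,
#'   0-based) and `level` columns partitioning `[0, N)`.
#' @param backend `"smooth"` or `"dp"`.
#' @param window,order Savitzky-Golay parameters (smoothing back end).
#' @param dp_base Base tolerance in Angstrom; level k uses
#'   `dp_base * 2^(k-1)` (vertex-preserving back end).
#' @return A [ligand_trajectory()] with provenance `"simplified"`. For the
#'   smoothing back end its length equals the input length; for the
#'   vertex-preserving back end it is the kept subset of input vertices.
#' @export
apply_simplification <- function(traj_in, state, backend = c("smooth", "dp"),
                                 window = 9, order = 2, dp_base = 0.5) {
  backend <- match.arg(backend)
  n <- nrow(traj_in)
  state <- validate_state(state, n)
  m <- traj_matrix(traj_in)

  if (backend == "smooth") {
    out <- m
    for (i in seq_len(nrow(state))) {
      k <- state$level[i]
      if (k == 0) next
      rows <- (state$start[i] + 1):state$end[i]
      seg <- m[rows, , drop = FALSE]
      for (pass in seq_len(k)) seg <- smooth_segment(seg, window, order)
      out[rows, ] <- seg
    }
    ligand_trajectory(out, steps = traj_in$step, provenance = "simplified")
  } else {
    kept <- integer(0)
    for (i in seq_len(nrow(state))) {
      rows <- (state$start[i] + 1):state$end[i]
      k <- state$level[i]
      if (k == 0 || length(rows) < 2) {
        kept <- c(kept, rows)
      } else {
        dp <- decimate_segment(m[rows, , drop = FALSE], dp_level_tol(dp_base, k))
        kept <- c(kept, rows[dp$kept])
      }
    }
    kept <- sort(unique(kept))
    ligand_trajectory(m[kept, , drop = FALSE], steps = traj_in$step[kept],
                      provenance = "simplified")
  }
}

dp_level_tol <- function(base, level) base * 2^(level - 1)

# ---- cache ---------------------------------------------------------------

#' Create a simplification cache
#'
#' Holds the last materialised trajectory and its state so repeated edits of
#' the same interval can be updated incrementally instead of recomputed.
#'
#' @return An environment of class `simplify_cache`.
#' @export
new_simplify_cache <- function() {
  structure(new.env(parent = emptyenv()), class = "simplify_cache")
}

cache_key <- function(traj_in, backend, window, order, dp_base) {
  hash(list(traj_matrix(traj_in), backend, window, order, dp_base))
}

# ---- interactive scheme --------------------------------------------------

#' Interactive per-interval simplification
#'
#' Updates the simplification state with one `[start, end)` interval set to
#' `level` and materialises the result. When a cache from a previous call is
#' supplied and the edit raises the level of exactly one cached state
#' interval (the typical "simplify the same part again" interaction), the
#' cached trajectory is updated incrementally; the incremental result is
#' identical to the canonical from-scratch materialisation. In all other
#' cases (lowering a level, partial overlaps, merges) the result is
#' recomputed from the raw trajectory.
#'
#' @param traj_in Raw [ligand_trajectory()].
#' @param start,end Half-open 0-based step interval, `0 <= start < end <= N`.
#' @param level Target simplification level (>= 0).
#' @param cache Optional [new_simplify_cache()]; updated in place. `NULL`
#'   always recomputes from scratch.
#' @inheritParams apply_simplification
#' @return An object of class `ligand_simplification`: a list with
#'   `trajectory`, `state`, `incremental` (logical), `backend` and `params`.
#' @export
simplify_interactive <- function(traj_in, start, end, level, cache = NULL,
                                 backend = c("smooth", "dp"),
                                 window = 9, order = 2, dp_base = 0.5) {
  backend <- match.arg(backend)
  n <- nrow(traj_in)
  if (!is.numeric(start) || !is.numeric(end) || start < 0 || end > n || start >= end)
    abort(paste0("interval [", start, ", ", end, ") out of bounds for ", n, " steps"))
  if (!is.numeric(level) || level < 0) abort("level must be a non-negative integer")
  level <- as.integer(level)

  key <- cache_key(traj_in, backend, window, order, dp_base)
  have_cache <- !is.null(cache) && identical(cache$key, key) && !is.null(cache$state)
  prior_state <- if (have_cache) cache$state else state_new(n)
  new_state <- state_apply(prior_state, start, end, level)

  incremental <- FALSE
  traj_out <- NULL

  if (have_cache) {
    prior_row <- which(prior_state$start == start & prior_state$end == end)
    new_row <- which(new_state$start == start & new_state$end == end &
                       new_state$level == level)
    aligned <- length(prior_row) == 1 && length(new_row) == 1
    if (aligned) {
      j <- prior_state$level[prior_row]
      if (backend == "smooth" && j <= level) {
        # apply the missing passes to the cached points of the interval
        incremental <- TRUE
        m <- traj_matrix(cache$traj)
        rows <- (start + 1):end
        seg <- m[rows, , drop = FALSE]
        for (pass in seq_len(level - j)) seg <- smooth_segment(seg, window, order)
        m[rows, ] <- seg
        traj_out <- ligand_trajectory(m, steps = traj_in$step,
                                      provenance = "simplified")
      } else if (backend == "dp" && j >= 1 && j <= level) {
        # re-run DP on the cached kept vertices with the larger tolerance:
        # output stays a subset of the original vertices
        incremental <- TRUE
        cached_steps <- cache$traj$step
        inside <- cached_steps >= start & cached_steps < end
        if (sum(inside) >= 2 && level > j) {
          seg <- traj_matrix(cache$traj)[inside, , drop = FALSE]
          dp <- decimate_segment(seg, dp_level_tol(dp_base, level))
          keep_steps <- sort(c(cached_steps[!inside], cached_steps[inside][dp$kept]))
        } else {
          keep_steps <- cached_steps
        }
        raw_m <- traj_matrix(traj_in)
        idx <- match(keep_steps, traj_in$step)
        traj_out <- ligand_trajectory(raw_m[idx, , drop = FALSE],
                                      steps = keep_steps,
                                      provenance = "simplified")
      }
    }
  }

  if (is.null(traj_out)) {
    traj_out <- apply_simplification(traj_in, new_state, backend,
                                     window, order, dp_base)
  }

  if (!is.null(cache)) {
    cache$key <- key
    cache$state <- new_state
    cache$traj <- traj_out
  }

  new_ligand_simplification(
    trajectory = traj_out, state = new_state, backend = backend,
    params = list(window = window, order = order, dp_base = dp_base),
    incremental = incremental
  )
}

# ---- automatic scheme ----------------------------------------------------

#' Automatic multi-scale simplification
#'
#' Iteratively simplifies only the parts of the trajectory that are still
#' complex. Starting from the whole range as one complex interval, each
#' iteration (i) evaluates the local complexity of the current trajectory,
#' (ii) marks vertices with complexity below `tau` as simple and removes
#' them from the complex set (splitting intervals; removed points are never
#' re-added), (iii) raises the simplification level of every remaining
#' complex interval by one and re-materialises, and (iv) stops when the
#' complex set is empty, the total-complexity improvement falls below
#' `eps`, or the iteration cap is hit (returning the best result so far
#' with a warning flag in the trace).
#'
#' @param traj_in Raw [ligand_trajectory()] (>= 3 points).
#' @param tau Complexity threshold below which a vertex counts as simple.
#'   Default 1.0 rad A^2 for the smoothing measure, 1.2 (path/chord ratio)
#'   for the vertex-preserving measure.
#' @param eps Absolute improvement threshold; by default
#'   `eps_frac * initial total complexity`.
#' @param eps_frac Fraction of the initial total complexity used for `eps`
#'   when `eps` is not given (default 0.01).
#' @param nu Complexity neighbourhood radius in Angstrom (default 2).
#' @param max_iter Iteration cap (default 50).
#' @inheritParams apply_simplification
#' @return An object of class `ligand_simplification` with elements
#'   `trajectory`, `state`, `trace` (per-iteration tibble), `converged`,
#'   `initial_complexity` and `final_complexity`. Use [generics::tidy()] for
#'   the trace and [generics::glance()] for a one-row summary.
#' @export
simplify_auto <- function(traj_in, tau = NULL, eps = NULL, eps_frac = 0.01,
                          nu = 2, backend = c("smooth", "dp"),
                          window = 9, order = 2, dp_base = 0.5,
                          max_iter = 50) {
  backend <- match.arg(backend)
  if (nrow(traj_in) < 3) abort("automatic simplification needs >= 3 points")
  if (is.null(tau)) tau <- if (backend == "smooth") 1.0 else 1.2
  if (tau <= 0) abort("tau must be positive")
  if (eps_frac <= 0) abort("eps_frac must be positive")
  if (!is.null(eps) && eps <= 0) abort("eps must be positive")
  measure <- if (backend == "smooth") complexity else complexity_dp

  n <- nrow(traj_in)
  state <- state_new(n)
  tout <- traj_in
  C <- tibble(start = 0L, end = as.integer(n), level = 0L)

  prof <- measure(tout, nu)
  total <- sum(prof$complexity)
  initial_total <- total
  if (is.null(eps)) eps <- max(eps_frac * initial_total, .Machine$double.eps)

  trace <- list(tibble(iteration = 0L, n_complex_intervals = nrow(C),
                       n_complex_steps = sum(C$end - C$start),
                       n_simple_removed = 0L,
                       total_complexity = total, delta = NA_real_))
  converged <- FALSE
  hit_cap <- FALSE
  iter <- 0L

  repeat {
    simple_steps <- prof$step[prof$complexity < tau]
    n_before <- sum(C$end - C$start)
    C <- intervals_subtract(C, simple_steps)
    n_removed <- n_before - sum(C$end - C$start)

    if (nrow(C) == 0) { converged <- TRUE; break }
    if (iter >= max_iter) { hit_cap <- TRUE; break }
    iter <- iter + 1L
    C$level <- C$level + 1L
    for (i in seq_len(nrow(C)))
      state <- state_apply(state, C$start[i], C$end[i], C$level[i])

    tout <- apply_simplification(traj_in, state, backend, window, order, dp_base)
    if (nrow(tout) < 3) {
      delta <- total
      total <- 0
      trace[[length(trace) + 1]] <- tibble(
        iteration = iter, n_complex_intervals = nrow(C),
        n_complex_steps = sum(C$end - C$start),
        n_simple_removed = as.integer(n_removed),
        total_complexity = total, delta = delta)
      converged <- TRUE
      break
    }
    prof <- measure(tout, nu)
    new_total <- sum(prof$complexity)
    delta <- total - new_total
    trace[[length(trace) + 1]] <- tibble(
      iteration = iter, n_complex_intervals = nrow(C),
      n_complex_steps = sum(C$end - C$start),
      n_simple_removed = as.integer(n_removed),
      total_complexity = new_total, delta = delta)
    total <- new_total
    if (delta < eps) { converged <- TRUE; break }
  }

  if (hit_cap)
    warn(paste0("automatic simplification hit the iteration cap (", max_iter,
                ") before converging; returning best so far"))

  new_ligand_simplification(
    trajectory = tout, state = state, backend = backend,
    params = list(window = window, order = order, dp_base = dp_base,
                  tau = tau, eps = eps, nu = nu, max_iter = max_iter),
    trace = bind_rows(trace), converged = converged, hit_cap = hit_cap,
    initial_complexity = initial_total, final_complexity = total
  )
}

# remove single steps from a set of half-open intervals, splitting them
intervals_subtract <- function(intervals, steps) {
  if (length(steps) == 0 || nrow(intervals) == 0) return(intervals)
  steps <- sort(unique(as.integer(steps)))
  out <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    a <- intervals$start[i]; b <- intervals$end[i]; lvl <- intervals$level[i]
    inside <- steps[steps >= a & steps < b]
    if (length(inside) == 0) {
      out[[i]] <- intervals[i, ]
      next
    }
    remaining <- setdiff(a:(b - 1), inside)
    if (length(remaining) == 0) {
      out[[i]] <- intervals[0, ]
      next
    }
    run_id <- cumsum(c(1L, diff(remaining) != 1L))
    out[[i]] <- tibble(
      start = as.integer(tapply(remaining, run_id, min)),
      end = as.integer(tapply(remaining, run_id, max)) + 1L,
      level = lvl
    )
  }
  bind_rows(out)
}

# ---- result object -------------------------------------------------------

new_ligand_simplification <- function(trajectory, state, backend, params,
                                      incremental = NA, trace = NULL,
                                      converged = NA, hit_cap = NA,
                                      initial_complexity = NA_real_,
                                      final_complexity = NA_real_) {
  structure(
    list(trajectory = trajectory, state = state, backend = backend,
         params = params, incremental = incremental, trace = trace,
         converged = converged, hit_cap = hit_cap,
         initial_complexity = initial_complexity,
         final_complexity = final_complexity),
    class = "ligand_simplification"
  )
}

#' @export
print.ligand_simplification <- function(x, ...) {
  cat("<ligand_simplification> backend:", x$backend, "\n")
  cat("  trajectory:", nrow(x$trajectory), "points; state intervals:",
      nrow(x$state), "(max level ", max(x$state$level), ")\n")
  if (!is.null(x$trace)) {
    cat("  auto: ", max(x$trace$iteration), " iteration(s), complexity ",
        signif(x$initial_complexity, 6), " -> ", signif(x$final_complexity, 6),
        if (isTRUE(x$converged)) ", converged" else ", NOT converged", "\n",
        sep = "")
  } else if (!is.na(x$incremental)) {
    cat("  interactive update (", if (x$incremental) "incremental" else
      "from scratch", ")\n", sep = "")
  }
  invisible(x)
}

#' Serialise a simplification result to JSON
#'
#' Writes the state intervals, back-end parameters and (for the automatic
#' scheme) the iteration trace.
#'
#' @param x A `ligand_simplification`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_simplification_state <- function(x, path) {
  payload <- list(
    backend = x$backend, params = x$params,
    state = x$state,
    converged = x$converged, hit_cap = x$hit_cap,
    initial_complexity = x$initial_complexity,
    final_complexity = x$final_complexity
  )
  if (!is.null(x$trace)) payload$trace <- x$trace
  jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}
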