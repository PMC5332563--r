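#' Tracking parameters
#'
#' @param d_max maximum centre displacement (pixels) for which two detections
#'   in consecutive frames may be associated; larger distances are forbidden.
#' @param lambda_s weight of the relative area-difference term in the
#'   association cost.
#' @param lambda_b scale of the appearance/disappearance cost.
#' @param d_cap distance scale over which the appearance cost grows away from
#'   the frame border.
#' @param k number of nearest assigned neighbours used to estimate the local
#'   collective displacement.
#' @param mu depth of the neighbourhood-preserving cost reduction; `NULL`
#'   (default) uses `0.5 * median` of the finite association costs.
#' @param sigma length scale (pixels) of agreement with the neighbourhood
#'   displacement.
#' @param T_iter maximum number of solve/adjust iterations.
#' @return A `track_params` list.
#' @export
track_params <- function(d_max = 40, lambda_s = 1, lambda_b = 0.3,
                         d_cap = 100, k = 4L, mu = NULL, sigma = 5,
                         T_iter = 5L) {
  stopifnot(d_max > 0, d_cap > 0, sigma > 0, k >= 1, T_iter >= 1)
  structure(
    list(d_max = d_max, lambda_s = lambda_s, lambda_b = lambda_b,
         d_cap = d_cap, k = as.integer(k), mu = mu, sigma = sigma,
         T_iter = as.integer(T_iter)),
    class = "track_params"
  )
}

# Distance of 0-based (x, y) centres to the nearest frame border.
border_distance <- function(x, y, frame_shape) {
  pmin(x, y, frame_shape[2] - 1 - x, frame_shape[1] - 1 - y)
}

#' Build the frame-to-frame cost matrix
#'
#' Association cost between detection `i` of frame A and `j` of frame B is
#' `d(c_i, c_j)/d_max + lambda_s * |A_i - A_j| / (A_i + A_j)`, forbidden
#' (`Inf`) beyond `d_max`. The cost of letting a detection appear or
#' disappear is `lambda_b * (1 + border_dist/d_cap)`: cells near the frame
#' border come and go cheaply, interior appearance is expensive.
#'
#' @param A,B detections tibbles (columns `x`, `y`, `area`) for two
#'   consecutive frames; either may be empty.
#' @param frame_shape `(height, width)` shared by both frames.
#' @param params a [track_params()].
#' @return An object of class `cost_matrix`: list with `assoc` (M_A x M_B),
#'   `appear` (length M_B), `disappear` (length M_A).
#' @export
build_cost_matrix <- function(A, B, frame_shape, params = track_params()) {
  ca <- cbind(A$x, A$y)
  cb <- cbind(B$x, B$y)
  d <- dist_xy(ca, cb)
  assoc <- d / params$d_max
  if (length(assoc)) {
    if (all(c("area" %in% names(A), "area" %in% names(B)))) {
      ssum <- outer(A$area, B$area, "+")
      sdiff <- abs(outer(A$area, B$area, "-"))
      assoc <- assoc + params$lambda_s * ifelse(ssum > 0, sdiff / ssum, 0)
    }
    assoc[d > params$d_max] <- Inf
  }
  structure(
    list(
      assoc = assoc,
      appear = params$lambda_b *
        (1 + border_distance(B$x, B$y, frame_shape) / params$d_cap),
      disappear = params$lambda_b *
        (1 + border_distance(A$x, A$y, frame_shape) / params$d_cap)
    ),
    class = "cost_matrix"
  )
}

# Jonker-Volgenant style shortest augmenting path solver for the square
# linear assignment problem. Deterministic; scans rows/columns in index
# order, so equal-cost optima resolve to the lexicographically first pairing
# found. `Inf` entries are replaced by a large finite sentinel.
hungarian_lap <- function(cost) {
  n <- nrow(cost)
  if (n == 0) {
    return(integer(0))
  }
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) (max(abs(finite)) + 1) * (n + 1) else 1
  cost[!is.finite(cost)] <- big
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L                   # columns are offset by 1 (index 1 = virtual)
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0 + 1] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j] + 1] <- u[p[j] + 1] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match_col <- integer(n)      # row -> column
  for (j in 2:(n + 1)) {
    if (p[j] > 0) match_col[p[j]] <- j - 1L
  }
  match_col
}

new_assignment <- function(pairs, appearing, disappearing, cost) {
  structure(
    list(pairs = pairs, appearing = appearing, disappearing = disappearing,
         cost = cost),
    class = "assignment"
  )
}

#' Solve the frame-to-frame assignment problem
#'
#' Embeds the cost matrix into the standard augmented square form — the
#' association block, appearance and disappearance costs on the diagonals of
#' the off blocks, and a zero dummy-dummy block — and solves it exactly with
#' the Hungarian algorithm.
#'
#' @param C a [build_cost_matrix()] result.
#' @return An object of class `assignment`: `pairs` (2-column matrix of
#'   row/column indices into A and B), `appearing` (indices into B),
#'   `disappearing` (indices into A) and the optimal `cost`.
#' @export
solve_assignment <- function(C) {
  ma <- length(C$disappear)
  mb <- length(C$appear)
  n <- ma + mb
  if (n == 0) {
    return(new_assignment(matrix(integer(0), 0, 2), integer(0), integer(0),
                          0))
  }
  aug <- matrix(Inf, n, n)
  if (ma > 0 && mb > 0) {
    aug[seq_len(ma), seq_len(mb)] <- C$assoc
  }
  for (i in seq_len(ma)) aug[i, mb + i] <- C$disappear[i]
  for (j in seq_len(mb)) aug[ma + j, j] <- C$appear[j]
  if (ma > 0 && mb > 0) {
    aug[(ma + 1):n, (mb + 1):n] <- 0
  }
  mc <- hungarian_lap(aug)
  pairs <- NULL
  appearing <- integer(0)
  disappearing <- integer(0)
  total <- 0
  for (i in seq_len(ma)) {
    j <- mc[i]
    if (j <= mb && is.finite(C$assoc[i, j])) {
      pairs <- rbind(pairs, c(i, j))
      total <- total + C$assoc[i, j]
    } else {
      disappearing <- c(disappearing, i)
      total <- total + C$disappear[i]
    }
  }
  if (mb > 0) {
    paired_b <- if (is.null(pairs)) integer(0) else pairs[, 2]
    appearing <- setdiff(seq_len(mb), paired_b)
    total <- total + sum(C$appear[appearing])
  }
  if (is.null(pairs)) {
    pairs <- matrix(integer(0), 0, 2)
  }
  colnames(pairs) <- c("a", "b")
  new_assignment(pairs, appearing, disappearing, total)
}

#' Lower costs of neighbourhood-preserving assignments
#'
#' Given a provisional assignment, each detection's expected displacement is
#' the mean displacement of its `k` nearest assigned neighbours; candidate
#' associations whose displacement agrees with that local collective motion
#' get their cost reduced by `mu * exp(-|v_ij - v_bar_i| / sigma)`, clamped
#' at zero. Forbidden entries stay forbidden; detections with no assigned
#' neighbours keep their row unchanged.
#'
#' @param C the original [build_cost_matrix()] result.
#' @param A0 an [solve_assignment()] result on `C`.
#' @param dets_A,dets_B the two detections tibbles.
#' @param params a [track_params()].
#' @return An adjusted `cost_matrix`.
#' @export
neighbourhood_adjust <- function(C, A0, dets_A, dets_B,
                                 params = track_params()) {
  ma <- length(C$disappear)
  mb <- length(C$appear)
  if (ma == 0 || mb == 0 || nrow(A0$pairs) == 0) {
    return(C)
  }
  mu <- params$mu
  if (is.null(mu)) {
    fin <- C$assoc[is.finite(C$assoc)]
    mu <- if (length(fin)) 0.5 * median(fin) else 0
  }
  if (mu == 0) {
    return(C)
  }
  disp <- cbind(
    dets_B$x[A0$pairs[, 2]] - dets_A$x[A0$pairs[, 1]],
    dets_B$y[A0$pairs[, 2]] - dets_A$y[A0$pairs[, 1]]
  )
  assigned <- A0$pairs[, 1]
  adj <- C$assoc
  for (i in seq_len(ma)) {
    nb <- assigned[assigned != i]
    if (length(nb) == 0) next
    d <- sqrt((dets_A$x[nb] - dets_A$x[i])^2 +
                (dets_A$y[nb] - dets_A$y[i])^2)
    sel <- nb[order(d)][seq_len(min(params$k, length(nb)))]
    vbar <- colMeans(disp[match(sel, assigned), , drop = FALSE])
    jj <- which(is.finite(adj[i, ]))
    if (length(jj) == 0) next
    vx <- dets_B$x[jj] - dets_A$x[i] - vbar[1]
    vy <- dets_B$y[jj] - dets_A$y[i] - vbar[2]
    adj[i, jj] <- pmax(0, C$assoc[i, jj] -
                         mu * exp(-sqrt(vx^2 + vy^2) / params$sigma))
  }
  out <- C
  out$assoc <- adj
  out
}

#' Track detections across two consecutive frames
#'
#' Iterates solve / neighbourhood-adjust until the assignment stabilises or
#' `T_iter` rounds are reached. The adjustment is always applied to the
#' original cost matrix using the latest assignment.
#'
#' @param dets_A,dets_B detections tibbles of the two frames.
#' @param frame_shape `(height, width)`.
#' @param params a [track_params()].
#' @return The final `assignment` (attribute `"iterations"` records the
#'   number of Hungarian solves).
#' @export
track_frames <- function(dets_A, dets_B, frame_shape,
                         params = track_params()) {
  C0 <- build_cost_matrix(dets_A, dets_B, frame_shape, params)
  a <- solve_assignment(C0)
  iters <- 1L
  for (t in seq_len(params$T_iter)) {
    Ct <- neighbourhood_adjust(C0, a, dets_A, dets_B, params)
    a2 <- solve_assignment(Ct)
    iters <- iters + 1L
    if (identical(a2$pairs, a$pairs)) {
      a <- a2
      break
    }
    a <- a2
  }
  attr(a, "iterations") <- iters
  a
}

#' Chain frame-to-frame assignments into whole-movie traces
#'
#' Cell identifiers are minted at first appearance, in frame order then label
#' order. Paired detections extend the trace; a disappearance closes it, and
#' a later reappearance gets a fresh identifier (gaps are not bridged).
#'
#' @param detections detections tibble over all frames (column `frame`
#'   0-based, `label` 1..M within each frame).
#' @param assignments list of `assignment` objects, one per consecutive frame
#'   pair, in frame order.
#' @return Traces tibble: `frame`, `cell_id`, `detection_label`, `x`, `y`,
#'   `area`.
#' @export
build_traces <- function(detections, assignments) {
  frames <- sort(unique(detections$frame))
  if (length(frames) == 0) {
    return(tibble::tibble(frame = integer(), cell_id = integer(),
                          detection_label = integer(), x = numeric(),
                          y = numeric(), area = numeric()))
  }
  if (length(assignments) != length(frames) - 1) {
    stop("need one assignment per consecutive frame pair", call. = FALSE)
  }
  per_frame <- lapply(frames, function(f) {
    d <- detections[detections$frame == f, , drop = FALSE]
    d[order(d$label), , drop = FALSE]
  })
  ids <- vector("list", length(frames))
  next_id <- 1L
  ids[[1]] <- seq_len(nrow(per_frame[[1]]))
  next_id <- nrow(per_frame[[1]]) + 1L
  for (f in seq_along(assignments)) {
    a <- assignments[[f]]
    na <- nrow(per_frame[[f]])
    nb <- nrow(per_frame[[f + 1]])
    if (nrow(a$pairs) + length(a$disappearing) != na ||
        nrow(a$pairs) + length(a$appearing) != nb) {
      stop("assignment chain inconsistent with detection counts",
           call. = FALSE)
    }
    nxt <- integer(nb)
    if (nrow(a$pairs) > 0) {
      nxt[a$pairs[, 2]] <- ids[[f]][a$pairs[, 1]]
    }
    for (j in a$appearing) {
      nxt[j] <- next_id
      next_id <- next_id + 1L
    }
    ids[[f + 1]] <- nxt
  }
  out <- lapply(seq_along(frames), function(f) {
    d <- per_frame[[f]]
    tibble::tibble(
      frame = d$frame, cell_id = ids[[f]], detection_label = d$label,
      x = d$x, y = d$y,
      area = if ("area" %in% names(d)) d$area else NA_real_
    )
  })
  dplyr::bind_rows(out)
}

#' Track a whole movie of detections
#'
#' @param detections detections tibble over all frames.
#' @param frame_shape `(height, width)`.
#' @param params a [track_params()].
#' @return Traces tibble (see [build_traces()]).
#' @export
track_movie <- function(detections, frame_shape, params = track_params()) {
  frames <- sort(unique(detections$frame))
  if (length(frames) >= 2 &&
      !all(diff(frames) == 1)) {
    stop("detections contain frame gaps; tracking needs consecutive frames",
         call. = FALSE)
  }
  assignments <- list()
  if (length(frames) >= 2) {
    for (f in seq_len(length(frames) - 1)) {
      da <- detections[detections$frame == frames[f], , drop = FALSE]
      db <- detections[detections$frame == frames[f + 1], , drop = FALSE]
      da <- da[order(da$label), , drop = FALSE]
      db <- db[order(db$label), , drop = FALSE]
      assignments[[f]] <- track_frames(da, db, frame_shape, params)
    }
  }
  build_traces(detections, assignments)
}

#' Probability that a whole trace is correct
#'
#' If each consecutive-frame assignment is correct independently with
#' probability `rho`, a trace spanning `n` frames is entirely correct with
#' probability `rho ^ n` — tracking quality decays exponentially with movie
#' length, which is why per-link accuracy must be extremely high for
#' long-term experiments.
#'
#' @param rho per-link correctness probability in `[0, 1]`.
#' @param n trace length (number of frames), `>= 1`.
#' @return `rho ^ n`.
#' @export
#' @examples
#' trace_correctness_probability(0.99, 100) # ~0.37
trace_correctness_probability <- function(rho, n) {
  stopifnot_scalar(rho, "rho")
  stopifnot_scalar(n, "n")
  if (rho < 0 || rho > 1) {
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  }
  if (n < 1) {
    stop("`n` must be at least 1", call. = FALSE)
  }
  rho^n
}

#' @rdname tidy.sa_fit
#' @exportS3Method generics::tidy
tidy.assignment <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(a = x$pairs[, 1], b = x$pairs[, 2], event = "pair"),
    tibble::tibble(a = x$disappearing, b = NA_integer_,
                   event = "disappear"),
    tibble::tibble(a = NA_integer_, b = x$appearing, event = "appear")
  )
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf(
    "<assignment> %d pairs, %d appearing, %d disappearing, cost %.4f\n",
    nrow(x$pairs), length(x$appearing), length(x$disappearing), x$cost
  ))
  invisible(x)
}
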