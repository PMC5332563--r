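#' Ground-truth contour
#'
#' A reference cell outline used for parameter learning: either a disc
#' (`centre` + `radius`) or a star-shaped polygon given by its vertices.
#'
#' @param centre `(x, y)` in pixels.
#' @param radius disc radius (pixels); ignored when `vertices` is given.
#' @param vertices optional n x 2 `(x, y)` vertex matrix of a star-shaped
#'   polygon (star-shaped about its centroid).
#' @param frame_index frame the contour belongs to.
#' @return An object of class `gt_contour`.
#' @export
gt_contour <- function(centre = NULL, radius = NULL, vertices = NULL,
                       frame_index = 0L) {
  if (is.null(vertices)) {
    stopifnot(!is.null(centre), !is.null(radius), radius > 0)
  }
  structure(
    list(centre = centre, radius = radius, vertices = vertices,
         frame_index = as.integer(frame_index)),
    class = "gt_contour"
  )
}

# Rasterise a gt_contour or snake to linear pixel indices on a grid of
# dim `shape`. Polygons are assumed star-shaped about their centroid.
rasterize_contour <- function(obj, shape) {
  if (inherits(obj, "snake")) {
    return(snake_interior(obj, shape))
  }
  if (inherits(obj, "gt_contour")) {
    if (is.null(obj$vertices)) {
      cx <- obj$centre[1]
      cy <- obj$centre[2]
      r <- obj$radius
      x0 <- max(0, floor(cx - r))
      x1 <- min(shape[2] - 1, ceiling(cx + r))
      y0 <- max(0, floor(cy - r))
      y1 <- min(shape[1] - 1, ceiling(cy + r))
      if (x1 < x0 || y1 < y0) {
        return(integer(0))
      }
      xs <- rep(x0:x1, each = y1 - y0 + 1)
      ys <- rep(y0:y1, times = x1 - x0 + 1)
      inside <- (xs - cx)^2 + (ys - cy)^2 <= r^2
      return(xs[inside] * shape[1] + ys[inside] + 1)
    }
    return(star_polygon_interior(obj$vertices, shape))
  }
  stop("cannot rasterise this object", call. = FALSE)
}

# Interior of an arbitrary star-shaped polygon (vertices in any order) about
# its centroid, by the same polar chord test used for snakes.
star_polygon_interior <- function(v, shape) {
  pc <- polygon_area_centroid(v)
  c0 <- pc$centroid
  ang <- atan2(v[, 2] - c0[2], v[, 1] - c0[1]) %% (2 * pi)
  ord <- order(ang)
  ang <- ang[ord]
  rad <- sqrt((v[ord, 1] - c0[1])^2 + (v[ord, 2] - c0[2])^2)
  n <- length(ang)
  rmax <- max(rad)
  x0 <- max(0, floor(c0[1] - rmax))
  x1 <- min(shape[2] - 1, ceiling(c0[1] + rmax))
  y0 <- max(0, floor(c0[2] - rmax))
  y1 <- min(shape[1] - 1, ceiling(c0[2] + rmax))
  if (x1 < x0 || y1 < y0) {
    return(integer(0))
  }
  xs <- rep(x0:x1, each = y1 - y0 + 1)
  ys <- rep(y0:y1, times = x1 - x0 + 1)
  dx <- xs - c0[1]
  dy <- ys - c0[2]
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx) %% (2 * pi)
  j <- findInterval(phi, ang)
  j[j == 0] <- n                                  # wrap before first vertex
  j2 <- j %% n + 1
  th1 <- ang[j]
  th2 <- ang[j2]
  dth <- (th2 - th1) %% (2 * pi)
  dphi <- (phi - th1) %% (2 * pi)
  r1 <- rad[j]
  r2 <- rad[j2]
  denom <- r2 * sin(dth - dphi) + r1 * sin(dphi)
  rb <- ifelse(denom > 1e-12 & dth > 1e-12,
               r1 * r2 * sin(dth) / denom, pmax(r1, r2))
  inside <- r <= rb
  xs[inside] * shape[1] + ys[inside] + 1
}

#' Contour match measure (area-based distance)
#'
#' `1 - A(intersection) / A(union)` of the rasterised interiors (the Jaccard
#' distance): 0 for identical contours, 1 for disjoint ones.
#'
#' @param gamma a computed contour ([snake()] or `gt_contour`).
#' @param theta the reference contour.
#' @param shape `(height, width)` of the raster grid; defaults to a grid
#'   covering both shapes.
#' @return Scalar in `[0, 1]`.
#' @export
contour_match <- function(gamma, theta, shape = NULL) {
  if (is.null(shape)) {
    ext <- function(o) {
      if (inherits(o, "snake")) {
        v <- snake_vertices(o)
      } else if (!is.null(o$vertices)) {
        v <- o$vertices
      } else {
        v <- cbind(o$centre[1] + c(-1, 1) * o$radius,
                   o$centre[2] + c(-1, 1) * o$radius)
      }
      c(max(v[, 2]), max(v[, 1]))
    }
    e1 <- ext(gamma)
    e2 <- ext(theta)
    shape <- c(ceiling(max(e1[1], e2[1])) + 2, ceiling(max(e1[2], e2[2])) + 2)
  }
  a <- rasterize_contour(gamma, shape)
  b <- rasterize_contour(theta, shape)
  if (length(a) == 0 || length(b) == 0) {
    stop("contour rasterises to zero pixels", call. = FALSE)
  }
  1 - length(intersect(a, b)) / length(union(a, b))
}

gt_centroid <- function(theta) {
  if (is.null(theta$vertices)) {
    theta$centre
  } else {
    polygon_area_centroid(theta$vertices)$centroid
  }
}

#' Cost of a contour-parameter set against ground-truth contours
#'
#' For every ground-truth contour, a few seeds are drawn uniformly in a disc
#' around its centroid, a snake is grown from each with the candidate
#' parameters, and the cost is the root mean square of all contour match
#' measures (degenerate snakes count as a full mismatch of 1). Deterministic
#' for a fixed `rng_seed`.
#'
#' @param params an [energy_params()] candidate.
#' @param gt list of `gt_contour`s (all in one frame).
#' @param helpers the frame's [compute_helpers()] result.
#' @param rng_seed integer seed.
#' @param n_seeds seeds per contour.
#' @param jitter_r seed scatter radius (pixels) around each centroid.
#' @return RMS cost in `[0, 1]` (assuming match measures in `[0, 1]`).
#' @export
contour_cost <- function(params, gt, helpers, rng_seed = 1L, n_seeds = 3L,
                         jitter_r = 3) {
  stopifnot(length(gt) >= 1)
  local_seed(rng_seed, {
    ms <- numeric(0)
    for (theta in gt) {
      c0 <- gt_centroid(theta)
      for (s in seq_len(n_seeds)) {
        repeat {
          ang <- runif(1, 0, 2 * pi)
          rr <- jitter_r * sqrt(runif(1))
          seed <- c0 + rr * c(cos(ang), sin(ang))
          if (in_bounds(helpers$shape, seed[1], seed[2])) break
        }
        sn <- deform(seed, helpers, params)
        ms <- c(ms, if (sn$degenerate) 1 else {
          contour_match(sn, theta, helpers$shape)
        })
      }
    }
    sqrt(mean(ms^2))
  })
}

#' Cost of a ranking-parameter set against ground-truth contours
#'
#' Snakes are grown from many seeds scattered inside and around every
#' ground-truth contour; for each contour the best-ranked (lowest rank)
#' candidate is selected and the cost is the RMS of the selected candidates'
#' match measures — a good ranking selects the best-matching contour.
#'
#' @param params a [seg_params()] candidate (its ranking weights are what is
#'   being scored; contour parameters come from `params$energy`).
#' @param gt list of `gt_contour`s.
#' @param helpers the frame's [compute_helpers()] result.
#' @param rng_seed integer seed.
#' @param n_rank seeds per contour.
#' @param select how the per-contour candidate is chosen: by the ranking
#'   under scrutiny (`"rank"`, the default), or the diagnostic baselines
#'   `"random"` (uniform draw) and `"best"` (oracle pick of the truly best
#'   match). The RNG stream is consumed identically in every mode, so runs
#'   with the same `rng_seed` grow the same candidate snakes and differ only
#'   in the selection — a paired comparison of ranking quality.
#' @return RMS cost.
#' @export
ranking_cost <- function(params, gt, helpers, rng_seed = 1L, n_rank = 6L,
                         select = c("rank", "random", "best")) {
  stopifnot(length(gt) >= 1)
  select <- match.arg(select)
  local_seed(rng_seed, {
    ms <- numeric(0)
    for (theta in gt) {
      c0 <- gt_centroid(theta)
      spread <- if (is.null(theta$radius)) {
        sqrt(polygon_area_centroid(theta$vertices)$area / pi)
      } else {
        theta$radius
      }
      # draw all seed positions first (fixed RNG consumption per contour)
      seeds <- matrix(NA_real_, n_rank, 2)
      for (s in seq_len(n_rank)) {
        repeat {
          ang <- runif(1, 0, 2 * pi)
          rr <- spread * sqrt(runif(1)) * 1.2     # inside and around
          pt <- c0 + rr * c(cos(ang), sin(ang))
          if (in_bounds(helpers$shape, pt[1], pt[2])) break
        }
        seeds[s, ] <- pt
      }
      pick_u <- runif(1)                          # selection draw (all modes)
      ranks <- rep(Inf, n_rank)
      matches <- rep(1, n_rank)
      for (s in seq_len(n_rank)) {
        sn <- deform(seeds[s, ], helpers, params$energy)
        if (sn$degenerate) next
        idx <- snake_interior(sn, helpers$shape)
        if (length(idx) == 0) next
        g <- snake_geometry(sn)
        ff <- fg_fraction(idx, helpers$foreground_mask)
        ranks[s] <- sn$energy_total +
          params$w_rank_area * ((g$area - params$energy$A_exp) /
                                  params$energy$A_exp)^2 +
          params$w_rank_fg * (1 - ff)
        matches[s] <- contour_match(sn, theta, helpers$shape)
      }
      ms <- c(ms, switch(select,
        rank = matches[which.min(ranks)],
        best = min(matches),
        random = matches[ceiling(pick_u * n_rank)]
      ))
    }
    sqrt(mean(ms^2))
  })
}

#' Minimise a cost function by simulated annealing
#'
#' Box-constrained simulated annealing with geometric cooling (temperature
#' `T0 * cool^step`), Gaussian proposals at 5% of each bound range, and
#' reflection at the bounds. The budget is counted in cost evaluations and
#' the best-so-far vector is tracked, so the result is never worse than the
#' initial point and the search can be stopped anytime.
#'
#' @param cost_fn function taking a named numeric vector, returning a scalar
#'   cost.
#' @param lower,upper named numeric vectors of box bounds.
#' @param budget maximum number of cost evaluations.
#' @param rng_seed integer seed; the whole trajectory is deterministic.
#' @param init optional initial vector; defaults to the box midpoint.
#' @param T0,cool initial temperature and geometric cooling factor.
#' @return An object of class `sa_fit`: `par` (best vector), `cost`,
#'   `init_par`, `init_cost`, and `trajectory` (tibble with one row per
#'   evaluation: proposal cost, best-so-far cost, acceptance).
#' @export
optimize_params <- function(cost_fn, lower, upper, budget = 500L,
                            rng_seed = 1L, init = NULL, T0 = 1,
                            cool = 0.95) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower), budget >= 1)
  if (is.null(init)) {
    init <- (lower + upper) / 2
  }
  init <- pmin(pmax(init, lower), upper)
  step_sd <- 0.05 * (upper - lower)
  local_seed(rng_seed, {
    cur <- init
    cur_cost <- cost_fn(cur)
    best <- cur
    best_cost <- cur_cost
    traj <- vector("list", budget)
    traj[[1]] <- tibble::tibble(eval = 1L, cost = cur_cost,
                                best = best_cost, accepted = TRUE)
    temp <- T0
    n_eval <- 1L
    while (n_eval < budget) {
      prop <- cur + rnorm(length(cur), 0, step_sd)
      # reflect at the bounds
      for (rep_i in 1:3) {
        over <- prop > upper
        prop[over] <- 2 * upper[over] - prop[over]
        under <- prop < lower
        prop[under] <- 2 * lower[under] - prop[under]
      }
      prop <- pmin(pmax(prop, lower), upper)
      pc <- cost_fn(prop)
      n_eval <- n_eval + 1L
      acc <- pc <= cur_cost || runif(1) < exp((cur_cost - pc) / temp)
      if (acc) {
        cur <- prop
        cur_cost <- pc
      }
      if (pc < best_cost) {
        best <- prop
        best_cost <- pc
      }
      traj[[n_eval]] <- tibble::tibble(eval = n_eval, cost = pc,
                                       best = best_cost, accepted = acc)
      temp <- temp * cool
    }
    structure(
      list(par = best, cost = best_cost, init_par = init,
           init_cost = traj[[1]]$cost,
           trajectory = dplyr::bind_rows(traj[seq_len(n_eval)])),
      class = "sa_fit"
    )
  })
}

#' Learn contour energy parameters from ground-truth contours
#'
#' Optimises the delicate contour weights (surface weights, boundary weights,
#' regularity and expected area) by simulated annealing of [contour_cost()].
#'
#' @param gt list of `gt_contour`s.
#' @param helpers the frame's [compute_helpers()] result.
#' @param base an [energy_params()] supplying the non-learned values.
#' @param budget cost evaluations.
#' @param rng_seed integer seed.
#' @param init optional named initial vector.
#' @param n_seeds,jitter_r passed to [contour_cost()].
#' @return List: `params` (an [energy_params()] with learned values), `fit`
#'   (the `sa_fit`).
#' @export
learn_contour_params <- function(gt, helpers, base = energy_params(),
                                 budget = 150L, rng_seed = 1L, init = NULL,
                                 n_seeds = 3L, jitter_r = 3) {
  lower <- c(w_border = 0, w_gradient = 0, w_content = 0, w_border_in = 0,
             w_area = 0, kappa = 0, A_exp = 0.25 * base$A_exp)
  upper <- c(w_border = 2, w_gradient = 2, w_content = 2, w_border_in = 2,
             w_area = 1, kappa = 1, A_exp = 4 * base$A_exp)
  apply_vec <- function(x) {
    p <- base
    for (nm in names(x)) p[[nm]] <- unname(x[nm])
    p$r_max <- 3 * sqrt(p$A_exp / pi)
    class(p) <- "energy_params"
    p
  }
  fit <- optimize_params(
    function(x) contour_cost(apply_vec(x), gt, helpers, rng_seed = rng_seed,
                             n_seeds = n_seeds, jitter_r = jitter_r),
    lower, upper, budget = budget, rng_seed = rng_seed, init = init
  )
  list(params = apply_vec(fit$par), fit = fit)
}

#' Broom-style accessors for starseg result objects
#'
#' `tidy()` returns the per-unit table of a result (per-ray vertices of a
#' snake, per-frame rows of a metric report, per-evaluation rows of a
#' simulated-annealing fit, per-event rows of an assignment); `glance()`
#' returns a one-row summary.
#'
#' @param x a `sa_fit`, `snake`, `metric_report` or `assignment`.
#' @param ... unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.sa_fit <- function(x, ...) {
  x$trajectory
}

#' @rdname tidy.sa_fit
#' @exportS3Method generics::glance
glance.sa_fit <- function(x, ...) {
  tibble::tibble(
    cost = x$cost, init_cost = x$init_cost,
    n_eval = nrow(x$trajectory),
    improvement = x$init_cost - x$cost
  )
}

#' @export
print.sa_fit <- function(x, ...) {
  cat(sprintf(
    "<sa_fit> cost %.4f (from %.4f) after %d evaluations\n",
    x$cost, x$init_cost, nrow(x$trajectory)
  ))
  invisible(x)
}

#' Cost trajectory plot for a simulated-annealing fit
#'
#' @param object an `sa_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sa_fit <- function(object, ...) {
  ggplot2::ggplot(object$trajectory, ggplot2::aes(.data$eval)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cost), alpha = 0.3,
                        size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best), colour = "firebrick") +
    ggplot2::labs(x = "cost evaluation", y = "cost",
                  title = "simulated annealing trajectory") +
    ggplot2::theme_minimal()
}
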