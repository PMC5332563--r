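#' Segmentation parameters
#'
#' Controls seeding, the iterative seeding/deformation loop, and the ranking
#' and overlap filters applied to candidate snakes.
#'
#' @param energy an [energy_params()] bundle used for contour deformation.
#' @param seed_sigma Gaussian smoothing applied to the border image before
#'   looking for its local minima (seed candidates).
#' @param min_seed_dist seeds closer than this (pixels) are merged.
#' @param area_min,area_max hard area filter bounds in px^2; `NULL` defaults
#'   to `0.2 * A_exp` and `4 * A_exp`.
#' @param fg_frac minimum fraction of a snake's interior that must lie inside
#'   the foreground mask.
#' @param overlap_frac a candidate is rejected when the overlap with an
#'   already accepted snake exceeds this fraction of the smaller interior.
#' @param max_iterations maximum number of seeding/deformation/filter rounds
#'   per frame.
#' @param jitter_seeds maximum number of random seeds drawn per uncovered
#'   foreground blob in iterations after the first.
#' @param w_rank_area,w_rank_fg weights of the additive soft penalties (area
#'   deviation, foreground deficit) added to the snake energy to form its
#'   rank.
#' @param coverage_stop stop iterating once this fraction of the foreground is
#'   covered by accepted snakes.
#' @return A `seg_params` list.
#' @export
seg_params <- function(energy = energy_params(), seed_sigma = 3,
                       min_seed_dist = 6, area_min = NULL, area_max = NULL,
                       fg_frac = 0.6, overlap_frac = 0.3,
                       max_iterations = 4L, jitter_seeds = 2L,
                       w_rank_area = 0.2, w_rank_fg = 1,
                       coverage_stop = 0.98) {
  if (is.null(area_min)) area_min <- 0.2 * energy$A_exp
  if (is.null(area_max)) area_max <- 4 * energy$A_exp
  stopifnot(area_min > 0, area_min < area_max, overlap_frac >= 0,
            max_iterations >= 1)
  structure(
    list(
      energy = energy, seed_sigma = seed_sigma,
      min_seed_dist = min_seed_dist, area_min = area_min,
      area_max = area_max, fg_frac = fg_frac, overlap_frac = overlap_frac,
      max_iterations = as.integer(max_iterations),
      jitter_seeds = as.integer(jitter_seeds),
      w_rank_area = w_rank_area, w_rank_fg = w_rank_fg,
      coverage_stop = coverage_stop
    ),
    class = "seg_params"
  )
}

new_seeds <- function(x, y, origin) {
  tibble::tibble(x = as.numeric(x), y = as.numeric(y), origin = origin)
}

# Strict 8-neighbour local minima of a matrix, restricted to `mask`.
local_minima <- function(img, mask) {
  h <- nrow(img)
  w <- ncol(img)
  big <- max(img) + 1
  pad <- matrix(big, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- img
  ok <- matrix(TRUE, h, w)
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dx == 0 && dy == 0) next
      nb <- pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
      ok <- ok & (img < nb)
    }
  }
  ok <- ok & mask
  idx <- which(ok, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

# Greedy merge of points closer than min_dist (keeps the first of each
# cluster in the given priority order).
merge_close_points <- function(pts, min_dist, value = NULL) {
  if (nrow(pts) == 0) {
    return(pts)
  }
  ord <- if (is.null(value)) seq_len(nrow(pts)) else order(value)
  pts <- pts[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    if (i < nrow(pts)) {
      lat <- (i + 1):nrow(pts)
      d <- sqrt((pts[lat, 1] - pts[i, 1])^2 + (pts[lat, 2] - pts[i, 2])^2)
      keep[lat[d < min_dist]] <- FALSE
    }
  }
  pts[keep, , drop = FALSE]
}

#' Seeds from local minima of the smoothed border image
#'
#' Tentative cell centres are the strict local minima of the smoothed
#' cell-border image inside the foreground mask (cell interiors are flat, so
#' edge strength dips at the centre). Minima closer than `min_seed_dist` are
#' merged.
#'
#' @param helpers a [compute_helpers()] result.
#' @param params a [seg_params()].
#' @return Tibble of seeds: `x`, `y`, `origin`.
#' @export
seeds_border_minima <- function(helpers, params = seg_params()) {
  seeds_from_image(helpers$border_image, helpers$foreground_mask, params,
                   "border_minima")
}

#' Seeds from local maxima of the cell-content image
#'
#' @inheritParams seeds_border_minima
#' @return Tibble of seeds: `x`, `y`, `origin`.
#' @export
seeds_content_maxima <- function(helpers, params = seg_params()) {
  seeds_from_image(1 - helpers$content_image, helpers$foreground_mask, params,
                   "content")
}

seeds_from_image <- function(img, mask, params, origin) {
  if (!any(mask)) {
    return(new_seeds(numeric(0), numeric(0), character(0)))
  }
  sm <- if (params$seed_sigma > 0) {
    as_matrix_img(EBImage::gblur(img, sigma = params$seed_sigma))
  } else {
    img
  }
  pts <- local_minima(sm, mask)
  if (nrow(pts) == 0) {
    return(new_seeds(numeric(0), numeric(0), character(0)))
  }
  val <- sm[cbind(pts[, 2] + 1, pts[, 1] + 1)]
  # discard shallow minima (numerical ripples on flat regions): a seed must
  # sit at least 5% of the image's dynamic range below its maximum
  rng <- range(sm[mask])
  deep <- val <= rng[2] - 0.05 * (rng[2] - rng[1])
  pts <- pts[deep, , drop = FALSE]
  val <- val[deep]
  if (nrow(pts) == 0) {
    return(new_seeds(numeric(0), numeric(0), character(0)))
  }
  pts <- merge_close_points(pts, params$min_seed_dist, value = val)
  new_seeds(pts[, 1], pts[, 2], origin)
}

# Union of accepted interiors as a logical matrix.
covered_mask <- function(detections, shape) {
  cov <- matrix(FALSE, shape[1], shape[2])
  for (s in detections$polygon) {
    cov[snake_interior(s, shape)] <- TRUE
  }
  cov
}

#' Seeds in the not-yet-covered part of the image
#'
#' Masks the border and content images by the union of already accepted
#' interiors, reruns the border-minima and content-maxima strategies there,
#' and drops any seed falling inside an accepted detection — so new seeds are
#' placed only where cells are expected but not yet found.
#'
#' @param helpers a [compute_helpers()] result.
#' @param accepted detections tibble (may be empty) as returned by
#'   [rank_and_filter()].
#' @param params a [seg_params()].
#' @return Tibble of seeds: `x`, `y`, `origin`.
#' @export
seeds_excluding_covered <- function(helpers, accepted,
                                    params = seg_params()) {
  cov <- if (!is.null(accepted) && nrow(accepted) > 0) {
    covered_mask(accepted, helpers$shape)
  } else {
    matrix(FALSE, helpers$shape[1], helpers$shape[2])
  }
  h2 <- helpers
  h2$border_image[cov] <- 1       # look like strong border: no minima there
  h2$content_image[cov] <- 0      # no content evidence there
  h2$foreground_mask <- helpers$foreground_mask & !cov
  out <- dplyr::bind_rows(
    seeds_border_minima(h2, params),
    seeds_content_maxima(h2, params)
  )
  if (nrow(out) == 0) {
    return(out)
  }
  inside <- cov[cbind(round(out$y) + 1, round(out$x) + 1)]
  out[!inside, , drop = FALSE]
}

#' Relocate a seed to the centroid of a detected contour
#'
#' A contour grown from a badly placed seed usually still covers the cell, so
#' its centroid falls closer to the true cell centre; growing again from the
#' centroid improves the contour.
#'
#' @param s a non-degenerate [snake()].
#' @return A one-row seed tibble with `origin = "centroid_relocation"`.
#' @export
relocate_seed <- function(s) {
  if (isTRUE(s$degenerate)) {
    stop("cannot relocate a degenerate snake", call. = FALSE)
  }
  g <- snake_geometry(s)
  new_seeds(g$centroid[1], g$centroid[2], "centroid_relocation")
}

# Random seeds inside uncovered foreground blobs (at most `jitter_seeds` per
# blob), drawn uniformly over each blob's pixels.
seeds_random_jitter <- function(helpers, accepted, params) {
  cov <- if (nrow(accepted) > 0) {
    covered_mask(accepted, helpers$shape)
  } else {
    matrix(FALSE, helpers$shape[1], helpers$shape[2])
  }
  open_fg <- helpers$foreground_mask & !cov
  if (!any(open_fg)) {
    return(new_seeds(numeric(0), numeric(0), character(0)))
  }
  lab <- as_matrix_img(EBImage::bwlabel(open_fg))
  xs <- numeric(0)
  ys <- numeric(0)
  for (b in sort(unique(lab[lab > 0]))) {
    idx <- which(lab == b)
    if (length(idx) < 9) next                    # ignore tiny slivers
    take <- sample(idx, min(params$jitter_seeds, length(idx)))
    ys <- c(ys, (take - 1) %% nrow(lab))
    xs <- c(xs, (take - 1) %/% nrow(lab))
  }
  new_seeds(xs, ys, "random_jitter")
}

# Fraction of a snake interior lying inside the foreground mask.
fg_fraction <- function(idx, fg) {
  if (length(idx) == 0) {
    return(0)
  }
  mean(fg[idx])
}

#' Rank candidate snakes and keep a non-overlapping subset
#'
#' Hard filters first: degenerate snakes, areas outside
#' `[area_min, area_max]`, and snakes with less than `fg_frac` of their
#' interior in the foreground mask are discarded. Survivors are ranked by
#' snake energy plus additive soft penalties (area deviation from the
#' expected area, foreground deficit), and accepted greedily in rank order;
#' a candidate overlapping an already accepted interior by more than
#' `overlap_frac` of the smaller one is discarded as a worse detection of the
#' same cell. Ties in rank are broken towards larger area, then input order.
#'
#' @param candidates list of deformed [snake()]s.
#' @param helpers a [compute_helpers()] result.
#' @param params a [seg_params()].
#' @param accepted optional detections tibble from a previous round; its rows
#'   are kept as-is and new candidates are filtered against them (the accepted
#'   set only ever grows across iterations).
#' @param frame_index frame number stored in the output.
#' @return Detections tibble: `frame`, `label`, `x`, `y`, `area`, `rank`,
#'   `polygon` (list column of snakes). Labels are 1..M in rank order.
#' @export
rank_and_filter <- function(candidates, helpers, params = seg_params(),
                            accepted = NULL, frame_index = 0L) {
  if (is.null(accepted) || nrow(accepted) == 0) {
    accepted <- empty_detections()
  }
  keep <- list()
  ranks <- numeric(0)
  areas <- numeric(0)
  for (s in candidates) {
    if (isTRUE(s$degenerate)) next
    idx <- snake_interior(s, helpers$shape)
    if (length(idx) == 0) next
    g <- snake_geometry(s)
    if (g$area < params$area_min || g$area > params$area_max) next
    ff <- fg_fraction(idx, helpers$foreground_mask)
    if (ff < params$fg_frac) next
    if (!is.finite(s$energy_total)) {
      s <- evaluate_snake(s, helpers, params$energy)
    }
    s$rank <- s$energy_total +
      params$w_rank_area * ((g$area - params$energy$A_exp) /
                              params$energy$A_exp)^2 +
      params$w_rank_fg * (1 - ff)
    attr(s, "interior") <- idx
    attr(s, "geometry") <- g
    keep[[length(keep) + 1]] <- s
    ranks <- c(ranks, s$rank)
    areas <- c(areas, g$area)
  }
  acc_snakes <- accepted$polygon
  acc_interiors <- lapply(acc_snakes, function(s) {
    i <- attr(s, "interior")
    if (is.null(i)) snake_interior(s, helpers$shape) else i
  })
  if (length(keep)) {
    for (k in order(ranks, -areas)) {
      s <- keep[[k]]
      idx <- attr(s, "interior")
      ok <- TRUE
      for (ai in acc_interiors) {
        ov <- length(intersect(idx, ai)) / min(length(idx), length(ai))
        if (ov > params$overlap_frac) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      g <- attr(s, "geometry")
      acc_snakes[[length(acc_snakes) + 1]] <- s
      acc_interiors[[length(acc_interiors) + 1]] <- idx
      accepted <- dplyr::bind_rows(
        accepted,
        tibble::tibble(
          frame = as.integer(frame_index), label = 0L,
          x = g$centroid[1], y = g$centroid[2], area = g$area,
          rank = s$rank, polygon = list(s)
        )
      )
    }
  }
  if (nrow(accepted) > 0) {
    ord <- order(accepted$rank, -accepted$area)
    accepted <- accepted[ord, , drop = FALSE]
    accepted$label <- seq_len(nrow(accepted))
    accepted$frame <- as.integer(frame_index)
  }
  accepted
}

empty_detections <- function() {
  tibble::tibble(
    frame = integer(), label = integer(), x = numeric(), y = numeric(),
    area = numeric(), rank = numeric(), polygon = list()
  )
}

#' Segment one frame with iterative seeding and snake deformation
#'
#' Runs the full per-frame pipeline: helper images, seed placement (border
#' minima and content maxima; centroids of the previous frame's detections
#' when given), snake deformation from every seed with one
#' centroid-relocation round per snake, ranking and overlap filtering, and
#' then further iterations that re-seed only the not-yet-covered areas (plus
#' a few random seeds inside uncovered foreground blobs). Iteration stops
#' when the foreground is essentially covered, no new seeds appear, or
#' `max_iterations` is reached. The accepted set only grows across
#' iterations; final labels are 1..M in rank order.
#'
#' @param raw numeric matrix in `[0, 1]`.
#' @param params a [seg_params()].
#' @param prev optional detections tibble from the previous frame whose
#'   centroids are used as extra first-iteration seeds.
#' @param preprocess a [preprocess_params()].
#' @param helpers optionally a precomputed [compute_helpers()] result.
#' @param frame_index frame number stored in the detections.
#' @param seed RNG seed for the randomised seeding strategy.
#' @return Detections tibble (see [rank_and_filter()]).
#' @export
segment_frame <- function(raw, params = seg_params(), prev = NULL,
                          preprocess = preprocess_params(), helpers = NULL,
                          frame_index = 0L, seed = 1L) {
  if (is.null(helpers)) {
    helpers <- compute_helpers(raw, preprocess)
  }
  accepted <- empty_detections()
  local_seed(seed, {
    for (iter in seq_len(params$max_iterations)) {
      if (iter == 1) {
        seeds <- dplyr::bind_rows(
          seeds_border_minima(helpers, params),
          seeds_content_maxima(helpers, params)
        )
        if (!is.null(prev) && nrow(prev) > 0) {
          seeds <- dplyr::bind_rows(
            seeds, new_seeds(prev$x, prev$y, "previous_frame")
          )
        }
      } else {
        seeds <- dplyr::bind_rows(
          seeds_excluding_covered(helpers, accepted, params),
          seeds_random_jitter(helpers, accepted, params)
        )
      }
      if (nrow(seeds) > 0) {
        dd <- merge_close_points(cbind(seeds$x, seeds$y),
                                 params$min_seed_dist / 2)
        seeds <- new_seeds(dd[, 1], dd[, 2], "merged")
      }
      if (nrow(seeds) == 0) break
      cands <- list()
      for (i in seq_len(nrow(seeds))) {
        s1 <- deform(c(seeds$x[i], seeds$y[i]), helpers, params$energy)
        cands[[length(cands) + 1]] <- s1
        if (!s1$degenerate) {
          rs <- relocate_seed(s1)
          if (in_bounds(helpers$shape, rs$x, rs$y)) {
            s2 <- deform(c(rs$x, rs$y), helpers, params$energy)
            cands[[length(cands) + 1]] <- s2
          }
        }
      }
      accepted <- rank_and_filter(cands, helpers, params,
                                  accepted = accepted,
                                  frame_index = frame_index)
      fg_n <- sum(helpers$foreground_mask)
      if (fg_n == 0) break
      cov <- covered_mask(accepted, helpers$shape)
      if (sum(cov & helpers$foreground_mask) / fg_n >= params$coverage_stop) {
        break
      }
    }
  })
  accepted
}

#' Segment a whole movie
#'
#' Applies [segment_frame()] to each frame, feeding each frame's detections to
#' the next as seed priors.
#'
#' @param frames list of intensity matrices.
#' @param params a [seg_params()].
#' @param preprocess a [preprocess_params()].
#' @param seed RNG seed (frame `f` uses `seed + f`).
#' @return Detections tibble over all frames.
#' @export
segment_movie <- function(frames, params = seg_params(),
                          preprocess = preprocess_params(), seed = 1L) {
  prev <- NULL
  out <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    prev <- segment_frame(frames[[f]], params, prev = prev,
                          preprocess = preprocess,
                          frame_index = f - 1L, seed = seed + f - 1L)
    out[[f]] <- prev
  }
  dplyr::bind_rows(out)
}

#' Rasterise detections to a label mask
#'
#' @param detections detections tibble for one frame.
#' @param shape `(height, width)`.
#' @return Integer matrix; 0 is background, labels follow `detections$label`.
#' @export
detections_to_mask <- function(detections, shape) {
  m <- matrix(0L, shape[1], shape[2])
  if (nrow(detections) == 0) {
    return(m)
  }
  for (i in order(-detections$rank)) {            # better ranks painted last
    m[snake_interior(detections$polygon[[i]], shape)] <- detections$label[i]
  }
  m
}
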