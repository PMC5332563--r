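#' Scene specification for the synthetic brightfield generator
#'
#' Describes a synthetic movie of roundish budding-yeast-like cells growing as
#' a monolayer, rendered with the three intensity facts characteristic of
#' brightfield imaging of yeast: cell interiors darker than the background, a
#' high-gradient dark rim at the cell border, and bright halos that make the
#' inter-cell space lighter than the background.
#'
#' @param frame_shape integer `(height, width)` in pixels.
#' @param n_cells number of cells at frame 0.
#' @param n_frames number of frames.
#' @param r_range `(min, max)` cell equivalent radius in pixels at frame 0.
#' @param background background intensity level in `[0, 1]`.
#' @param interior cell interior intensity; must be `< background`.
#' @param border_dark intensity of the thin dark rim at the cell boundary.
#' @param halo intensity of the bright halo just outside the cell; must be
#'   `> background`.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @param drift colony drift `(dx, dy)` in pixels per frame.
#' @param jitter per-cell isotropic jitter standard deviation, pixels/frame.
#' @param division_prob per-cell, per-frame probability of budding off a
#'   daughter cell.
#' @param layout `"colony"` packs cells around a common centre (contact
#'   allowed); `"sparse"` enforces pairwise centre distances greater than three
#'   times the maximum radius; `"two_colonies"` packs two side-by-side
#'   sub-colonies.
#' @param seed integer RNG seed; the whole movie is a deterministic function
#'   of the spec.
#'
#' @return An object of class `scene_spec` (a named list).
#' @export
scene_spec <- function(frame_shape = c(256L, 256L),
                       n_cells = 10,
                       n_frames = 5,
                       r_range = c(7, 12),
                       background = 0.70,
                       interior = 0.35,
                       border_dark = 0.15,
                       halo = 0.90,
                       noise_sigma = 0.02,
                       drift = c(0, 0),
                       jitter = 0.3,
                       division_prob = 0,
                       layout = c("colony", "sparse", "two_colonies"),
                       seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(
    length(frame_shape) == 2, all(frame_shape >= 16),
    n_cells >= 0, n_frames >= 1,
    length(r_range) == 2, r_range[1] > 0, r_range[1] <= r_range[2]
  )
  lv <- c(background, interior, border_dark, halo)
  if (any(lv < 0 | lv > 1)) {
    stop("intensity levels must lie in [0, 1]", call. = FALSE)
  }
  if (!(interior < background && background < halo)) {
    stop("levels must satisfy interior < background < halo", call. = FALSE)
  }
  structure(
    list(
      frame_shape = as.integer(frame_shape), n_cells = as.integer(n_cells),
      n_frames = as.integer(n_frames), r_range = r_range,
      background = background, interior = interior,
      border_dark = border_dark, halo = halo, noise_sigma = noise_sigma,
      drift = drift, jitter = jitter, division_prob = division_prob,
      layout = layout, seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

# One repulsion sweep: push apart every pair of cells that overlaps beyond
# light contact. `pos` is an n x 2 (x, y) matrix; `r` the radii.
resolve_overlaps <- function(pos, r, frame_shape, max_sweeps = 40,
                             contact = 0.95) {
  n <- nrow(pos)
  if (n < 2) {
    return(pos)
  }
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    d <- dist_xy(pos, pos)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        need <- contact * (r[i] + r[j])
        if (d[i, j] < need) {
          moved <- TRUE
          dir <- pos[j, ] - pos[i, ]
          nd <- sqrt(sum(dir^2))
          dir <- if (nd < 1e-9) c(1, 0) else dir / nd
          push <- (need - d[i, j]) / 2 + 0.1
          pos[i, ] <- pos[i, ] - dir * push
          pos[j, ] <- pos[j, ] + dir * push
        }
      }
    }
    if (!moved) {
      return(pos)
    }
    # keep centres inside the frame with a small margin
    pos[, 1] <- pmin(pmax(pos[, 1], 2), frame_shape[2] - 3)
    pos[, 2] <- pmin(pmax(pos[, 2], 2), frame_shape[1] - 3)
    d <- dist_xy(pos, pos)
  }
  pos
}

place_cells <- function(spec) {
  n <- spec$n_cells
  h <- spec$frame_shape[1]
  w <- spec$frame_shape[2]
  r <- runif(n, spec$r_range[1], spec$r_range[2])
  if (n == 0) {
    return(list(pos = matrix(numeric(0), 0, 2), r = r))
  }
  if (spec$layout == "sparse") {
    min_d <- 3 * spec$r_range[2]
    pos <- matrix(NA_real_, n, 2)
    tries <- 0
    placed <- 0
    while (placed < n) {
      cand <- c(runif(1, min_d / 2, w - 1 - min_d / 2),
                runif(1, min_d / 2, h - 1 - min_d / 2))
      ok <- placed == 0 ||
        all(sqrt(rowSums(sweep(pos[seq_len(placed), , drop = FALSE], 2,
                               cand)^2)) > min_d)
      if (ok) {
        placed <- placed + 1
        pos[placed, ] <- cand
      }
      tries <- tries + 1
      if (tries > 20000) {
        stop("infeasible sparse packing for this frame size", call. = FALSE)
      }
    }
  } else if (spec$layout == "two_colonies") {
    c1 <- c((w - 1) * 0.3, (h - 1) * 0.45)
    c2 <- c((w - 1) * 0.7, (h - 1) * 0.55)
    n1 <- ceiling(n / 2)
    spread <- sqrt(n / 2) * mean(spec$r_range) * 0.9
    pos <- rbind(
      cbind(c1[1] + rnorm(n1, 0, spread), c1[2] + rnorm(n1, 0, spread)),
      cbind(c2[1] + rnorm(n - n1, 0, spread), c2[2] + rnorm(n - n1, 0, spread))
    )
    pos <- resolve_overlaps(pos, r, spec$frame_shape)
  } else {
    centre <- c((w - 1) / 2, (h - 1) / 2)
    spread <- sqrt(n) * mean(spec$r_range) * 1.1
    pos <- cbind(centre[1] + rnorm(n, 0, spread),
                 centre[2] + rnorm(n, 0, spread))
    pos <- resolve_overlaps(pos, r, spec$frame_shape)
  }
  list(pos = pos, r = r)
}

# Paint one movie frame. `cells` is a data.frame with x, y, r, ecc, phi.
render_frame <- function(cells, spec, noise = TRUE) {
  h <- spec$frame_shape[1]
  w <- spec$frame_shape[2]
  img <- matrix(spec$background, h, w)
  mask <- matrix(0L, h, w)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  n <- nrow(cells)
  # halos first (max-combined, only brighten), then bodies on top
  if (n > 0) {
    for (i in seq_len(n)) {
      d <- cell_norm_dist(xs, ys, cells[i, ])
      halo_px <- d > 1 & d <= 1.35
      img[halo_px] <- pmax(img[halo_px], spec$halo)
    }
    for (i in seq_len(n)) {
      d <- cell_norm_dist(xs, ys, cells[i, ])
      img[d <= 1] <- spec$border_dark
      img[d <= 0.88] <- spec$interior
      mask[d <= 1] <- cells$id[i]
    }
  }
  if (noise && spec$noise_sigma > 0) {
    img <- img + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
  }
  list(img = clamp01(img), mask = mask)
}

# Normalised elliptical distance of pixel grid from a cell (1 = boundary).
cell_norm_dist <- function(xs, ys, cell) {
  u <- xs - cell$x
  v <- ys - cell$y
  cp <- cos(cell$phi)
  sp <- sin(cell$phi)
  a <- cell$r * sqrt(cell$ecc)
  b <- cell$r / sqrt(cell$ecc)
  sqrt(((u * cp + v * sp) / a)^2 + ((-u * sp + v * cp) / b)^2)
}

#' Render a synthetic brightfield movie with exact ground truth
#'
#' Generates frames, per-frame label masks, a ground-truth table and a lineage
#' table from a [scene_spec()]. Cells move by colony drift plus per-cell
#' jitter, overlaps are resolved by pairwise repulsion, and divisions bud off
#' an adjacent daughter at half the mother's radius which then grows by 5% per
#' frame. Cells whose centre leaves the frame are removed (they have
#' disappeared from the field of view). Ground-truth cells whose centre lies
#' within one radius of the frame edge are flagged facultative, mirroring the
#' usual benchmark convention that algorithms are neither penalised nor
#' rewarded for edge cells.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements `frames` (list of intensity matrices),
#'   `masks` (list of integer label matrices, labels = cell ids),
#'   `truth` (tibble: `frame`, `cell_id`, `x`, `y`, `facultative`),
#'   `lineage` (tibble: `mother_id`, `daughter_id`, `frame`) and `spec`.
#' @export
render_movie <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  local_seed(spec$seed, {
    init <- place_cells(spec)
    n <- spec$n_cells
    cells <- data.frame(
      id = seq_len(n),
      x = init$pos[, 1], y = init$pos[, 2], r = init$r,
      ecc = if (n) runif(n, 1.0, 1.3) else numeric(0),
      phi = if (n) runif(n, 0, pi) else numeric(0),
      grow = rep(FALSE, n)
    )
    next_id <- n + 1L
    frames <- vector("list", spec$n_frames)
    masks <- vector("list", spec$n_frames)
    truth <- vector("list", spec$n_frames)
    lineage <- list()
    h <- spec$frame_shape[1]
    w <- spec$frame_shape[2]
    for (f in seq_len(spec$n_frames) - 1L) {
      if (f > 0) {
        m <- nrow(cells)
        if (m > 0) {
          cells$x <- cells$x + spec$drift[1] + rnorm(m, 0, spec$jitter)
          cells$y <- cells$y + spec$drift[2] + rnorm(m, 0, spec$jitter)
          cells$r <- ifelse(cells$grow,
                            pmin(cells$r * 1.05, spec$r_range[2]), cells$r)
          # divisions
          if (spec$division_prob > 0) {
            divs <- which(runif(m) < spec$division_prob)
            for (i in divs) {
              ang <- runif(1, 0, 2 * pi)
              rd <- cells$r[i] * 0.5
              d0 <- cells$r[i] * 0.9 + rd
              daughter <- data.frame(
                id = next_id,
                x = cells$x[i] + d0 * cos(ang),
                y = cells$y[i] + d0 * sin(ang),
                r = rd, ecc = runif(1, 1.0, 1.3), phi = runif(1, 0, pi),
                grow = TRUE
              )
              lineage[[length(lineage) + 1]] <- tibble::tibble(
                mother_id = cells$id[i], daughter_id = next_id, frame = f
              )
              cells <- rbind(cells, daughter)
              next_id <- next_id + 1L
            }
          }
          pos <- resolve_overlaps(cbind(cells$x, cells$y), cells$r,
                                  spec$frame_shape)
          cells$x <- pos[, 1]
          cells$y <- pos[, 2]
          keep <- cells$x >= 0 & cells$x <= w - 1 &
            cells$y >= 0 & cells$y <= h - 1
          cells <- cells[keep, , drop = FALSE]
        }
      }
      fr <- render_frame(cells, spec)
      frames[[f + 1]] <- fr$img
      masks[[f + 1]] <- fr$mask
      truth[[f + 1]] <- tibble::tibble(
        frame = f,
        cell_id = cells$id,
        x = cells$x,
        y = cells$y,
        facultative = as.integer(
          cells$x < cells$r | cells$y < cells$r |
            (w - 1 - cells$x) < cells$r | (h - 1 - cells$y) < cells$r
        )
      )
    }
    list(
      frames = frames,
      masks = masks,
      truth = dplyr::bind_rows(truth),
      lineage = if (length(lineage)) {
        dplyr::bind_rows(lineage)
      } else {
        tibble::tibble(mother_id = integer(), daughter_id = integer(),
                       frame = integer())
      },
      spec = spec
    )
  })
}

#' Deterministic benchmark suite of synthetic scenes
#'
#' Seven named scenes covering the situations most often met in monolayer
#' yeast movies: sparse isolated cells, a small colony, a colony translating
#' across the field, two dense colonies, two colonies merging, a
#' divisions-heavy scene and one large densely packed colony.
#'
#' @param seed integer; the suite is fully deterministic given the seed.
#' @return Named list of rendered movies (see [render_movie()]).
#' @export
make_benchmark_suite <- function(seed = 1L) {
  seed <- as.integer(seed)
  specs <- list(
    sparse = scene_spec(
      frame_shape = c(256L, 256L), n_cells = 8, n_frames = 5,
      layout = "sparse", jitter = 0.3, seed = seed + 11L
    ),
    small_colony = scene_spec(
      frame_shape = c(256L, 256L), n_cells = 12, n_frames = 5,
      layout = "colony", jitter = 0.3, seed = seed + 22L
    ),
    translating_colony = scene_spec(
      frame_shape = c(256L, 256L), n_cells = 10, n_frames = 8,
      layout = "colony", drift = c(4, 1), jitter = 0.4, seed = seed + 33L
    ),
    two_colonies = scene_spec(
      frame_shape = c(288L, 288L), n_cells = 14, n_frames = 5,
      layout = "two_colonies", jitter = 0.3, seed = seed + 44L
    ),
    merging_colonies = scene_spec(
      frame_shape = c(256L, 256L), n_cells = 14, n_frames = 6,
      layout = "two_colonies", drift = c(2, 0), jitter = 0.5, seed = seed + 55L
    ),
    dividing = scene_spec(
      frame_shape = c(256L, 256L), n_cells = 8, n_frames = 10,
      layout = "colony", division_prob = 0.05, jitter = 0.3, seed = seed + 66L
    ),
    dense = scene_spec(
      frame_shape = c(320L, 320L), n_cells = 35, n_frames = 3,
      layout = "colony", jitter = 0.3, seed = seed + 77L
    )
  )
  movies <- lapply(specs, render_movie)
  names(movies) <- names(specs)
  movies
}
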