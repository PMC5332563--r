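#' Energy parameters for polar active contours
#'
#' The snake energy is `E = E_image + E_shape + E_surface`. `E_image` is a
#' length-normalised line integral of a boundary cost combining edge strength
#' and local brightness. `E_shape` is an area bias around the expected cell
#' area plus a contour-regularity penalty. `E_surface` averages user-chosen
#' interior filters over the snake interior — by default the cell-content
#' image (interiors should look like content) and the cell-border image
#' (interiors should not contain border).
#'
#' @param w_border weight of the `1 - border_image` boundary term.
#' @param w_gradient weight of the `clean` brightness boundary term.
#' @param w_term weight reserved for a line-termination boundary term; unused
#'   by default (0) and kept as an extension slot.
#' @param w_content,w_border_in surface-filter weights for `1 - content_image`
#'   and `border_image` averaged over the interior.
#' @param w_area weight of the quadratic area bias `((A - A_exp)/A_exp)^2`.
#' @param A_exp expected cell area in px^2.
#' @param kappa weight of the circular regularity penalty
#'   `sum((R[j+1] - R[j])^2) / mean(R)^2`.
#' @param r_min,r_max admissible radius range in pixels; `r_max = NULL` uses
#'   `3 * sqrt(A_exp / pi)`.
#' @param n_rays number of equally spaced rays (vertices) of the polygon.
#' @param ray_step radial sampling step in pixels during deformation.
#' @param smooth_passes number of circular moving-average regularisation
#'   passes applied to the per-ray argmin radii.
#' @param max_rel_step clamp on the relative change between adjacent radii.
#' @return An `energy_params` list.
#' @export
energy_params <- function(w_border = 1, w_gradient = 0.5, w_term = 0,
                          w_content = 1, w_border_in = 0.5,
                          w_area = 0.15, A_exp = pi * 10^2, kappa = 0.1,
                          r_min = 2, r_max = NULL, n_rays = 36L,
                          ray_step = 1, smooth_passes = 3,
                          max_rel_step = 0.33) {
  if (is.null(r_max)) {
    r_max <- 3 * sqrt(A_exp / pi)
  }
  stopifnot(r_min > 0, r_min < r_max, ray_step > 0, n_rays >= 8)
  w <- c(w_border, w_gradient, w_term, w_content, w_border_in, w_area, kappa)
  if (any(!is.finite(w))) {
    stop("all energy weights must be finite", call. = FALSE)
  }
  structure(
    list(
      w_border = w_border, w_gradient = w_gradient, w_term = w_term,
      w_content = w_content, w_border_in = w_border_in,
      w_area = w_area, A_exp = A_exp, kappa = kappa,
      r_min = r_min, r_max = r_max, n_rays = as.integer(n_rays),
      ray_step = ray_step, smooth_passes = smooth_passes,
      max_rel_step = max_rel_step
    ),
    class = "energy_params"
  )
}

#' Construct a star-shaped polar snake
#'
#' @param centre `(x, y)` centre in pixels (0-based convention).
#' @param radii numeric vector of `n_rays` positive ray lengths; recycled if
#'   scalar.
#' @param n_rays number of equally spaced rays; defaults to `length(radii)`
#'   when `radii` has length > 1.
#' @return An object of class `snake`.
#' @export
snake <- function(centre, radii, n_rays = NULL) {
  if (is.null(n_rays)) {
    n_rays <- if (length(radii) > 1) length(radii) else 36L
  }
  n_rays <- as.integer(n_rays)
  if (n_rays < 8) {
    stop("a snake needs at least 8 rays", call. = FALSE)
  }
  radii <- rep_len(as.numeric(radii), n_rays)
  if (any(radii <= 0)) {
    stop("all radii must be positive", call. = FALSE)
  }
  structure(
    list(
      centre = as.numeric(centre),
      angles = (seq_len(n_rays) - 1) * 2 * pi / n_rays,
      radii = radii,
      energy_image = NA_real_, energy_shape = NA_real_,
      energy_surface = NA_real_, energy_total = NA_real_,
      rank = NA_real_, degenerate = FALSE
    ),
    class = "snake"
  )
}

#' Polygon vertices of a snake
#'
#' @param s a [snake()].
#' @return An `n_rays` x 2 matrix of `(x, y)` vertices.
#' @export
snake_vertices <- function(s) {
  cbind(
    s$centre[1] + s$radii * cos(s$angles),
    s$centre[2] + s$radii * sin(s$angles)
  )
}

#' Area and centroid of a snake polygon (shoelace formula)
#'
#' @param s a [snake()].
#' @return List with `area` (px^2) and `centroid` `(x, y)`.
#' @export
snake_geometry <- function(s) {
  polygon_area_centroid(snake_vertices(s))
}

# Exact star-polygon rasterisation: a pixel is inside iff its distance from
# the centre does not exceed the polygon boundary (the chord between adjacent
# vertices) along the pixel's angle. Returns linear indices into a matrix of
# dim `shape` plus the pixel count.
snake_interior <- function(s, shape) {
  n <- length(s$angles)
  dth <- 2 * pi / n
  rmax <- max(s$radii)
  x0 <- max(0, floor(s$centre[1] - rmax))
  x1 <- min(shape[2] - 1, ceiling(s$centre[1] + rmax))
  y0 <- max(0, floor(s$centre[2] - rmax))
  y1 <- min(shape[1] - 1, ceiling(s$centre[2] + rmax))
  if (x1 < x0 || y1 < y0) {
    return(integer(0))
  }
  xs <- rep(x0:x1, each = y1 - y0 + 1)
  ys <- rep(y0:y1, times = x1 - x0 + 1)
  dx <- xs - s$centre[1]
  dy <- ys - s$centre[2]
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx) %% (2 * pi)
  j <- pmin(floor(phi / dth), n - 1)             # segment index, 0-based
  r1 <- s$radii[j + 1]
  r2 <- s$radii[(j + 1) %% n + 1]
  th1 <- j * dth
  # chord between polar points (r1, th1) and (r2, th1 + dth)
  denom <- r2 * sin(th1 + dth - phi) + r1 * sin(phi - th1)
  rb <- ifelse(denom > 1e-12, r1 * r2 * sin(dth) / denom, 0)
  inside <- r <= rb
  (xs[inside]) * shape[1] + (ys[inside] + 1)     # column-major linear index
}

#' Boundary (image) energy of a snake
#'
#' Length-normalised line integral along the polygon of the boundary cost
#' `w_border * (1 - border_image) + w_gradient * clean`; minimal when the
#' contour follows strong edges over the dark cell rim.
#'
#' @param s a [snake()].
#' @param helpers a [compute_helpers()] result.
#' @param params an [energy_params()].
#' @return Scalar energy.
#' @export
energy_image <- function(s, helpers, params = energy_params()) {
  v <- snake_vertices(s)
  n <- nrow(v)
  vn <- v[c(2:n, 1), , drop = FALSE]
  seg_len <- sqrt(rowSums((vn - v)^2))
  total <- sum(seg_len)
  if (total <= 1e-9) {
    stop("zero-length contour", call. = FALSE)
  }
  if (params$w_border == 0 && params$w_gradient == 0) {
    return(0)
  }
  # sample each edge proportionally to its length
  acc <- 0
  for (e in seq_len(n)) {
    m <- max(2L, ceiling(seg_len[e]))
    t <- (seq_len(m) - 0.5) / m
    px <- v[e, 1] + t * (vn[e, 1] - v[e, 1])
    py <- v[e, 2] + t * (vn[e, 2] - v[e, 2])
    px <- pmin(pmax(px, 0), helpers$shape[2] - 1)   # clip to image bounds
    py <- pmin(pmax(py, 0), helpers$shape[1] - 1)
    b <- sample_bilinear(helpers$border_image, px, py)
    cl <- sample_bilinear(helpers$clean, px, py)
    cost <- params$w_border * (1 - b) + params$w_gradient * cl
    acc <- acc + mean(cost) * seg_len[e]
  }
  acc / total
}

#' Shape (internal) energy of a snake
#'
#' `w_area * ((A - A_exp)/A_exp)^2` biases snakes towards the expected cell
#' area; `kappa * sum((R[j+1] - R[j])^2)/mean(R)^2` (circular index) penalises
#' irregular contours.
#'
#' @inheritParams energy_image
#' @return Scalar energy.
#' @export
energy_shape <- function(s, params = energy_params()) {
  a <- snake_geometry(s)$area
  r <- s$radii
  reg <- sum((c(r[-1], r[1]) - r)^2) / mean(r)^2
  params$w_area * ((a - params$A_exp) / params$A_exp)^2 + params$kappa * reg
}

#' Surface (interior) energy of a snake
#'
#' Mean over the interior pixels of `w_content * (1 - content_image) +
#' w_border_in * border_image`: interiors should look like cell content and
#' should not contain cell border.
#'
#' @inheritParams energy_image
#' @return Scalar energy.
#' @export
energy_surface <- function(s, helpers, params = energy_params()) {
  if (params$w_content == 0 && params$w_border_in == 0) {
    return(0)
  }
  idx <- snake_interior(s, helpers$shape)
  if (length(idx) == 0) {
    stop("snake interior rasterises to zero pixels", call. = FALSE)
  }
  mean(
    params$w_content * (1 - helpers$content_image[idx]) +
      params$w_border_in * helpers$border_image[idx]
  )
}

# Fill in all exact energy components (and total) of a snake.
evaluate_snake <- function(s, helpers, params) {
  s$energy_image <- energy_image(s, helpers, params)
  s$energy_shape <- energy_shape(s, params)
  s$energy_surface <- energy_surface(s, helpers, params)
  s$energy_total <- s$energy_image + s$energy_shape + s$energy_surface
  s
}

# Approximate per-ray energy profiles: one matrix (n_rays x n_steps) whose
# [j, m] entry is the 1-D energy of putting ray j's radius at step m.
# boundary cost at the tip + running interior mean along the ray + a per-ray
# area bias that treats the snake as a circle of that radius.
ray_energy_profiles <- function(seed, helpers, params) {
  n <- params$n_rays
  steps <- seq(params$r_min, params$r_max, by = params$ray_step)
  m <- length(steps)
  ang <- (seq_len(n) - 1) * 2 * pi / n
  px <- outer(cos(ang), steps) + seed[1]          # n x m
  py <- outer(sin(ang), steps) + seed[2]
  ok <- in_bounds(helpers$shape, px, py)
  b <- matrix(sample_bilinear(helpers$border_image, px, py), n, m)
  cl <- matrix(sample_bilinear(helpers$clean, px, py), n, m)
  ct <- matrix(sample_bilinear(helpers$content_image, px, py), n, m)
  line_cost <- params$w_border * (1 - b) + params$w_gradient * cl
  interior <- params$w_content * (1 - ct) + params$w_border_in * b
  interior[!ok] <- 0
  run_mean <- t(apply(interior, 1, cumsum)) /
    matrix(seq_len(m), n, m, byrow = TRUE)
  area_bias <- params$w_area * ((pi * steps^2 - params$A_exp) /
                                  params$A_exp)^2
  e <- line_cost + run_mean + matrix(area_bias, n, m, byrow = TRUE)
  e[!ok] <- Inf
  list(energy = e, steps = steps)
}

# Circular moving average (window 3) plus relative-step clamp; keeps the
# star-shape invariant since radii stay positive and within [r_min, r_max].
regularize_radii <- function(r, params) {
  n <- length(r)
  for (pass in seq_len(params$smooth_passes)) {
    r <- (c(r[n], r[-n]) + r + c(r[-1], r[1])) / 3
    lim <- 1 + params$max_rel_step
    for (j in seq_len(n)) {                       # forward clamp (circular)
      nxt <- j %% n + 1
      r[nxt] <- min(max(r[nxt], r[j] / lim), r[j] * lim)
    }
    for (j in rev(seq_len(n))) {                  # backward clamp
      prv <- if (j == 1) n else j - 1
      r[prv] <- min(max(r[prv], r[j] / lim), r[j] * lim)
    }
    r <- pmin(pmax(r, params$r_min), params$r_max)
  }
  r
}

#' Grow a snake from a seed by per-ray energy minimisation
#'
#' Rays are cast from the fixed seed (the polygon centre never moves); along
#' each ray a 1-D approximation of the snake energy is evaluated in a single
#' cumulative pass and the minimising radius selected (ties towards the
#' smaller radius). The raw radii are then regularised by circular smoothing
#' with a bounded relative step between adjacent rays, and the exact energy
#' components of the final contour are computed.
#'
#' If at least half the rays have no admissible radius (they leave the image
#' immediately), the snake is flagged `degenerate` so that ranking can discard
#' it.
#'
#' @param seed `(x, y)` seed position inside the image.
#' @param helpers a [compute_helpers()] result.
#' @param params an [energy_params()].
#' @return A [snake()] with energies filled in; attribute `"radii_raw"` holds
#'   the pre-regularisation per-ray argmin radii.
#' @export
deform <- function(seed, helpers, params = energy_params()) {
  seed <- as.numeric(seed)
  if (!in_bounds(helpers$shape, seed[1], seed[2])) {
    stop("seed lies outside the image", call. = FALSE)
  }
  prof <- ray_energy_profiles(seed, helpers, params)
  e <- prof$energy
  n <- nrow(e)
  bad_ray <- !is.finite(apply(e, 1, min))
  raw <- numeric(n)
  for (j in seq_len(n)) {
    raw[j] <- if (bad_ray[j]) {
      params$r_min
    } else {
      prof$steps[which.min(e[j, ])]               # which.min: first min = smaller radius
    }
  }
  s <- snake(seed, pmin(pmax(raw, params$r_min), params$r_max), n)
  s$radii <- regularize_radii(s$radii, params)
  s$degenerate <- sum(bad_ray) >= n / 2
  if (!s$degenerate) {
    s <- evaluate_snake(s, helpers, params)
  }
  attr(s, "radii_raw") <- raw
  s
}

#' @export
print.snake <- function(x, ...) {
  cat(sprintf(
    "<snake> centre (%.1f, %.1f), %d rays, mean radius %.2f px%s\n",
    x$centre[1], x$centre[2], length(x$radii), mean(x$radii),
    if (isTRUE(x$degenerate)) " [degenerate]" else ""
  ))
  if (is.finite(x$energy_total)) {
    cat(sprintf(
      "  E = %.4f (image %.4f + shape %.4f + surface %.4f)\n",
      x$energy_total, x$energy_image, x$energy_shape, x$energy_surface
    ))
  }
  invisible(x)
}

#' @rdname tidy.sa_fit
#' @exportS3Method generics::tidy
tidy.snake <- function(x, ...) {
  vx <- x$centre[1] + x$radii * cos(x$angles)
  vy <- x$centre[2] + x$radii * sin(x$angles)
  tibble::tibble(
    ray = seq_along(x$radii),
    angle = x$angles,
    radius = x$radii,
    x = vx,
    y = vy
  )
}

#' @rdname tidy.sa_fit
#' @exportS3Method generics::glance
glance.snake <- function(x, ...) {
  g <- snake_geometry(x)
  s <- x                                          # avoid data-mask capture
  tibble::tibble(
    x = s$centre[1], y = s$centre[2], area = g$area,
    mean_radius = mean(s$radii),
    energy_image = s$energy_image, energy_shape = s$energy_shape,
    energy_surface = s$energy_surface, energy_total = s$energy_total,
    degenerate = s$degenerate
  )
}
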