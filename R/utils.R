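# Internal geometry and image helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Seeds R's RNG, runs `code`, and restores the previous RNG state so that
#' package functions never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Bilinear interpolation of a matrix at 0-based (x, y) points.
# Points outside the image return NA.
sample_bilinear <- function(img, x, y) {
  h <- nrow(img)
  w <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  if (!any(ok)) {
    return(out)
  }
  xs <- x[ok]
  ys <- y[ok]
  x0 <- pmin(floor(xs), w - 2)
  y0 <- pmin(floor(ys), h - 2)
  x0 <- pmax(x0, 0)
  y0 <- pmax(y0, 0)
  fx <- xs - x0
  fy <- ys - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1)
  i11 <- cbind(y0 + 2, x0 + 2)
  out[ok] <- img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
  out
}

# Is a 0-based (x, y) point inside the image?
in_bounds <- function(shape, x, y) {
  x >= 0 & x <= shape[2] - 1 & y >= 0 & y <= shape[1] - 1
}

# Euclidean distance matrix between two 2-column (x, y) matrices.
dist_xy <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(matrix(numeric(0), nrow(a), nrow(b)))
  }
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx^2 + dy^2)
}

# Shoelace area and centroid of a closed polygon given as (x, y) vertex matrix.
polygon_area_centroid <- function(v) {
  x <- v[, 1]
  y <- v[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) {
    return(list(area = 0, centroid = c(mean(x), mean(y))))
  }
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  list(area = abs(a), centroid = c(cx, cy))
}

as_matrix_img <- function(x) {
  # EBImage operations return Image objects; collapse back to a plain matrix.
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}
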