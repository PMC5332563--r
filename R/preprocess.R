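#' Preprocessing parameters
#'
#' @param bg_radius radius (pixels) of the structuring disc used for the
#'   background estimate; must exceed the largest expected cell radius.
#' @param bg_sigma Gaussian smoothing sigma applied to the background field.
#' @param edge_sigma smoothing sigma applied before edge detection.
#' @param content_sigma smoothing sigma for the cell-content image.
#' @param min_contrast darkness (background minus raw) below which a pixel can
#'   never be foreground; guards the Otsu threshold against structure-free
#'   images.
#' @param min_obj_area connected foreground components smaller than this many
#'   pixels are discarded.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(bg_radius = 16, bg_sigma = 4, edge_sigma = 1,
                              content_sigma = 2, min_contrast = 0.08,
                              min_obj_area = 30) {
  if (bg_radius <= 0) {
    stop("`bg_radius` must be positive", call. = FALSE)
  }
  structure(
    list(
      bg_radius = bg_radius, bg_sigma = bg_sigma, edge_sigma = edge_sigma,
      content_sigma = content_sigma, min_contrast = min_contrast,
      min_obj_area = min_obj_area
    ),
    class = "preprocess_params"
  )
}

disc_brush <- function(radius) {
  size <- 2L * as.integer(ceiling(radius)) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

#' Estimate the smooth background of a brightfield frame
#'
#' Cells appear darker than the background, so the background is recovered by
#' grey-scale morphological closing with a disc larger than any cell (which
#' fills the dark cell bodies) followed by Gaussian smoothing.
#'
#' @param raw numeric matrix in `[0, 1]`.
#' @param radius structuring disc radius in pixels; must exceed the largest
#'   expected cell radius.
#' @param sigma smoothing sigma for the final field.
#' @return A numeric matrix, same shape as `raw`.
#' @export
estimate_background <- function(raw, radius = 16, sigma = 4) {
  check_raw(raw)
  if (!is.numeric(radius) || radius <= 0) {
    stop("`radius` must be a positive number", call. = FALSE)
  }
  closed <- as_matrix_img(EBImage::closing(raw, disc_brush(radius)))
  if (sigma > 0) {
    closed <- as_matrix_img(EBImage::gblur(closed, sigma = sigma))
  }
  closed
}

check_raw <- function(raw) {
  if (!is.matrix(raw) || !is.numeric(raw)) {
    stop("`raw` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(raw) < 16 || ncol(raw) < 16) {
    stop("image must be at least 16 x 16 pixels", call. = FALSE)
  }
  if (min(raw) < -1e-9 || max(raw) > 1 + 1e-9) {
    stop("intensities must be normalised to [0, 1]", call. = FALSE)
  }
  invisible(raw)
}

#' Compute the helper images used by seeding and the snake energy
#'
#' From one raw frame derives: the smooth `background`; the background-
#' subtracted `clean` image (re-centred at 0.5 and clipped to `[0, 1]`); a
#' boolean `foreground_mask` of pixels significantly darker than the
#' background (Otsu threshold on the darkness image, hole filling, small
#' component removal); a `border_image` of edge strength (Sobel gradient
#' magnitude of the smoothed clean image, rescaled to `[0, 1]`); and a
#' `content_image` of interior likelihood (smoothed darkness restricted to the
#' foreground, rescaled to `[0, 1]`).
#'
#' A structure-free (near-constant) image yields an all-background mask and
#' zero border/content images rather than an error.
#'
#' @param raw numeric matrix in `[0, 1]`.
#' @param params a [preprocess_params()].
#' @return An object of class `helper_images`: list with `raw`, `background`,
#'   `clean`, `foreground_mask` (logical matrix), `border_image`,
#'   `content_image` and `shape`.
#' @export
compute_helpers <- function(raw, params = preprocess_params()) {
  check_raw(raw)
  background <- estimate_background(raw, params$bg_radius, params$bg_sigma)
  clean <- clamp01(raw - background + 0.5)
  darkness <- pmax(background - raw, 0)

  fg <- matrix(FALSE, nrow(raw), ncol(raw))
  if (max(darkness) > params$min_contrast) {
    thr <- EBImage::otsu(darkness, range = c(0, max(darkness)))
    thr <- max(thr, params$min_contrast)
    fg_img <- EBImage::fillHull(darkness > thr)
    lab <- EBImage::bwlabel(fg_img)
    lab_m <- as_matrix_img(lab)
    sizes <- tabulate(lab_m[lab_m > 0])
    keep <- which(sizes >= params$min_obj_area)
    fg <- matrix(lab_m %in% keep, nrow(raw), ncol(raw))
  }

  sm <- if (params$edge_sigma > 0) {
    as_matrix_img(EBImage::gblur(clean, sigma = params$edge_sigma))
  } else {
    clean
  }
  gx <- sobel_filter(sm, t(sobel_kernel()))
  gy <- sobel_filter(sm, sobel_kernel())
  border <- sqrt(gx^2 + gy^2)
  if (max(border) > 0) {
    border <- border / max(border)
  }

  content <- as_matrix_img(EBImage::gblur(darkness,
                                          sigma = params$content_sigma))
  content[!fg] <- 0
  if (max(content) > 0) {
    content <- content / max(content)
  }

  structure(
    list(
      raw = raw, background = background, clean = clean,
      foreground_mask = fg, border_image = border, content_image = content,
      shape = dim(raw)
    ),
    class = "helper_images"
  )
}

sobel_kernel <- function() {
  matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE) / 8
}

sobel_filter <- function(img, k) {
  as_matrix_img(EBImage::filter2(img, k))
}

#' @export
print.helper_images <- function(x, ...) {
  cat(sprintf(
    "<helper_images> %d x %d px, foreground %.1f%%\n",
    x$shape[1], x$shape[2], 100 * mean(x$foreground_mask)
  ))
  invisible(x)
}
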