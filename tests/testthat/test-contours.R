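test_that("snake construction enforces its invariants", {
  expect_error(snake(c(10, 10), 5, n_rays = 4), "at least 8")
  expect_error(snake(c(10, 10), c(5, -1, 5, 5, 5, 5, 5, 5)), "positive")
  s <- snake(c(10, 10), 5, n_rays = 12)
  expect_length(s$radii, 12)
  expect_equal(diff(s$angles), rep(2 * pi / 12, 11))
})

test_that("snake geometry matches closed forms for a circle", {
  s <- snake(c(30, 30), 10, n_rays = 360)
  g <- snake_geometry(s)
  expect_equal(g$area, pi * 100, tolerance = 1e-3)
  expect_equal(g$centroid, c(30, 30), tolerance = 1e-9)
})

test_that("energy decomposition is exact and zero weights give zero terms", {
  mv <- one_cell_movie(radius = 10, seed = 2)
  h <- compute_helpers(mv$frames[[1]])
  p <- energy_params()
  s <- deform(c(mv$truth$x, mv$truth$y), h, p)
  expect_equal(s$energy_total,
               s$energy_image + s$energy_shape + s$energy_surface)
  p0 <- energy_params(w_border = 0, w_gradient = 0)
  expect_equal(energy_image(s, h, p0), 0)
  p1 <- energy_params(w_content = 0, w_border_in = 0)
  expect_equal(energy_surface(s, h, p1), 0)
})

test_that("the boundary energy is length-normalised and edge-seeking", {
  # uniform image: any radius gives the same value
  h <- fake_helpers(border = 0.3, clean = 0.6)
  p <- energy_params()
  e1 <- energy_image(snake(c(32, 32), 5), h, p)
  e2 <- energy_image(snake(c(32, 32), 15), h, p)
  expect_equal(e1, e2, tolerance = 1e-9)
  # on a real cell, the contour on the rim beats one 3 px inside
  mv <- one_cell_movie(radius = 10, seed = 2)
  hh <- compute_helpers(mv$frames[[1]])
  ctr <- c(mv$truth$x, mv$truth$y)
  expect_lt(energy_image(snake(ctr, 10), hh, p),
            energy_image(snake(ctr, 7), hh, p))
})

test_that("zero-length contours are rejected", {
  h <- fake_helpers()
  s <- snake(c(32, 32), 5)
  s$radii <- rep(1e-12, length(s$radii))
  expect_error(energy_image(s, h, energy_params()), "zero-length")
})

test_that("the shape energy penalises area deviation and irregularity", {
  p <- energy_params(A_exp = pi * 100, w_area = 0.15, kappa = 0.1)
  circ <- snake(c(50, 50), 10, n_rays = 360)
  expect_lt(energy_shape(circ, p), 1e-3)          # regularity exactly 0
  expect_equal(sum((diff(c(circ$radii, circ$radii[1])))^2), 0)
  big <- snake(c(50, 50), 20, n_rays = 360)       # area 4 x expected
  expect_gt(energy_shape(big, p), energy_shape(circ, p))
  # alternating radii r, 2r: closed form of the circular regularity sum
  n <- 12
  alt <- snake(c(50, 50), rep(c(5, 10), 6), n_rays = n)
  reg_expected <- n * 25 / 7.5^2                  # n steps of (2r-r)^2 / mean^2
  p_reg <- energy_params(w_area = 0, kappa = 1)
  expect_equal(energy_shape(alt, p_reg), reg_expected, tolerance = 1e-9)
})

test_that("the surface energy prefers content-filled interiors", {
  mv <- one_cell_movie(radius = 10, seed = 2)
  h <- compute_helpers(mv$frames[[1]])
  ctr <- c(mv$truth$x, mv$truth$y)
  p <- energy_params(w_content = 1, w_border_in = 1)
  on_cell <- energy_surface(snake(ctr, 9), h, p)
  on_bg <- energy_surface(snake(ctr + c(40, 0), 9), h, p)
  expect_lt(on_cell, on_bg)
  # an ideal interior scores exactly zero
  ideal <- fake_helpers(border = 0, content = 1)
  expect_equal(energy_surface(snake(c(32, 32), 8), ideal, p), 0)
})

test_that("deform recovers the radius of an ideal cell", {
  mv <- one_cell_movie(radius = 10, seed = 2)
  h <- compute_helpers(mv$frames[[1]])
  s <- deform(c(mv$truth$x, mv$truth$y), h)
  expect_false(s$degenerate)
  r_true <- sqrt(sum(mv$masks[[1]] > 0) / pi)
  expect_lt(abs(mean(s$radii) - r_true), 1.5)
})

test_that("snakes grown on empty background fail the ranking filter", {
  mv <- one_cell_movie(radius = 10, seed = 2)
  h <- compute_helpers(mv$frames[[1]])
  far <- c(mv$truth$x + 50, mv$truth$y)           # empty background
  s <- deform(far, h)
  dets <- rank_and_filter(list(s), h)
  expect_equal(nrow(dets), 0)
})

test_that("pre-regularisation radii equal exhaustive per-ray minimisation", {
  mv <- one_cell_movie(radius = 8, seed = 17, frame_shape = c(96L, 96L))
  h <- compute_helpers(mv$frames[[1]])
  p <- energy_params(n_rays = 12, r_min = 2, ray_step = 2, r_max = 10.5,
                     A_exp = pi * 64)
  seed <- c(mv$truth$x, mv$truth$y)
  s <- deform(seed, h, p)
  # independent oracle: evaluate the 1-D profile ray by ray, step by step
  steps <- seq(2, 10.5, by = 2)
  for (j in 1:12) {
    ang <- (j - 1) * 2 * pi / 12
    costs <- vapply(seq_along(steps), function(m) {
      r <- steps[m]
      px <- seed[1] + cos(ang) * steps[1:m]
      py <- seed[2] + sin(ang) * steps[1:m]
      tip_b <- starseg:::sample_bilinear(h$border_image, px[m], py[m])
      tip_c <- starseg:::sample_bilinear(h$clean, px[m], py[m])
      ct <- starseg:::sample_bilinear(h$content_image, px, py)
      bb <- starseg:::sample_bilinear(h$border_image, px, py)
      p$w_border * (1 - tip_b) + p$w_gradient * tip_c +
        mean(p$w_content * (1 - ct) + p$w_border_in * bb) +
        p$w_area * ((pi * r^2 - p$A_exp) / p$A_exp)^2
    }, numeric(1))
    expect_equal(attr(s, "radii_raw")[j], steps[which.min(costs)])
  }
})

test_that("regularised radii respect bounds and the star-shape invariant", {
  mv <- render_movie(scene_spec(n_cells = 6, n_frames = 1,
                                layout = "colony", seed = 19))
  h <- compute_helpers(mv$frames[[1]])
  p <- energy_params()
  tr <- mv$truth
  for (i in seq_len(nrow(tr))) {
    s <- deform(c(tr$x[i], tr$y[i]), h, p)
    expect_true(all(s$radii >= p$r_min - 1e-9))
    expect_true(all(s$radii <= p$r_max + 1e-9))
    expect_true(all(s$radii > 0))                 # star-shaped by construction
  }
})

test_that("deformation is covariant under a 90-degree image rotation", {
  mv <- one_cell_movie(radius = 10, seed = 2)
  img <- mv$frames[[1]]
  ctr <- c(mv$truth$x, mv$truth$y)
  rot90 <- function(m) t(m)[ncol(m):1, ]          # counter-clockwise
  h1 <- compute_helpers(img)
  h2 <- compute_helpers(rot90(img))
  s1 <- deform(ctr, h1)
  w <- ncol(img)
  s2 <- deform(c(ctr[2], w - 1 - ctr[1]), h2)     # rotated seed
  shift <- length(s1$radii) / 4                   # 90 degrees of rays
  r_back <- c(s2$radii[(shift + 1):length(s2$radii)],
              s2$radii[seq_len(shift)])
  expect_lt(max(abs(r_back - s1$radii)), 1)
})

test_that("tidy and glance summarise snakes", {
  s <- snake(c(10, 12), 5, n_rays = 16)
  td <- tidy(s)
  expect_equal(nrow(td), 16)
  expect_named(td, c("ray", "angle", "radius", "x", "y"))
  g <- glance(s)
  expect_equal(g$x, 10)
  expect_true(is.na(g$energy_total))
})
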