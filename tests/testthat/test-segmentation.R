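test_that("border-minima seeding finds well-separated cells", {
  mv <- render_movie(scene_spec(n_cells = 3, n_frames = 1,
                                layout = "sparse", seed = 21))
  h <- compute_helpers(mv$frames[[1]])
  seeds <- seeds_border_minima(h)
  expect_equal(nrow(seeds), 3)
  tr <- mv$truth
  d <- starseg:::dist_xy(cbind(seeds$x, seeds$y), cbind(tr$x, tr$y))
  expect_lt(max(apply(d, 1, min)), 3)
})

test_that("seeding returns nothing on an empty foreground", {
  h <- compute_helpers(matrix(0.5, 64, 64))
  expect_equal(nrow(seeds_border_minima(h)), 0)
  expect_equal(nrow(seeds_content_maxima(h)), 0)
})

test_that("seeds closer than min_seed_dist are merged", {
  bi <- matrix(1, 64, 64)
  bi[cbind(c(31, 31), c(30, 32))] <- 0.2          # two dips 2 px apart
  h <- fake_helpers(shape = c(64L, 64L), border = bi, content = 0,
                    clean = 0.5, fg = TRUE)
  seeds <- seeds_border_minima(h, seg_params(min_seed_dist = 5,
                                             seed_sigma = 1))
  expect_equal(nrow(seeds), 1)
})

test_that("re-seeding excludes covered areas", {
  mv <- render_movie(scene_spec(n_cells = 3, n_frames = 1,
                                layout = "sparse", seed = 21))
  h <- compute_helpers(mv$frames[[1]])
  tr <- mv$truth
  p <- seg_params()
  # detect 2 of the 3 cells
  two <- lapply(1:2, function(i) deform(c(tr$x[i], tr$y[i]), h, p$energy))
  accepted <- rank_and_filter(two, h, p)
  expect_equal(nrow(accepted), 2)
  seeds <- seeds_excluding_covered(h, accepted, p)
  # at least one seed inside the missing cell, none inside covered cells
  m3 <- mv$masks[[1]] == tr$cell_id[3]
  hit <- m3[cbind(round(seeds$y) + 1, round(seeds$x) + 1)]
  expect_gte(sum(hit), 1)
  cov <- starseg:::covered_mask(accepted, h$shape)
  expect_false(any(cov[cbind(round(seeds$y) + 1, round(seeds$x) + 1)]))
  # with nothing accepted, masking is the identity: border minima reappear
  s0 <- seeds_border_minima(h, p)
  s_all <- seeds_excluding_covered(h, accepted = NULL, p)
  expect_true(all(paste(s0$x, s0$y) %in% paste(s_all$x, s_all$y)))
  # fully covered foreground yields nothing
  all_three <- rank_and_filter(
    lapply(1:3, function(i) deform(c(tr$x[i], tr$y[i]), h, p$energy)), h, p
  )
  h_cov <- h
  h_cov$foreground_mask <- starseg:::covered_mask(all_three, h$shape)
  expect_equal(nrow(seeds_excluding_covered(h_cov, all_three, p)), 0)
})

test_that("seed relocation moves towards the true centre", {
  mv <- one_cell_movie(radius = 10, seed = 23)
  h <- compute_helpers(mv$frames[[1]])
  ctr <- c(mv$truth$x, mv$truth$y)
  # a circle snake relocates to its own centre
  circ <- snake(ctr, 8)
  expect_equal(unlist(relocate_seed(circ)[, c("x", "y")]),
               c(x = ctr[1], y = ctr[2]), tolerance = 1e-9)
  # an off-centre seed's contour centroid is closer to the truth
  off <- ctr + c(5, -4)
  s <- deform(off, h)
  rs <- relocate_seed(s)
  expect_lt(sqrt((rs$x - ctr[1])^2 + (rs$y - ctr[2])^2),
            sqrt(sum((off - ctr)^2)))
  expect_equal(rs$origin, "centroid_relocation")
  # centroid agrees with an independent shoelace computation
  irregular <- snake(ctr, c(4, 6, 8, 5, 7, 9, 4, 6, 8, 5, 7, 9), n_rays = 12)
  v <- snake_vertices(irregular)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- sum(x * yn - xn * y) / 2
  cx <- sum((x + xn) * (x * yn - xn * y)) / (6 * a)
  cy <- sum((y + yn) * (x * yn - xn * y)) / (6 * a)
  rs2 <- relocate_seed(irregular)
  expect_equal(c(rs2$x, rs2$y), c(cx, cy), tolerance = 1e-9)
  # degenerate snakes cannot be relocated
  bad <- snake(ctr, 5)
  bad$degenerate <- TRUE
  expect_error(relocate_seed(bad), "degenerate")
})

test_that("ranking keeps one snake per cell and drops background snakes", {
  mv <- render_movie(scene_spec(n_cells = 2, n_frames = 1,
                                layout = "sparse", seed = 25))
  h <- compute_helpers(mv$frames[[1]])
  tr <- mv$truth
  p <- seg_params()
  s1 <- deform(c(tr$x[1], tr$y[1]), h, p$energy)
  s2 <- deform(c(tr$x[2], tr$y[2]), h, p$energy)
  # two identical snakes on one cell: one survives
  expect_equal(nrow(rank_and_filter(list(s1, s1), h, p)), 1)
  # 5 candidates on 2 cells (3 redundant): exactly 2 accepted
  s1b <- deform(c(tr$x[1] + 2, tr$y[1]), h, p$energy)
  s1c <- deform(c(tr$x[1] - 2, tr$y[1] + 1), h, p$energy)
  dets <- rank_and_filter(list(s1, s1b, s1c, s2, s2), h, p)
  expect_equal(nrow(dets), 2)
  d <- starseg:::dist_xy(cbind(dets$x, dets$y), cbind(tr$x, tr$y))
  expect_lt(max(apply(d, 2, min)), 3)
})

test_that("accepted detections never overlap beyond the threshold", {
  mv <- render_movie(scene_spec(n_cells = 15, n_frames = 1,
                                layout = "colony", seed = 27))
  p <- seg_params()
  dets <- segment_frame(mv$frames[[1]], p, seed = 1)
  ints <- lapply(dets$polygon, starseg:::snake_interior,
                 shape = dim(mv$frames[[1]]))
  if (nrow(dets) >= 2) {
    for (i in seq_len(nrow(dets) - 1)) {
      for (j in (i + 1):nrow(dets)) {
        ov <- length(intersect(ints[[i]], ints[[j]])) /
          min(length(ints[[i]]), length(ints[[j]]))
        expect_lte(ov, p$overlap_frac)
      }
    }
  }
})

test_that("segmenting a blank frame returns no detections", {
  dets <- segment_frame(matrix(0.6, 64, 64), seed = 1)
  expect_equal(nrow(dets), 0)
})

test_that("a crowded frame is segmented accurately", {
  mv <- render_movie(scene_spec(n_cells = 20, n_frames = 1,
                                layout = "colony", seed = 31,
                                frame_shape = c(288L, 288L)))
  dets <- segment_frame(mv$frames[[1]], seed = 1)
  rep <- segmentation_metrics(mv$truth, as_result(dets), max_dist = 5)
  expect_gte(rep$summary$f_measure, 0.95)
  # seeding from (slightly shifted) true detections cannot hurt
  prev <- tibble::tibble(x = mv$truth$x + 1, y = mv$truth$y,
                         label = seq_len(nrow(mv$truth)))
  dets_p <- segment_frame(mv$frames[[1]], prev = prev, seed = 1)
  rep_p <- segmentation_metrics(mv$truth, as_result(dets_p), max_dist = 5)
  expect_gte(rep_p$summary$f_measure, rep$summary$f_measure)
})

test_that("segmentation is deterministic under a fixed seed", {
  mv <- render_movie(scene_spec(n_cells = 8, n_frames = 1,
                                layout = "colony", seed = 33))
  d1 <- segment_frame(mv$frames[[1]], seed = 7)
  d2 <- segment_frame(mv$frames[[1]], seed = 7)
  expect_identical(d1[, c("frame", "label", "x", "y", "area", "rank")],
                   d2[, c("frame", "label", "x", "y", "area", "rank")])
})

test_that("labels are contiguous and ordered by rank", {
  mv <- render_movie(scene_spec(n_cells = 10, n_frames = 1,
                                layout = "colony", seed = 35))
  dets <- segment_frame(mv$frames[[1]], seed = 1)
  expect_equal(dets$label, seq_len(nrow(dets)))
  expect_true(!is.unsorted(dets$rank))
})
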