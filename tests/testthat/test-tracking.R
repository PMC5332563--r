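test_that("association costs follow the distance + shape formula", {
  fs <- c(100L, 100L)
  p <- track_params(d_max = 50, lambda_s = 1)
  # two 100 px^2 cells 10 px apart: cost 10/50 + 0 = 0.2
  A <- tibble::tibble(x = 40, y = 40, area = 100)
  B <- tibble::tibble(x = 50, y = 40, area = 100)
  C <- build_cost_matrix(A, B, fs, p)
  expect_equal(C$assoc[1, 1], 0.2)
  # identical lists give a zero diagonal
  D <- random_detections(5)
  CD <- build_cost_matrix(D, D, fs, track_params())
  expect_equal(diag(CD$assoc), rep(0, 5))
  # beyond d_max the association is forbidden
  Bfar <- tibble::tibble(x = 95, y = 95, area = 100)
  expect_equal(build_cost_matrix(A, Bfar, fs, p)$assoc[1, 1], Inf)
  # appearance at a corner is cheaper than at the centre
  corner <- tibble::tibble(x = 0, y = 0, area = 100)
  centre <- tibble::tibble(x = 49.5, y = 49.5, area = 100)
  c1 <- build_cost_matrix(A, corner, fs, p)$appear
  c2 <- build_cost_matrix(A, centre, fs, p)$appear
  expect_lt(c1, c2)
})

test_that("the assignment solver matches hand-enumerated optima", {
  C <- structure(
    list(assoc = matrix(c(1, 2, 2, 1), 2, 2),
         appear = c(100, 100), disappear = c(100, 100)),
    class = "cost_matrix"
  )
  a <- solve_assignment(C)
  expect_equal(a$pairs, matrix(c(1L, 2L, 1L, 2L), 2, 2,
                               dimnames = list(NULL, c("a", "b"))))
  expect_equal(a$cost, 2)
  # all associations forbidden: everything appears/disappears
  C2 <- structure(
    list(assoc = matrix(Inf, 2, 3), appear = c(1, 1, 1),
         disappear = c(1, 1)),
    class = "cost_matrix"
  )
  a2 <- solve_assignment(C2)
  expect_equal(nrow(a2$pairs), 0)
  expect_equal(sort(a2$appearing), 1:3)
  expect_equal(sort(a2$disappearing), 1:2)
  expect_equal(a2$cost, 5)
  # empty frames are fine
  e <- tibble::tibble(x = numeric(0), y = numeric(0), area = numeric(0))
  a3 <- solve_assignment(build_cost_matrix(e, e, c(64L, 64L)))
  expect_equal(a3$cost, 0)
})

test_that("the solver equals the brute-force optimum on random instances", {
  set.seed(99)
  for (t in 1:60) {
    ma <- sample(0:4, 1)
    mb <- sample(0:(8 - ma), 1)
    C <- build_cost_matrix(random_detections(ma), random_detections(mb),
                           c(100L, 100L), track_params(d_max = 60))
    a <- solve_assignment(C)
    expect_equal(a$cost, brute_force_assignment_cost(C), tolerance = 1e-9)
  }
})

test_that("assignments satisfy the bijectivity invariants", {
  set.seed(5)
  for (t in 1:20) {
    ma <- sample(0:6, 1)
    mb <- sample(0:6, 1)
    C <- build_cost_matrix(random_detections(ma), random_detections(mb),
                           c(100L, 100L), track_params(d_max = 70))
    a <- solve_assignment(C)
    expect_equal(nrow(a$pairs) + length(a$appearing), mb)
    expect_equal(nrow(a$pairs) + length(a$disappearing), ma)
    expect_equal(anyDuplicated(a$pairs[, 1]), 0)
    expect_equal(anyDuplicated(a$pairs[, 2]), 0)
  }
})

test_that("swapping the frames transposes the assignment", {
  set.seed(11)
  A <- random_detections(5)
  B <- random_detections(6)
  fs <- c(100L, 100L)
  p <- track_params(d_max = 70)
  f <- solve_assignment(build_cost_matrix(A, B, fs, p))
  r <- solve_assignment(build_cost_matrix(B, A, fs, p))
  expect_equal(f$cost, r$cost, tolerance = 1e-9)
  expect_setequal(paste(f$pairs[, 1], f$pairs[, 2]),
                  paste(r$pairs[, 2], r$pairs[, 1]))
})

test_that("neighbourhood adjustment lowers agreeing costs and only those", {
  # rigid translation of a 5-cell clump
  set.seed(3)
  pos <- cbind(runif(5, 30, 70), runif(5, 30, 70))
  A <- tibble::tibble(x = pos[, 1], y = pos[, 2], area = rep(100, 5))
  B <- tibble::tibble(x = pos[, 1] + 8, y = pos[, 2], area = rep(100, 5))
  fs <- c(128L, 128L)
  p <- track_params(mu = 0.5, sigma = 5)
  C <- build_cost_matrix(A, B, fs, p)
  a0 <- solve_assignment(C)
  Cadj <- neighbourhood_adjust(C, a0, A, B, p)
  for (i in 1:5) {
    # the true pair agrees perfectly, so it gets the full depth (or clamps
    # at zero when the original cost was below the depth)
    expect_lt(Cadj$assoc[i, i], C$assoc[i, i])
    expect_equal(C$assoc[i, i] - Cadj$assoc[i, i],
                 min(0.5, C$assoc[i, i]), tolerance = 1e-6)
    for (j in setdiff(1:5, i)) {
      if (is.finite(C$assoc[i, j])) {
        drop_ij <- C$assoc[i, j] - Cadj$assoc[i, j]
        expect_lte(drop_ij, 0.5 + 1e-9)           # never more than the depth
      }
    }
  }
  # mu = 0 leaves the matrix untouched
  expect_identical(neighbourhood_adjust(C, a0, A, B,
                                        track_params(mu = 0))$assoc,
                   C$assoc)
  # a single isolated cell has no neighbours: row unchanged
  A1 <- A[1, ]
  B1 <- B[1, ]
  C1 <- build_cost_matrix(A1, B1, fs, p)
  a1 <- solve_assignment(C1)
  expect_identical(neighbourhood_adjust(C1, a1, A1, B1, p)$assoc, C1$assoc)
})

test_that("collective drift is tracked and the heuristic earns its keep", {
  # identical frames pair to the identity
  D <- random_detections(6)
  aid <- track_frames(D, D, c(100L, 100L))
  expect_equal(aid$pairs[, 1], aid$pairs[, 2])
  # empty second frame: everything disappears
  e <- tibble::tibble(x = numeric(0), y = numeric(0), area = numeric(0))
  ae <- track_frames(D, e, c(100L, 100L))
  expect_equal(sort(ae$disappearing), 1:6)
  # an adversarial drift-plus-jitter pair where independent motion fails
  found <- FALSE
  for (s in 1:30) {
    pr <- drift_pair(n = 8, drift = c(18, 4), jitter = 3, seed = s)
    a0 <- track_frames(pr$A, pr$B, pr$frame_shape, track_params(mu = 0))
    a1 <- track_frames(pr$A, pr$B, pr$frame_shape, track_params())
    r0 <- identity_link_recall(a0, 8)
    r1 <- identity_link_recall(a1, 8)
    if (r1 == 1 && r0 < 1) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("link recall does not drop when the heuristic is enabled", {
  rec <- vapply(1:50, function(s) {
    pr <- drift_pair(n = 8, drift = c(18, 4), jitter = 3, seed = s)
    c(
      identity_link_recall(
        track_frames(pr$A, pr$B, pr$frame_shape, track_params(mu = 0)), 8
      ),
      identity_link_recall(
        track_frames(pr$A, pr$B, pr$frame_shape, track_params()), 8
      )
    )
  }, numeric(2))
  expect_gte(mean(rec[2, ]), mean(rec[1, ]))
})

test_that("traces chain assignments with fresh ids for reappearances", {
  # 3 frames, 2 cells, identity assignments
  dets <- dplyr::bind_rows(lapply(0:2, function(f) {
    tibble::tibble(frame = f, label = 1:2, x = c(10, 40), y = c(10, 40),
                   area = 100)
  }))
  tr <- track_movie(dets, c(64L, 64L))
  expect_equal(dplyr::n_distinct(tr$cell_id), 2)
  expect_equal(nrow(tr), 6)
  by_id <- split(tr$frame, tr$cell_id)
  expect_true(all(vapply(by_id, length, integer(1)) == 3))
  # disappearance then a new appearance elsewhere: distinct ids
  dets2 <- dplyr::bind_rows(
    tibble::tibble(frame = 0L, label = 1L, x = 10, y = 10, area = 100),
    tibble::tibble(frame = 1L, label = 1L, x = 10.5, y = 10, area = 100),
    tibble::tibble(frame = 2L, label = 1L, x = 55, y = 55, area = 100)
  )
  tr2 <- track_movie(dets2, c(64L, 64L), track_params(d_max = 20))
  expect_equal(dplyr::n_distinct(tr2$cell_id), 2)
  # frame gaps are refused
  dets3 <- dets[dets$frame != 1, ]
  expect_error(track_movie(dets3, c(64L, 64L)), "gaps")
  # inconsistent chains are refused
  expect_error(build_traces(dets, list()), "one assignment per")
})

test_that("tracking true detections of a dividing movie recovers the lineage count", {
  mv <- render_movie(scene_spec(n_cells = 6, n_frames = 12,
                                division_prob = 0.06, jitter = 0.4,
                                seed = 41))
  dets <- mv$truth |>
    dplyr::group_by(frame) |>
    dplyr::mutate(label = dplyr::row_number(), area = 300) |>
    dplyr::ungroup() |>
    dplyr::select(frame, label, x, y, area)
  tr <- track_movie(dets, c(256L, 256L))
  expect_equal(dplyr::n_distinct(tr$cell_id),
               dplyr::n_distinct(mv$truth$cell_id))
})

test_that("the trace-correctness law behaves like a decay law", {
  expect_equal(trace_correctness_probability(1, 50), 1)
  expect_equal(trace_correctness_probability(0.7, 1), 0.7)
  expect_equal(trace_correctness_probability(0.99, 100), 0.99^100)
  expect_error(trace_correctness_probability(1.2, 5), "\\[0, 1\\]")
  expect_error(trace_correctness_probability(0.9, 0), "at least 1")
})
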