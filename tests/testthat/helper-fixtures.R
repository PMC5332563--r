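# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; no binary fixtures.

# Rename detections so the evaluation readers see a cell_id column.
as_result <- function(detections) {
  dplyr::rename(detections, cell_id = "label")
}

# A single near-circular cell of known radius, noise-free unless asked.
one_cell_movie <- function(radius = 10, noise = 0, seed = 2,
                           frame_shape = c(128L, 128L)) {
  render_movie(scene_spec(
    n_cells = 1, n_frames = 1, r_range = c(radius, radius),
    noise_sigma = noise, jitter = 0, seed = seed, frame_shape = frame_shape
  ))
}

# Fabricated helper-image bundle with fully controlled channels.
fake_helpers <- function(shape = c(64L, 64L), border = 0, content = 0,
                         clean = 0.5, fg = TRUE) {
  as_chan <- function(v) {
    if (is.matrix(v)) v else matrix(v, shape[1], shape[2])
  }
  structure(
    list(
      raw = as_chan(clean), background = as_chan(0.5),
      clean = as_chan(clean),
      foreground_mask = as_chan(fg) > 0,
      border_image = as_chan(border), content_image = as_chan(content),
      shape = as.integer(shape)
    ),
    class = "helper_images"
  )
}

# Exhaustive oracle for the frame-to-frame assignment problem: enumerate
# every subset of A that stays and every injection into B.
all_permutations <- function(v, k) {
  if (k == 0) {
    return(list(integer(0)))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i], k - 1)) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

all_subsets <- function(v) {
  if (!length(v)) {
    return(list(integer(0)))
  }
  rest <- all_subsets(v[-1])
  c(rest, lapply(rest, function(s) c(v[1], s)))
}

brute_force_assignment_cost <- function(C) {
  ma <- length(C$disappear)
  mb <- length(C$appear)
  best <- Inf
  for (S in all_subsets(seq_len(ma))) {
    k <- length(S)
    if (k > mb) next
    for (p in all_permutations(seq_len(mb), k)) {
      cost <- sum(C$disappear[setdiff(seq_len(ma), S)]) +
        sum(C$appear[setdiff(seq_len(mb), p)])
      if (k > 0) cost <- cost + sum(C$assoc[cbind(S, p)])
      if (is.finite(cost) && cost < best) best <- cost
    }
  }
  best
}

random_detections <- function(n, frame_shape = c(100L, 100L)) {
  tibble::tibble(
    x = runif(n, 0, frame_shape[2] - 1),
    y = runif(n, 0, frame_shape[1] - 1),
    area = runif(n, 50, 150)
  )
}

# Rigid collective drift plus per-cell jitter detection pair; true pairing is
# the identity.
drift_pair <- function(n = 8, drift = c(18, 4), jitter = 3, seed = 1,
                       frame_shape = c(128L, 128L)) {
  set.seed(seed)
  pos <- cbind(runif(n, 40, 90), runif(n, 40, 90))
  A <- tibble::tibble(x = pos[, 1], y = pos[, 2], area = runif(n, 90, 110))
  B <- tibble::tibble(
    x = pos[, 1] + drift[1] + rnorm(n, 0, jitter),
    y = pos[, 2] + drift[2] + rnorm(n, 0, jitter),
    area = A$area + rnorm(n, 0, 3)
  )
  list(A = A, B = B, frame_shape = frame_shape)
}

identity_link_recall <- function(a, n_true) {
  sum(a$pairs[, 1] == a$pairs[, 2]) / n_true
}

# Ground-truth table of a 2-cell movie with an id swap in the result at the
# given frame boundaries (cells far apart so matching is unambiguous).
two_cell_truth <- function(n_frames = 10) {
  dplyr::bind_rows(lapply(seq_len(n_frames) - 1L, function(f) {
    tibble::tibble(
      frame = f, cell_id = c(1L, 2L),
      x = c(20, 80), y = c(20, 80), facultative = 0L
    )
  }))
}

swap_after <- function(traces, boundary) {
  sw <- traces$frame > boundary
  old <- traces$cell_id
  traces$cell_id[sw & old == 1] <- 2L
  traces$cell_id[sw & old == 2] <- 1L
  traces
}
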