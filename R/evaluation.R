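#' Mutual-nearest-neighbour centre matching
#'
#' Two cells — one in the ground truth, one in the results — are matched when
#' each is the other's nearest neighbour and their distance is below
#' `max_dist`. Ties at exactly equal distance resolve towards the lower
#' ground-truth `cell_id`.
#'
#' @param G_frame ground-truth tibble for one frame (columns `cell_id`, `x`,
#'   `y`).
#' @param R_frame result tibble for one frame (columns `cell_id` or `label`,
#'   `x`, `y`).
#' @param max_dist matching threshold in pixels.
#' @return Tibble of matched pairs: `gt_id`, `r_id`, `dist`.
#' @export
match_centres <- function(G_frame, R_frame, max_dist = 8) {
  rid <- if ("cell_id" %in% names(R_frame)) {
    R_frame$cell_id
  } else {
    R_frame$label
  }
  empty <- tibble::tibble(gt_id = integer(), r_id = integer(),
                          dist = numeric())
  if (nrow(G_frame) == 0 || nrow(R_frame) == 0) {
    return(empty)
  }
  g <- G_frame[order(G_frame$cell_id), , drop = FALSE]
  ord_r <- order(rid)
  r_x <- R_frame$x[ord_r]
  r_y <- R_frame$y[ord_r]
  rid <- rid[ord_r]
  d <- dist_xy(cbind(g$x, g$y), cbind(r_x, r_y))
  nn_of_g <- apply(d, 1, which.min)
  nn_of_r <- apply(d, 2, which.min)
  gi <- which(nn_of_r[nn_of_g] == seq_len(nrow(g)))
  gi <- gi[d[cbind(gi, nn_of_g[gi])] < max_dist]
  tibble::tibble(
    gt_id = g$cell_id[gi],
    r_id = rid[nn_of_g[gi]],
    dist = d[cbind(gi, nn_of_g[gi])]
  )
}

metric_row <- function(correct, n_result, n_truth) {
  p <- if (n_result > 0) correct / n_result else as.numeric(n_truth == 0)
  r <- if (n_truth > 0) correct / n_truth else as.numeric(n_result == 0)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(
    precision = p, recall = r, f_measure = f,
    n_correct = correct, n_result = n_result, n_truth = n_truth,
    flagged = (n_result == 0) != (n_truth == 0)
  )
}

new_metric_report <- function(per_frame, summary, problem) {
  structure(list(per_frame = per_frame, summary = summary, problem = problem),
            class = "metric_report")
}

#' Segmentation precision, recall and F-measure
#'
#' Matches result cells to ground-truth cells frame by frame
#' ([match_centres()]) and scores precision `|C|/|R|`, recall `|C|/|G|` and
#' `F = 2PR/(P+R)`, adjusted for facultative ground-truth cells: a
#' facultative cell, and any result cell matched to one, is removed from both
#' numerator and denominator, so algorithms are neither penalised nor
#' rewarded for finding or missing such cells. Aggregate values pool counts
#' over frames.
#'
#' @param truth ground-truth tibble: `frame`, `cell_id`, `x`, `y`, optional
#'   `facultative` (0/1; absent means all 0).
#' @param result result tibble: `frame`, `cell_id` (or `label`), `x`, `y`.
#' @param max_dist matching threshold in pixels.
#' @return A `metric_report`: `$per_frame` tibble and `$summary` one-row
#'   tibble.
#' @export
segmentation_metrics <- function(truth, result, max_dist = 8) {
  truth <- ensure_facultative(truth)
  frames <- sort(unique(c(truth$frame, result$frame)))
  rows <- lapply(frames, function(f) {
    g <- truth[truth$frame == f, , drop = FALSE]
    r <- result[result$frame == f, , drop = FALSE]
    m <- match_centres(g, r, max_dist)
    fac_ids <- g$cell_id[g$facultative == 1]
    c_f <- m[m$gt_id %in% fac_ids, , drop = FALSE]
    n_c <- nrow(m) - nrow(c_f)
    n_r <- nrow(r) - nrow(c_f)             # result cells matched to facultative
    n_g <- nrow(g) - length(fac_ids)
    dplyr::mutate(metric_row(n_c, n_r, n_g), frame = f, .before = 1)
  })
  per_frame <- dplyr::bind_rows(rows)
  summary <- metric_row(sum(per_frame$n_correct), sum(per_frame$n_result),
                        sum(per_frame$n_truth))
  new_metric_report(per_frame, summary, "segmentation")
}

ensure_facultative <- function(truth) {
  if (!"facultative" %in% names(truth)) {
    truth$facultative <- 0L
  }
  truth
}

# Links (consecutive-frame presence pairs) of a trace-style table.
# Returns tibble: frame (first frame of the link), id, and for GT the
# facultative flag of either endpoint.
table_links <- function(tab, frame_pairs) {
  out <- lapply(seq_len(nrow(frame_pairs)), function(k) {
    f1 <- frame_pairs[k, 1]
    f2 <- frame_pairs[k, 2]
    a <- tab[tab$frame == f1, , drop = FALSE]
    b <- tab[tab$frame == f2, , drop = FALSE]
    ids <- intersect(a$cell_id, b$cell_id)
    tibble::tibble(f1 = f1, f2 = f2, id = ids)
  })
  dplyr::bind_rows(out)
}

link_metrics <- function(truth, traces, max_dist, frame_pairs, problem) {
  truth <- ensure_facultative(truth)
  # per-frame mutual-NN matchings, GT id <-> result id
  match_by_frame <- function(f) {
    match_centres(truth[truth$frame == f, , drop = FALSE],
                  traces[traces$frame == f, , drop = FALSE], max_dist)
  }
  fac <- function(f) {
    g <- truth[truth$frame == f, , drop = FALSE]
    g$cell_id[g$facultative == 1]
  }
  rows <- lapply(seq_len(nrow(frame_pairs)), function(k) {
    f1 <- frame_pairs[k, 1]
    f2 <- frame_pairs[k, 2]
    pair <- frame_pairs[k, , drop = FALSE]
    g_links <- table_links(truth, pair)
    g_links <- g_links[!(g_links$id %in% fac(f1)) &
                         !(g_links$id %in% fac(f2)), , drop = FALSE]
    r_links <- table_links(traces, pair)
    m1 <- match_by_frame(f1)
    m2 <- match_by_frame(f2)
    # GT cell matched to each result endpoint (NA when unmatched)
    g1 <- m1$gt_id[match(r_links$id, m1$r_id)]
    g2 <- m2$gt_id[match(r_links$id, m2$r_id)]
    # exclude result links touching a facultative GT cell at either endpoint
    excl <- (!is.na(g1) & g1 %in% fac(f1)) | (!is.na(g2) & g2 %in% fac(f2))
    r_kept <- r_links[!excl, , drop = FALSE]
    g1 <- g1[!excl]
    g2 <- g2[!excl]
    correct <- sum(!is.na(g1) & !is.na(g2) & g1 == g2 &
                     g1 %in% g_links$id)
    dplyr::mutate(metric_row(correct, nrow(r_kept), nrow(g_links)),
                  frame = f1, .before = 1)
  })
  per_frame <- dplyr::bind_rows(rows)
  summary <- metric_row(sum(per_frame$n_correct), sum(per_frame$n_result),
                        sum(per_frame$n_truth))
  new_metric_report(per_frame, summary, problem)
}

#' Tracking precision, recall and F-measure
#'
#' The unit of evaluation is the link: the presence of one cell in two
#' consecutive frames. A result link is correct when its two endpoint
#' detections match (mutual-nearest-neighbour, per frame) ground-truth
#' detections carrying the same ground-truth identity. Links involving a
#' facultative ground-truth cell at either endpoint are excluded from both
#' numerator and denominator.
#'
#' @param truth ground-truth tibble: `frame`, `cell_id`, `x`, `y`, optional
#'   `facultative`.
#' @param traces result traces tibble: `frame`, `cell_id`, `x`, `y`.
#' @param max_dist matching threshold in pixels.
#' @return A `metric_report`.
#' @export
tracking_metrics <- function(truth, traces, max_dist = 8) {
  frames <- sort(unique(truth$frame))
  if (length(frames) < 2) {
    stop("tracking evaluation needs at least 2 frames", call. = FALSE)
  }
  fp <- cbind(frames[-length(frames)], frames[-1])
  link_metrics(truth, traces, max_dist, fp, "tracking")
}

#' Long-term tracking precision, recall and F-measure
#'
#' Identical to [tracking_metrics()] but evaluated on a single link per cell,
#' from the first to the last frame of the movie: only cells present over
#' the whole experiment — and traces spanning it without identity changes —
#' count.
#'
#' @inheritParams tracking_metrics
#' @return A `metric_report`.
#' @export
long_term_metrics <- function(truth, traces, max_dist = 8) {
  frames <- sort(unique(truth$frame))
  if (length(frames) < 2) {
    stop("long-term evaluation needs at least 2 frames", call. = FALSE)
  }
  fp <- cbind(frames[1], frames[length(frames)])
  link_metrics(truth, traces, max_dist, fp, "long_term")
}

#' Evaluate segmentation, tracking and long-term tracking at once
#'
#' @inheritParams tracking_metrics
#' @return Named list of three `metric_report`s: `segmentation`, `tracking`,
#'   `long_term`.
#' @export
evaluate_all <- function(truth, traces, max_dist = 8) {
  list(
    segmentation = segmentation_metrics(truth, traces, max_dist),
    tracking = tracking_metrics(truth, traces, max_dist),
    long_term = long_term_metrics(truth, traces, max_dist)
  )
}

#' @export
print.metric_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<metric_report: %s> P = %.4f, R = %.4f, F = %.4f (correct %d / result %d / truth %d)%s\n",
    x$problem, s$precision, s$recall, s$f_measure,
    s$n_correct, s$n_result, s$n_truth,
    if (s$flagged) " [degenerate counts flagged]" else ""
  ))
  invisible(x)
}

#' @rdname tidy.sa_fit
#' @exportS3Method generics::tidy
tidy.metric_report <- function(x, ...) {
  x$per_frame
}

#' @rdname tidy.sa_fit
#' @exportS3Method generics::glance
glance.metric_report <- function(x, ...) {
  dplyr::mutate(x$summary, problem = x$problem, .before = 1)
}

#' Per-frame F-measure plot for a metric report
#'
#' @param object a `metric_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.metric_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$per_frame[, c("frame", "precision", "recall", "f_measure")],
    -"frame", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "frame", y = NULL,
      title = sprintf("%s quality per frame", object$problem)
    ) +
    ggplot2::theme_minimal()
}
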