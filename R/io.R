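#' Read a sequence of grey-scale frames
#'
#' Accepts a directory (file-name-sorted `.tif`/`.tiff`/`.png` sequence), a
#' multi-page TIFF, a single image file, or a character vector of files.
#' Images of any bit depth are normalised to `[0, 1]` on load; multi-channel
#' images are collapsed by averaging.
#'
#' @param path directory, file, or vector of files.
#' @return List of numeric matrices.
#' @export
read_frames <- function(path) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    sort(list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                    full.names = TRUE))
  } else {
    path
  }
  if (length(files) == 0) {
    stop("no frames found at ", path[1], call. = FALSE)
  }
  out <- list()
  for (f in files) {
    if (!file.exists(f)) {
      stop("cannot read frame file: ", f, call. = FALSE)
    }
    img <- tryCatch(
      {
        if (grepl("\\.png$", f, ignore.case = TRUE)) {
          if (!requireNamespace("png", quietly = TRUE)) {
            stop("the png package is needed to read PNG frames")
          }
          list(png::readPNG(f))
        } else {
          tiff::readTIFF(f, all = TRUE)
        }
      },
      error = function(e) {
        stop("cannot read frame file: ", f, " (", conditionMessage(e), ")",
             call. = FALSE)
      }
    )
    for (page in img) {
      m <- page
      if (length(dim(m)) == 3) {
        m <- apply(m, c(1, 2), mean)
      }
      out[[length(out) + 1]] <- clamp01(m)
    }
  }
  out
}

#' Write frames as a multi-page TIFF
#'
#' @param frames list of matrices in `[0, 1]`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write label masks as 16-bit TIFF
#'
#' @param masks list of integer matrices (0 = background).
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_label_masks <- function(masks, path) {
  scaled <- lapply(masks, function(m) m / 65535)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read label masks written by [write_label_masks()]
#'
#' @param path `.tif` path.
#' @return List of integer matrices.
#' @export
read_label_masks <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    m <- round(p * 65535)
    storage.mode(m) <- "integer"
    m
  })
}

# ---- CSV dialects ---------------------------------------------------------
# detections: frame,label,x,y,area
# truth / traces (evaluation dialect): frame,cell_id,x,y,facultative

write_csv_plain <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, required, dialect) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(read.csv(path), error = function(e) {
    stop("cannot parse ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf(
      "%s is not a valid %s file (header line 1 lacks: %s)",
      path, dialect, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad)) {
    stop(sprintf("%s: malformed record at line %d", path, bad[1] + 1),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write / read a detections table
#'
#' Dialect: `frame,label,x,y,area` (0-based frames, 0-based pixel
#' coordinates).
#'
#' @param detections detections tibble.
#' @param path CSV path.
#' @return The tibble (readers) or the path, invisibly (writers).
#' @export
write_detections <- function(detections, path) {
  write_csv_plain(
    data.frame(frame = detections$frame, label = detections$label,
               x = detections$x, y = detections$y, area = detections$area),
    path
  )
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  read_csv_checked(path, c("frame", "label", "x", "y", "area"), "detections")
}

#' Write / read ground truth or traces in the evaluation dialect
#'
#' Dialect: `frame,cell_id,x,y,facultative` (facultative 0/1; a missing
#' column reads as all 0). Traces written with [write_traces()] additionally
#' carry `detection_label` and `area`, which [read_result()] ignores.
#'
#' @param truth tibble with at least `frame`, `cell_id`, `x`, `y`.
#' @param path CSV path.
#' @return The tibble (readers) or the path, invisibly (writers).
#' @export
write_truth <- function(truth, path) {
  truth <- ensure_facultative(truth)
  write_csv_plain(
    data.frame(frame = truth$frame, cell_id = truth$cell_id,
               x = truth$x, y = truth$y, facultative = truth$facultative),
    path
  )
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read_csv_checked(path, c("frame", "cell_id", "x", "y"),
                         "ground-truth")
  ensure_facultative(df)
}

#' @rdname write_truth
#' @export
read_result <- function(path) {
  read_truth(path)
}

#' Write traces
#'
#' Dialect: `frame,cell_id,detection_label,x,y,area`, one row per
#' (frame, cell); readable back with [read_result()] for evaluation.
#'
#' @param traces traces tibble from [build_traces()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  write_csv_plain(
    data.frame(frame = traces$frame, cell_id = traces$cell_id,
               detection_label = traces$detection_label,
               x = traces$x, y = traces$y, area = traces$area),
    path
  )
}

# ---- configuration --------------------------------------------------------

default_config_entries <- function() {
  pp <- preprocess_params()
  ep <- energy_params()
  sp <- seg_params()
  tp <- track_params()
  c(
    setNames(pp[names(pp)], paste0("preprocess.", names(pp))),
    setNames(ep[names(ep)], paste0("contour.", names(ep))),
    setNames(
      sp[setdiff(names(sp), "energy")],
      paste0("segmentation.", setdiff(names(sp), "energy"))
    ),
    setNames(tp[names(tp)], paste0("tracking.", names(tp))),
    list(
      "evaluation.max_dist" = 8,
      "learning.budget" = 150L, "learning.n_seeds" = 3L,
      "learning.jitter_r" = 3
    )
  )
}

#' Flat configuration covering every tunable parameter
#'
#' Keys are namespaced `module.param` (for example `contour.A_exp`,
#' `tracking.d_max`). Unknown keys are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param ... overrides as `key = value` pairs (quote the keys:
#'   `` `contour.A_exp` = 300 ``).
#' @param overrides optionally a named list of overrides.
#' @return A named list of class `starseg_config`.
#' @export
starseg_config <- function(..., overrides = NULL) {
  cfg <- default_config_entries()
  ov <- c(list(...), overrides)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  structure(cfg, class = "starseg_config")
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [starseg_config()].
#' @return A `starseg_config` (reader) or `path`, invisibly (writer).
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  starseg_config(overrides = vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

cfg_section <- function(cfg, prefix) {
  keys <- grep(paste0("^", prefix, "\\."), names(cfg), value = TRUE)
  vals <- cfg[keys]
  names(vals) <- sub(paste0("^", prefix, "\\."), "", keys)
  vals
}

#' Materialise parameter bundles from a flat config
#'
#' @param config a [starseg_config()].
#' @return List with `preprocess`, `seg` (with its `energy`), `track`,
#'   `max_dist`, `learning`.
#' @export
config_params <- function(config = starseg_config()) {
  pp <- do.call(preprocess_params, cfg_section(config, "preprocess"))
  ep <- do.call(energy_params, cfg_section(config, "contour"))
  sp_args <- cfg_section(config, "segmentation")
  sp <- do.call(seg_params, c(list(energy = ep), sp_args))
  tp <- do.call(track_params, cfg_section(config, "tracking"))
  list(
    preprocess = pp, seg = sp, track = tp,
    max_dist = config[["evaluation.max_dist"]],
    learning = cfg_section(config, "learning")
  )
}

# ---- command bodies (thin wrappers used by the CLI script) ----------------

#' Segment a movie from disk to disk
#'
#' Reads frames, segments every frame, and writes `detections.csv`, a 16-bit
#' label-mask TIFF and the effective configuration into `out_dir`.
#'
#' @param input frames path (see [read_frames()]).
#' @param out_dir output directory (created if needed).
#' @param config a [starseg_config()].
#' @param seed integer RNG seed.
#' @param verbose print per-frame progress lines.
#' @return The detections tibble, invisibly.
#' @export
cli_segment <- function(input, out_dir, config = starseg_config(),
                        seed = 1L, verbose = TRUE) {
  frames <- read_frames(input)
  p <- config_params(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prev <- NULL
  dets <- list()
  masks <- list()
  for (f in seq_along(frames)) {
    t0 <- Sys.time()
    prev <- segment_frame(frames[[f]], p$seg, prev = prev,
                          preprocess = p$preprocess,
                          frame_index = f - 1L, seed = seed + f - 1L)
    dets[[f]] <- prev
    masks[[f]] <- detections_to_mask(prev, dim(frames[[f]]))
    if (verbose) {
      message(sprintf("frame %d: %d cells (%.2fs)", f - 1L, nrow(prev),
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  detections <- dplyr::bind_rows(dets)
  write_detections(detections, file.path(out_dir, "detections.csv"))
  write_label_masks(masks, file.path(out_dir, "masks.tif"))
  write_config(config, file.path(out_dir, "config.yaml"))
  invisible(detections)
}

#' Track a detections file into traces
#'
#' @param detections_csv path to a detections CSV.
#' @param out_csv output traces CSV path.
#' @param frame_shape `(height, width)` of the frames.
#' @param config a [starseg_config()].
#' @return The traces tibble, invisibly.
#' @export
cli_track <- function(detections_csv, out_csv, frame_shape,
                      config = starseg_config()) {
  dets <- read_detections(detections_csv)
  p <- config_params(config)
  traces <- track_movie(dets, frame_shape, p$track)
  write_traces(traces, out_csv)
  invisible(traces)
}

#' Evaluate result traces against ground truth
#'
#' Computes segmentation, tracking and long-term tracking precision / recall
#' / F, writes a per-frame CSV and a human-readable summary.
#'
#' @param truth_csv ground-truth CSV (evaluation dialect).
#' @param result_csv result CSV (evaluation dialect).
#' @param out_dir output directory; `NULL` skips writing.
#' @param config a [starseg_config()].
#' @return Named list of three `metric_report`s, invisibly.
#' @export
cli_evaluate <- function(truth_csv, result_csv, out_dir = NULL,
                         config = starseg_config()) {
  truth <- read_truth(truth_csv)
  result <- read_result(result_csv)
  reports <- evaluate_all(truth, result,
                          max_dist = config[["evaluation.max_dist"]])
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    per_frame <- dplyr::bind_rows(lapply(reports, function(r) {
      dplyr::mutate(r$per_frame, problem = r$problem, .before = 1)
    }))
    write_csv_plain(per_frame, file.path(out_dir, "metrics_per_frame.csv"))
    summary <- dplyr::bind_rows(lapply(reports, glance))
    write_csv_plain(summary, file.path(out_dir, "metrics_summary.csv"))
    txt <- vapply(reports, function(r) {
      sprintf("%-13s P=%.4f R=%.4f F=%.4f", r$problem, r$summary$precision,
              r$summary$recall, r$summary$f_measure)
    }, character(1))
    writeLines(txt, file.path(out_dir, "summary.txt"))
  }
  invisible(reports)
}

#' Learn contour parameters from images plus ground truth
#'
#' Ground-truth contours are taken as discs around the annotated centres
#' (radius from `contour.A_exp`) unless a label-mask TIFF is supplied, in
#' which case per-cell equivalent discs are derived from the mask areas.
#'
#' @param input frames path.
#' @param truth_csv ground-truth CSV.
#' @param out_dir output directory for the optimised config and trajectory.
#' @param config a [starseg_config()].
#' @param budget cost evaluations.
#' @param seed integer RNG seed.
#' @param masks_tif optional label-mask TIFF aligned with the frames.
#' @return List `params` / `fit` from [learn_contour_params()], invisibly.
#' @export
cli_learn <- function(input, truth_csv, out_dir, config = starseg_config(),
                      budget = NULL, seed = 1L, masks_tif = NULL) {
  frames <- read_frames(input)
  truth <- read_truth(truth_csv)
  p <- config_params(config)
  if (is.null(budget)) {
    budget <- p$learning$budget
  }
  f0 <- min(truth$frame)
  g0 <- truth[truth$frame == f0, , drop = FALSE]
  r_default <- sqrt(p$seg$energy$A_exp / pi)
  gt <- lapply(seq_len(nrow(g0)), function(i) {
    r_i <- r_default
    if (!is.null(masks_tif)) {
      mask <- read_label_masks(masks_tif)[[f0 + 1]]
      a <- sum(mask == g0$cell_id[i])
      if (a > 0) r_i <- sqrt(a / pi)
    }
    gt_contour(centre = c(g0$x[i], g0$y[i]), radius = r_i, frame_index = f0)
  })
  helpers <- compute_helpers(frames[[f0 + 1]], p$preprocess)
  res <- learn_contour_params(
    gt, helpers, base = p$seg$energy, budget = budget, rng_seed = seed,
    n_seeds = p$learning$n_seeds, jitter_r = p$learning$jitter_r
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  learned <- config
  for (nm in names(res$fit$par)) {
    learned[[paste0("contour.", nm)]] <- unname(res$fit$par[nm])
  }
  learned[["contour.r_max"]] <- res$params$r_max
  write_config(learned, file.path(out_dir, "config_learned.yaml"))
  write_csv_plain(res$fit$trajectory,
                  file.path(out_dir, "cost_trajectory.csv"))
  invisible(res)
}

#' Generate a synthetic scene from the command line
#'
#' @param out_dir output directory.
#' @param scene one of the [make_benchmark_suite()] scene names.
#' @param seed integer RNG seed.
#' @return The rendered movie, invisibly.
#' @export
cli_synth <- function(out_dir, scene = "small_colony", seed = 1L) {
  suite <- make_benchmark_suite(seed)
  if (!scene %in% names(suite)) {
    stop("unknown scene: ", scene, "; choose one of ",
         paste(names(suite), collapse = ", "), call. = FALSE)
  }
  movie <- suite[[scene]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_frames(movie$frames, file.path(out_dir, "frames.tif"))
  write_label_masks(movie$masks, file.path(out_dir, "masks.tif"))
  write_truth(movie$truth, file.path(out_dir, "truth.csv"))
  write_csv_plain(movie$lineage, file.path(out_dir, "lineage.csv"))
  invisible(movie)
}
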