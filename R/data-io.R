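# Dataset layout on disk:
#   <root>/<procedure_id>/frames/%06d.png
#   <root>/<procedure_id>/labels.csv      (index, phase, binary)
#   <root>/manifest.json                  (written by generate_study)
# In memory a dataset is a tibble with one row per frame and a `frame`
# list-column, so the usual dplyr verbs work on it directly.

#' Write one procedure's frames and labels
#'
#' @param proc A procedure tibble as returned by [generate_procedure()].
#' @param root Dataset root directory.
#' @return (Invisibly) the procedure directory path.
#' @export
write_procedure <- function(proc, root) {
  stopifnot(is.data.frame(proc), nrow(proc) > 0)
  pid <- proc$procedure_id[1]
  fdir <- file.path(root, pid, "frames")
  dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
  purrr::walk2(proc$frame, proc$index, function(fr, idx) {
    png::writePNG(fr$pixels, file.path(fdir, sprintf("%06d.png", idx)))
  })
  utils::write.csv(
    data.frame(index = proc$index, phase = proc$phase,
               binary = as.integer(proc$binary)),
    file.path(root, pid, "labels.csv"), row.names = FALSE
  )
  invisible(file.path(root, pid))
}

#' Load an annotated frame dataset
#'
#' Reads every procedure directory under `root`, pairing each frame image
#' with its row in `labels.csv`. The stored three-phase label is kept, and
#' its binary projection (ablation vs not) is recomputed on load — the
#' binary task is what the detector trains on.
#'
#' @param root Dataset root, laid out as written by [generate_study()].
#' @param scope_radius_frac Scope-disc radius used to reconstruct the frame
#'   masks (must match the generator's value; default matches
#'   [scene_params()]).
#' @return A dataset tibble sorted by `(procedure_id, index)` with columns
#'   `procedure_id`, `index`, `phase`, `binary`, `frame`.
#' @export
load_dataset <- function(root, scope_radius_frac = 0.95) {
  if (!dir.exists(root)) stop("No such dataset root: ", root, call. = FALSE)
  pids <- sort(setdiff(list.dirs(root, recursive = FALSE, full.names = FALSE),
                       character(0)))
  pids <- pids[dir.exists(file.path(root, pids, "frames"))]
  if (!length(pids)) {
    stop("No procedure directories with a frames/ subdirectory under ",
         root, call. = FALSE)
  }
  masks <- list()  # one mask per image size
  rows <- purrr::map(pids, function(pid) {
    lab_path <- file.path(root, pid, "labels.csv")
    if (!file.exists(lab_path)) {
      stop("Missing labels.csv for procedure ", pid, call. = FALSE)
    }
    lab <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
    if (!all(c("index", "phase") %in% names(lab))) {
      stop("labels.csv for ", pid, " must have columns index, phase.",
           call. = FALSE)
    }
    bad <- setdiff(unique(lab$phase), .PHASES)
    if (length(bad)) {
      stop("Unknown phase label(s) in ", pid, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    lab <- lab[order(lab$index), , drop = FALSE]
    n_files <- length(list.files(file.path(root, pid, "frames"),
                                 pattern = "\\.png$"))
    if (n_files != nrow(lab)) {
      stop("Procedure ", pid, ": ", n_files, " frame files do not match ",
           nrow(lab), " label rows; every frame needs exactly one label.",
           call. = FALSE)
    }
    frames <- purrr::map2(lab$index, lab$phase, function(idx, ph) {
      fp <- file.path(root, pid, "frames", sprintf("%06d.png", idx))
      if (!file.exists(fp)) {
        stop("Missing frame file ", fp, call. = FALSE)
      }
      px <- png::readPNG(fp)
      if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
      n <- dim(px)[1]
      key <- as.character(n)
      if (is.null(masks[[key]])) {
        masks[[key]] <<- disc_mask(n, scope_radius_frac)
      }
      new_frame(px[, , 1:3], masks[[key]], ph, pid, idx)
    })
    tibble::tibble(
      procedure_id = pid,
      index = as.integer(lab$index),
      phase = lab$phase,
      binary = phase_to_binary(lab$phase),
      frame = frames
    )
  })
  ds <- dplyr::arrange(dplyr::bind_rows(rows), .data$procedure_id,
                       .data$index)
  if (nrow(ds) == 0) stop("Empty dataset under ", root, call. = FALSE)
  ds
}

#' Per-class frame counts of a dataset
#'
#' @param ds Dataset tibble.
#' @return A tibble with columns `binary` and `n`.
#' @export
dataset_counts <- function(ds) {
  dplyr::count(ds, .data$binary)
}

#' Class-balanced subsample
#'
#' Complete procedures contain far more not-ablation than ablation frames;
#' training on them unbalanced biases the classifier towards the majority
#' label. This keeps the minority class whole and uniformly subsamples the
#' majority class down to the same size, reproducibly for a given seed.
#'
#' @param ds Dataset tibble with a logical `binary` column.
#' @param seed Integer seed for the subsample draw.
#' @return A dataset tibble with exactly `min(n_ablation, n_other)` frames
#'   per class, in original `(procedure_id, index)` order.
#' @export
balanced_subsample <- function(ds, seed = 1L) {
  n_pos <- sum(ds$binary)
  n_neg <- sum(!ds$binary)
  if (n_pos == 0 || n_neg == 0) {
    missing <- if (n_pos == 0) "ablation" else "not-ablation"
    stop("Cannot balance: no '", missing, "' frames in the dataset.",
         call. = FALSE)
  }
  k <- min(n_pos, n_neg)
  keep <- withr::with_seed(seed, {
    pos <- which(ds$binary)
    neg <- which(!ds$binary)
    c(if (n_pos > k) sample(pos, k) else pos,
      if (n_neg > k) sample(neg, k) else neg)
  })
  dplyr::arrange(ds[sort(keep), ], .data$procedure_id, .data$index)
}

#' Randomly rotate a frame about the image centre
#'
#' Augmentation against the fixed per-procedure orientation of the laser
#' fibre: its orientation is roughly constant within one procedure but
#' arbitrary between procedures, so training images are rotated by a
#' uniform random angle. Bilinear interpolation, black fill; the scope-disc
#' support is preserved (a centred disc maps to itself) and the label is
#' untouched. Quarter-turn angles are exact array rotations.
#'
#' @param frame A [new_frame()] object (square).
#' @param seed Integer seed for the angle draw (ignored when `angle` given).
#' @param angle Optional fixed angle in degrees (counter-clockwise),
#'   bypassing the random draw.
#' @return The rotated frame.
#' @export
random_rotation <- function(frame, seed = 1L, angle = NULL) {
  stopifnot(inherits(frame, "feto_frame"))
  d <- dim(frame$pixels)
  if (d[1] != d[2]) stop("random_rotation() needs a square frame.",
                         call. = FALSE)
  th <- if (is.null(angle)) {
    withr::with_seed(seed, stats::runif(1, 0, 360))
  } else {
    angle %% 360
  }
  if (th == 0) return(frame)
  px <- .rotate_array(frame$pixels, th)
  for (c in 1:3) px[, , c] <- px[, , c] * frame$mask
  new_frame(px, frame$mask, frame$phase, frame$procedure_id, frame$index,
            spot = NULL)
}

#' Leave-one-procedure-out split plan
#'
#' One fold per procedure: the fold's validation set is that complete
#' procedure (kept imbalanced — evaluation is over full sequences), the
#' training set is everything else (class-balanced and rotation-augmented
#' at training time). A k-fold grouping of procedures is available as an
#' option.
#'
#' @param ds Dataset tibble (>= 2 procedures).
#' @param k Optional number of folds; default (`NULL`) is leave-one-out.
#' @return A `feto_splits` tibble with columns `fold`, `validation`
#'   (list of procedure ids) and `train` (list of procedure ids).
#' @export
make_loocv_splits <- function(ds, k = NULL) {
  pids <- sort(unique(ds$procedure_id))
  if (length(pids) < 2) {
    stop("Need at least 2 procedures to cross-validate.", call. = FALSE)
  }
  groups <- if (is.null(k)) {
    as.list(pids)
  } else {
    stopifnot(k >= 2, k <= length(pids))
    split(pids, rep_len(seq_len(k), length(pids)))
  }
  plan <- tibble::tibble(
    fold = seq_along(groups),
    validation = lapply(groups, as.character),
    train = lapply(groups, function(g) setdiff(pids, g))
  )
  class(plan) <- c("feto_splits", class(plan))
  plan
}

#' Serialise a split plan to JSON
#' @param splits A `feto_splits` tibble.
#' @param path Output file.
#' @return (Invisibly) `path`.
#' @export
write_splits <- function(splits, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(splits)), function(i) {
      list(fold = splits$fold[i],
           validation = splits$validation[[i]],
           train = splits$train[[i]])
    }),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
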