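# Complete classification: one binary ablation detector is turned into a
# three-phase {ablation, targeting, other} classifier by a channel-swap
# heuristic. A targeting frame looks like an ablation frame whose salient
# blue features are green instead, so the same detector run on the
# green/blue-swapped image acts as a targeting detector — no targeting
# annotations are ever needed.

#' Swap the green and blue channels of a frame
#'
#' Red is untouched; green and blue are exchanged pixelwise. Label metadata
#' is dropped (the swapped image is an inference-time construct, not an
#' annotated frame). The operation is an involution and fixes any
#' achromatic image.
#'
#' @param frame A [new_frame()] object or a `H x W x 3` array.
#' @return The swapped frame (or array, matching the input type).
#' @export
swap_green_blue <- function(frame) {
  if (inherits(frame, "feto_frame")) {
    d <- dim(frame$pixels)
    if (length(d) != 3 || d[3] != 3) {
      stop("swap_green_blue() needs a 3-channel frame.", call. = FALSE)
    }
    new_frame(frame$pixels[, , c(1, 3, 2)], frame$mask, NA_character_,
              frame$procedure_id, frame$index, spot = frame$spot)
  } else {
    d <- dim(frame)
    if (length(d) != 3 || d[3] != 3) {
      stop("swap_green_blue() needs a 3-channel array.", call. = FALSE)
    }
    frame[, , c(1, 3, 2)]
  }
}

#' Binary ablation classification of one frame
#'
#' @param model A trained `feto_model`.
#' @param frame Frame to classify.
#' @param threshold Operating point on the positive-class score; the frame
#'   is labelled `ablation` iff `score_positive >= threshold` (ties go
#'   positive).
#' @return A list with `label` (`"ablation"` / `"not_ablation"`) and
#'   `scores` (one-row tibble of the two class scores).
#' @export
classify_binary <- function(model, frame, threshold = 0.5) {
  sc <- predict_scores(model, frame)
  list(
    label = ifelse(sc$score_positive >= threshold, "ablation",
                   "not_ablation"),
    scores = sc
  )
}

#' Arbitrate the two binary passes into a final phase
#'
#' Decision rule of the complete pipeline, given the positive-class score of
#' the ablation pass (original image) and of the targeting pass (swapped
#' image): both below threshold — `other`; only one at/above — that phase;
#' both at/above — the phase with the larger score, ties broken towards
#' `ablation` (the costlier miss clinically; configurable).
#'
#' @param ablation_score,targeting_score Numeric vectors in \[0, 1\].
#' @param threshold Score threshold defining "classified as".
#' @param tie `"ablation"` or `"targeting"`: winner when both passes fire
#'   with exactly equal scores.
#' @return Character vector of phases.
#' @export
arbitrate_phase <- function(ablation_score, targeting_score,
                            threshold = 0.5, tie = "ablation") {
  tie <- match.arg(tie, c("ablation", "targeting"))
  stopifnot(length(ablation_score) == length(targeting_score))
  a_pos <- ablation_score >= threshold
  t_pos <- targeting_score >= threshold
  out <- rep("other", length(ablation_score))
  out[a_pos & !t_pos] <- "ablation"
  out[!a_pos & t_pos] <- "targeting"
  both <- a_pos & t_pos
  if (tie == "ablation") {
    out[both] <- ifelse(ablation_score[both] >= targeting_score[both],
                        "ablation", "targeting")
  } else {
    out[both] <- ifelse(targeting_score[both] >= ablation_score[both],
                        "targeting", "ablation")
  }
  out
}

#' Complete three-phase classification of one frame
#'
#' Runs the same binary detector twice — on the original image (ablation
#' pass) and on its green/blue-swapped version (targeting pass) — and
#' arbitrates the two positive-class scores into a final phase via
#' [arbitrate_phase()]. `filtered_binary` is the binary prediction after
#' this arbitration (`TRUE` iff the final phase is `ablation`): arbitration
#' can re-label a raw ablation positive to targeting, never the other way,
#' so the complete pipeline acts as a filter on ablation detections.
#'
#' @inheritParams classify_binary
#' @param tie Tie rule for [arbitrate_phase()].
#' @return A one-row tibble: `ablation_score`, `targeting_score`,
#'   `final_label`, `filtered_binary`.
#' @export
classify_complete <- function(model, frame, threshold = 0.5,
                              tie = "ablation") {
  classify_frames(model, list(frame), threshold = threshold, tie = tie)
}

#' Complete classification of many frames
#'
#' Vectorised [classify_complete()]: scores every frame on both passes with
#' one model, returning a per-frame results table.
#'
#' @param model A trained `feto_model`.
#' @param frames A dataset tibble, list of frames, or single frame.
#' @param threshold,tie See [classify_complete()].
#' @return A tibble with one row per frame: `index` (when available),
#'   `ablation_score`, `targeting_score`, `final_label`, `raw_binary`
#'   (ablation pass alone) and `filtered_binary`.
#' @export
classify_frames <- function(model, frames, threshold = 0.5,
                            tie = "ablation") {
  fl <- if (inherits(frames, "feto_frame")) {
    list(frames)
  } else if (is.data.frame(frames)) {
    frames$frame
  } else {
    frames
  }
  idx <- if (is.data.frame(frames) && "index" %in% names(frames)) {
    frames$index
  } else {
    seq_along(fl) - 1L
  }
  sc_a <- predict_scores(model, fl)$score_positive
  sc_t <- predict_scores(model, lapply(fl, swap_green_blue))$score_positive
  final <- arbitrate_phase(sc_a, sc_t, threshold = threshold, tie = tie)
  tibble::tibble(
    index = idx,
    ablation_score = sc_a,
    targeting_score = sc_t,
    final_label = final,
    raw_binary = sc_a >= threshold,
    filtered_binary = final == "ablation"
  )
}

#' Filtered binary predictions
#'
#' Projects complete-classification results back to the binary task: a
#' frame stays an ablation positive only if arbitration kept it. Every
#' filtered positive is by construction also a raw-pass positive, so the
#' filtered positive set is a subset of the raw one.
#'
#' @param results Tibble from [classify_frames()].
#' @return Logical vector of filtered binary predictions.
#' @export
filter_binary_predictions <- function(results) {
  stopifnot(is.data.frame(results), "filtered_binary" %in% names(results))
  results$filtered_binary
}

#' Segment per-frame labels into a phase timeline
#'
#' Run-length encodes the final labels of consecutive frames into maximal
#' constant-phase runs with half-open `[start, end)` index ranges;
#' concatenating the runs reconstructs the input labelling exactly.
#'
#' @param results Tibble from [classify_frames()] (frames ordered by
#'   `index`), or a character vector of labels.
#' @return A tibble with columns `phase`, `start`, `end`.
#' @export
segment_timeline <- function(results) {
  labels <- if (is.data.frame(results)) {
    if (is.unsorted(results$index, strictly = TRUE)) {
      stop("Frames must be strictly ordered by index.", call. = FALSE)
    }
    results$final_label
  } else {
    as.character(results)
  }
  if (length(labels) == 0) {
    return(tibble::tibble(phase = character(), start = integer(),
                          end = integer()))
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  tibble::tibble(
    phase = r$values,
    start = as.integer(c(0L, ends[-length(ends)])),
    end = as.integer(ends)
  )
}

#' Write per-frame results and a timeline
#'
#' @param results Tibble from [classify_frames()].
#' @param csv_path,timeline_path Output files (CSV of per-frame results;
#'   JSON of timeline runs). Either may be `NULL` to skip.
#' @return (Invisibly) the results.
#' @export
write_results <- function(results, csv_path = NULL, timeline_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(results), csv_path, row.names = FALSE)
  }
  if (!is.null(timeline_path)) {
    jsonlite::write_json(as.data.frame(segment_timeline(results)),
                         timeline_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(results)
}
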