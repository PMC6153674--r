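# Evaluation protocol: per-frame binary metrics on complete held-out
# procedures (never subsampled), leave-one-procedure-out cross-validation,
# cumulative confusion tables over folds, and precision-recall sweeps of
# the detector score.

#' Binary confusion table
#'
#' Counts over paired truth/prediction vectors for the ablation task:
#' `tp` (truth ablation, predicted ablation), `fn` (truth ablation, missed),
#' `fp` (false alarm), `tn` (correct rejection).
#'
#' @param truth,pred Logical (or 0/1) vectors of equal length.
#' @return A `feto_confusion` object.
#' @export
confusion <- function(truth, pred) {
  truth <- as.logical(truth)
  pred <- as.logical(pred)
  if (length(truth) != length(pred)) {
    stop("truth and pred must have the same length.", call. = FALSE)
  }
  new_confusion(
    tp = sum(truth & pred),
    fn = sum(truth & !pred),
    fp = sum(!truth & pred),
    tn = sum(!truth & !pred)
  )
}

#' @rdname confusion
#' @param tp,fn,fp,tn Non-negative integer cell counts (for building a
#'   table from published numbers).
#' @export
new_confusion <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  out <- lapply(cells, as.integer)
  structure(out, class = "feto_confusion")
}

#' @export
print.feto_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("ablation", "not_ablation"),
                              predicted = c("ablation", "not_ablation")))
  print(m)
  invisible(x)
}

#' @export
`+.feto_confusion` <- function(e1, e2) {
  new_confusion(e1$tp + e2$tp, e1$fn + e2$fn, e1$fp + e2$fp, e1$tn + e2$tn)
}

#' Total frames in a confusion table
#' @param ct A `feto_confusion`.
#' @return Integer total of the four cells.
#' @export
confusion_total <- function(ct) {
  stopifnot(inherits(ct, "feto_confusion"))
  ct$tp + ct$fn + ct$fp + ct$tn
}

#' F-measure from precision and recall
#'
#' The harmonic mean `f1 = 2 / (1/r + 1/p)`. Undefined (NA) whenever either
#' input is undefined or zero-denominator degenerate; `p = r = 0` yields 0.
#'
#' @param p,r Precision and recall in \[0, 1\] (NA allowed).
#' @return Numeric vector of F-measures.
#' @export
f_measure <- function(p, r) {
  out <- ifelse(is.na(p) | is.na(r), NA_real_,
                ifelse(p + r == 0, 0, 2 * p * r / (p + r)))
  out
}

#' Precision, recall and F-measure of a confusion table
#'
#' `p = tp/(tp+fp)`, `r = tp/(tp+fn)`, `f1 = 2/(1/r + 1/p)`. A zero
#' denominator makes the corresponding metric undefined: it is reported as
#' `NA` (never coerced to 0 or 1) and propagates to `f1`.
#'
#' @param ct A `feto_confusion` (or list with tp/fn/fp/tn).
#' @return A one-row tibble: `precision`, `recall`, `f1`.
#' @export
prf <- function(ct) {
  p <- if (ct$tp + ct$fp == 0) NA_real_ else ct$tp / (ct$tp + ct$fp)
  r <- if (ct$tp + ct$fn == 0) NA_real_ else ct$tp / (ct$tp + ct$fn)
  tibble::tibble(precision = p, recall = r, f1 = f_measure(p, r))
}

#' Precision-recall curve by threshold sweep
#'
#' Sweeps an even grid of `n_thresholds` operating points over \[0, 1\] on
#' the detector score. For the raw binary detector a frame is predicted
#' positive iff `score >= tau`; for the filtered pipeline, additionally only
#' if arbitration kept the final label `ablation` (pass `final_label`).
#' Grid points with undefined precision (no predicted positives) are
#' omitted. Recall is non-increasing in the threshold.
#'
#' @param truth Logical vector of ground-truth binary labels.
#' @param scores Numeric vector of positive-class scores in \[0, 1\].
#' @param n_thresholds Number of grid points (default 101).
#' @param final_label Optional character vector of final arbitration labels
#'   gating the filtered prediction.
#' @return A tibble: `threshold`, `precision`, `recall`.
#' @export
pr_curve <- function(truth, scores, n_thresholds = 101L,
                     final_label = NULL) {
  truth <- as.logical(truth)
  if (length(truth) != length(scores)) {
    stop("truth and scores must have the same length.", call. = FALSE)
  }
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) {
    stop("scores must lie in [0, 1].", call. = FALSE)
  }
  gate <- if (is.null(final_label)) rep(TRUE, length(truth)) else
    final_label == "ablation"
  taus <- seq(0, 1, length.out = n_thresholds)
  rows <- lapply(taus, function(tau) {
    pred <- gate & scores >= tau
    ct <- confusion(truth, pred)
    m <- prf(ct)
    tibble::tibble(threshold = tau, precision = m$precision,
                   recall = m$recall)
  })
  out <- dplyr::bind_rows(rows)
  out[!is.na(out$precision), ]
}

.fold_seed <- function(seed, fold, salt = 0L) {
  as.integer((as.numeric(seed) * 1009 + fold * 7919 + salt * 104729) %%
               (.Machine$integer.max - 1)) + 1L
}

#' Cross-validated study evaluation
#'
#' Runs the full protocol over a split plan: for each fold the training
#' procedures are class-balanced by subsampling, a detector is trained
#' (with rotation augmentation) or an SVM baseline fitted, and the complete
#' held-out procedure(s) are evaluated without any balancing. Reports
#' per-sequence precision/recall/F-measure, the cumulative confusion table
#' summed over folds, pooled precision-recall sweeps, and per-procedure
#' phase timelines.
#'
#' The two CNN-based methods share one trained model per fold: `raw_cnn` is
#' the plain binary detector, `filtered_cnn` applies the channel-swap
#' arbitration before projecting back to the binary task.
#'
#' @param ds Dataset tibble ([load_dataset()] / [generate_procedure()]).
#' @param splits A [make_loocv_splits()] plan (default: LOOCV over `ds`).
#' @param methods Subset of `c("raw_cnn", "filtered_cnn", "svm")`.
#' @param backbone A [backbone_config()] for the CNN methods.
#' @param train_cfg A [train_config()].
#' @param threshold Operating point for label decisions.
#' @param seed Master seed; per-fold training/subsampling seeds derive from
#'   it.
#' @param n_thresholds Grid size for the PR sweep.
#' @return A `feto_report` list with elements `per_sequence`, `cumulative`,
#'   `pr`, `timelines`, `predictions`, `config`.
#' @export
evaluate_study <- function(ds, splits = NULL,
                           methods = c("raw_cnn", "filtered_cnn"),
                           backbone = backbone_config(),
                           train_cfg = train_config(),
                           threshold = 0.5, seed = 1L,
                           n_thresholds = 101L) {
  methods <- match.arg(methods, c("raw_cnn", "filtered_cnn", "svm"),
                       several.ok = TRUE)
  splits <- splits %||% make_loocv_splits(ds)
  need_cnn <- any(c("raw_cnn", "filtered_cnn") %in% methods)

  per_seq <- list()
  preds <- list()
  timelines <- list()

  for (i in seq_len(nrow(splits))) {
    fold <- splits$fold[i]
    tr_ids <- splits$train[[i]]
    va_ids <- splits$validation[[i]]
    tr <- ds[ds$procedure_id %in% tr_ids, ]
    va <- ds[ds$procedure_id %in% va_ids, ]
    tr_bal <- balanced_subsample(tr, seed = .fold_seed(seed, fold, 1L))

    fold_preds <- list()
    if (need_cnn) {
      model <- build_model(backbone, seed = .fold_seed(seed, fold, 2L))
      cfg_f <- train_cfg
      cfg_f$seed <- .fold_seed(seed, fold, 3L)
      model <- suppressWarnings(train(model, tr_bal, cfg_f))
      res <- classify_frames(model, va, threshold = threshold)
      if ("raw_cnn" %in% methods) {
        fold_preds$raw_cnn <- tibble::tibble(
          procedure_id = va$procedure_id, index = va$index,
          truth = va$binary, pred = res$raw_binary,
          score = res$ablation_score, final_label = NA_character_
        )
      }
      if ("filtered_cnn" %in% methods) {
        fold_preds$filtered_cnn <- tibble::tibble(
          procedure_id = va$procedure_id, index = va$index,
          truth = va$binary, pred = res$filtered_binary,
          score = res$ablation_score, final_label = res$final_label
        )
        for (pid in va_ids) {
          timelines[[pid]] <- list(
            predicted = segment_timeline(res[va$procedure_id == pid, ]),
            truth = segment_timeline(va$phase[va$procedure_id == pid])
          )
        }
      }
    }
    if ("svm" %in% methods) {
      pipe <- train_svm_baseline(tr_bal)
      sv <- predict_svm_baseline(pipe, va)
      fold_preds$svm <- tibble::tibble(
        procedure_id = va$procedure_id, index = va$index,
        truth = va$binary, pred = sv$label,
        score = sv$score, final_label = NA_character_
      )
    }

    for (m in names(fold_preds)) {
      fp <- fold_preds[[m]]
      ct <- confusion(fp$truth, fp$pred)
      per_seq[[length(per_seq) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(method = m, fold = fold,
                       procedure_id = paste(va_ids, collapse = "+"),
                       tp = ct$tp, fn = ct$fn, fp = ct$fp, tn = ct$tn),
        prf(ct)
      )
      preds[[length(preds) + 1L]] <- dplyr::mutate(fp, method = m,
                                                   fold = fold)
    }
  }

  per_sequence <- dplyr::bind_rows(per_seq)
  predictions <- dplyr::bind_rows(preds)

  cumulative <- per_sequence |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(tp = sum(.data$tp), fn = sum(.data$fn),
                     fp = sum(.data$fp), tn = sum(.data$tn),
                     .groups = "drop")
  cumulative <- dplyr::bind_cols(
    cumulative,
    dplyr::bind_rows(lapply(seq_len(nrow(cumulative)), function(j) {
      prf(new_confusion(cumulative$tp[j], cumulative$fn[j],
                        cumulative$fp[j], cumulative$tn[j]))
    }))
  )

  pr <- predictions |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(g, key) {
      fl <- if (all(is.na(g$final_label))) NULL else g$final_label
      pr_curve(g$truth, g$score, n_thresholds = n_thresholds,
               final_label = fl)
    }) |>
    dplyr::ungroup()

  structure(
    list(
      per_sequence = per_sequence,
      cumulative = cumulative,
      pr = pr,
      timelines = timelines,
      predictions = predictions,
      config = list(methods = methods, backbone = unclass(backbone),
                    train = unclass(train_cfg), threshold = threshold,
                    seed = seed,
                    folds = lapply(seq_len(nrow(splits)), function(i) {
                      list(fold = splits$fold[i],
                           validation = splits$validation[[i]],
                           train = splits$train[[i]])
                    }))
    ),
    class = "feto_report"
  )
}

#' @export
print.feto_report <- function(x, ...) {
  cat("<feto_report> methods: ",
      paste(unique(x$per_sequence$method), collapse = ", "),
      " | ", length(unique(x$per_sequence$fold)), " folds\n", sep = "")
  cat("\nPer-sequence metrics (2 d.p.):\n")
  ps <- x$per_sequence
  ps$precision <- round(ps$precision, 2)
  ps$recall <- round(ps$recall, 2)
  ps$f1 <- round(ps$f1, 2)
  print(ps, n = nrow(ps))
  cat("\nCumulative:\n")
  cm <- x$cumulative
  cm$precision <- round(cm$precision, 2)
  cm$recall <- round(cm$recall, 2)
  cm$f1 <- round(cm$f1, 2)
  print(cm)
  invisible(x)
}

#' Serialise a study report
#'
#' Writes the per-sequence table and PR data as CSV and the full report
#' (including timelines, predictions and the resolved configuration) as
#' JSON, at full numeric precision.
#'
#' @param report A `feto_report`.
#' @param dir Output directory (created if missing).
#' @return (Invisibly) `dir`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "feto_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(report$per_sequence),
                   file.path(dir, "per_sequence.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$pr),
                   file.path(dir, "pr_curve.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(cumulative = as.data.frame(report$cumulative),
         timelines = lapply(report$timelines, function(t) {
           list(predicted = as.data.frame(t$predicted),
                truth = as.data.frame(t$truth))
         }),
         config = report$config),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  utils::write.csv(as.data.frame(report$predictions),
                   file.path(dir, "predictions.csv"), row.names = FALSE)
  invisible(dir)
}
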