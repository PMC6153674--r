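# Shared fixtures. Everything is generated in code at test time; the heavy
# objects (the 5-procedure study, its cross-validated report, a small
# trained detector) are built once per test run and cached in an
# environment so several test files can reuse them.

.fix <- new.env(parent = emptyenv())

quick_scene <- function(size = 64L, ...) {
  scene_params(image_size = size, ...)
}

# a couple of labelled procedures at desk scale, for unit tests
tiny_procedures <- function() {
  if (is.null(.fix$tiny_procs)) {
    p1 <- generate_procedure(procedure_script(
      list(c("other", 8), c("targeting", 10), c("ablation", 8),
           c("targeting", 4), c("other", 6)),
      quick_scene(tool_angle_deg = 40, texture_seed = 11), seed = 101
    ), "proc_a")
    p2 <- generate_procedure(procedure_script(
      list(c("other", 6), c("targeting", 8), c("ablation", 8),
           c("targeting", 6), c("other", 8)),
      quick_scene(tool_angle_deg = 250, texture_seed = 23,
                  light_intensity = 0.6, turbidity = 0.25), seed = 202
    ), "proc_b")
    .fix$tiny_procs <- dplyr::bind_rows(p1, p2)
  }
  .fix$tiny_procs
}

# small detector trained on proc_a frames; learns the colour cue quickly
tiny_model <- function() {
  if (is.null(.fix$tiny_model)) {
    ds <- tiny_procedures()
    tr <- balanced_subsample(ds[ds$procedure_id == "proc_a", ], seed = 5)
    m <- build_model(backbone_config("small_cnn"), seed = 5)
    .fix$tiny_model <- suppressWarnings(
      train(m, tr, train_config(iterations = 300, seed = 5))
    )
  }
  .fix$tiny_model
}

# the simulated study mirroring the five-sequence clinical setting
study_dataset <- function() {
  if (is.null(.fix$study_ds)) {
    root <- file.path(tempdir(), "fetoseg-study")
    if (!dir.exists(root)) {
      generate_study(5, root, seed = 42, frames_per_procedure = 60,
                     image_size = 128)
    }
    .fix$study_ds <- load_dataset(root)
  }
  .fix$study_ds
}

# leave-one-procedure-out report over the study: shared by the filtering,
# end-to-end and baseline-comparison tests
study_report <- function() {
  if (is.null(.fix$study_report)) {
    .fix$study_report <- evaluate_study(
      study_dataset(),
      methods = c("raw_cnn", "filtered_cnn", "svm"),
      seed = 1
    )
  }
  .fix$study_report
}
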