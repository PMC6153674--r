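# Dataset I/O, class balancing, rotation augmentation and split plans.

test_that("write-then-load round trip preserves labels and pixels", {
  root <- file.path(tempdir(), "roundtrip")
  unlink(root, recursive = TRUE)
  generate_study(2, root, seed = 11, frames_per_procedure = 8,
                 image_size = 64)
  ds <- load_dataset(root)
  expect_equal(sort(unique(ds$procedure_id)), c("proc_01", "proc_02"))
  expect_equal(nrow(ds), 16)
  expect_identical(ds$binary, ds$phase == "ablation")
  # pixels survive the PNG round trip exactly (8-bit grid at render time)
  scr_frame <- ds$frame[[1]]
  rerendered <- load_dataset(root)$frame[[1]]
  expect_identical(scr_frame$pixels, rerendered$pixels)
  # frames sorted by (procedure_id, index)
  expect_false(is.unsorted(ds$index[ds$procedure_id == "proc_01"]))
})

test_that("malformed datasets are rejected with clear errors", {
  root <- file.path(tempdir(), "broken")
  unlink(root, recursive = TRUE)
  generate_study(2, root, seed = 12, frames_per_procedure = 4,
                 image_size = 64)
  # unknown phase string
  lab <- utils::read.csv(file.path(root, "proc_01", "labels.csv"))
  lab$phase[2] <- "lasering"
  utils::write.csv(lab, file.path(root, "proc_01", "labels.csv"),
                   row.names = FALSE)
  expect_error(load_dataset(root), "lasering")
  # missing frame file (and, symmetrically, an unlabelled frame file)
  lab$phase[2] <- "targeting"
  utils::write.csv(lab, file.path(root, "proc_01", "labels.csv"),
                   row.names = FALSE)
  unlink(file.path(root, "proc_02", "frames", "000001.png"))
  expect_error(load_dataset(root), "do not match")
  extra <- file.path(root, "proc_02", "frames")
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(extra, "000001.png"))
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(extra, "000099.png"))
  expect_error(load_dataset(root), "do not match")
  # no procedures at all
  empty <- file.path(tempdir(), "empty-root")
  unlink(empty, recursive = TRUE)
  dir.create(empty)
  expect_error(load_dataset(empty), "No procedure directories")
  expect_error(load_dataset(file.path(tempdir(), "no-such-dir")),
               "No such dataset root")
})

test_that("balanced_subsample equalises classes reproducibly", {
  ds <- tiny_procedures()
  n_pos <- sum(ds$binary)
  expect_gt(sum(!ds$binary), n_pos)  # imbalanced as generated
  bal <- balanced_subsample(ds, seed = 4)
  expect_equal(sum(bal$binary), n_pos)   # minority kept whole
  expect_equal(sum(!bal$binary), n_pos)  # majority subsampled to match
  bal2 <- balanced_subsample(ds, seed = 4)
  expect_identical(paste(bal$procedure_id, bal$index),
                   paste(bal2$procedure_id, bal2$index))
  bal3 <- balanced_subsample(ds, seed = 5)
  expect_false(identical(paste(bal$procedure_id, bal$index),
                         paste(bal3$procedure_id, bal3$index)))
  # already balanced input passes through (up to ordering)
  rebal <- balanced_subsample(bal, seed = 9)
  expect_equal(nrow(rebal), nrow(bal))
  expect_setequal(paste(rebal$procedure_id, rebal$index),
                  paste(bal$procedure_id, bal$index))
  # a missing class is named in the error
  expect_error(balanced_subsample(ds[ds$binary, ], seed = 1),
               "not-ablation")
  expect_error(balanced_subsample(ds[!ds$binary, ], seed = 1),
               "'ablation'")
})

test_that("rotation is exact at quarter turns and preserves labels", {
  fr <- render_frame(quick_scene(), "targeting", rng_seed = 2)
  expect_identical(random_rotation(fr, angle = 0)$pixels, fr$pixels)
  r90 <- random_rotation(fr, angle = 90)
  n <- dim(fr$pixels)[1]
  for (c in 1:3) {
    expected <- t(fr$pixels[, , c])[n:1, ]
    expect_equal(r90$pixels[, , c], expected * fr$mask, tolerance = 1e-12)
  }
  rr <- random_rotation(fr, seed = 77)
  expect_identical(rr$phase, fr$phase)
  expect_identical(dim(rr$pixels), dim(fr$pixels))
  expect_identical(rr$pixels, random_rotation(fr, seed = 77)$pixels)
})

test_that("interpolation leakage from random rotation is below 1%", {
  set.seed(55)
  for (i in 1:20) {
    ph <- sample(c("targeting", "ablation", "other"), 1)
    fr <- render_frame(quick_scene(texture_seed = i), ph, rng_seed = i)
    rot <- random_rotation(fr, seed = 1000 + i)
    m0 <- mean(fr$pixels[array(fr$mask, dim(fr$pixels))])
    m1 <- mean(rot$pixels[array(rot$mask, dim(rot$pixels))])
    expect_lt(abs(m1 - m0) / m0, 0.01)
  }
})

test_that("leave-one-procedure-out splits cover each procedure once", {
  ds <- study_dataset()
  splits <- make_loocv_splits(ds)
  expect_equal(nrow(splits), 5)
  vals <- unlist(splits$validation)
  expect_setequal(vals, unique(ds$procedure_id))
  expect_equal(anyDuplicated(vals), 0)
  for (i in seq_len(nrow(splits))) {
    expect_length(intersect(splits$train[[i]], splits$validation[[i]]), 0)
    expect_setequal(c(splits$train[[i]], splits$validation[[i]]),
                    unique(ds$procedure_id))
  }
  # two procedures: each trains on the other
  two <- tiny_procedures()
  s2 <- make_loocv_splits(two)
  expect_equal(nrow(s2), 2)
  expect_identical(s2$train[[1]], s2$validation[[2]])
  expect_identical(s2$train[[2]], s2$validation[[1]])
  expect_error(make_loocv_splits(two[two$procedure_id == "proc_a", ]),
               "at least 2")
  # k-fold grouping is available as an option
  s_k <- make_loocv_splits(ds, k = 2)
  expect_equal(nrow(s_k), 2)
  expect_setequal(unlist(s_k$validation), unique(ds$procedure_id))
  # serialisable
  path <- file.path(tempdir(), "splits.json")
  write_splits(splits, path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed, 5)
})
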