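# Binary ablation classifier. A compact convolutional network implemented
# directly on matrix operations (im2col + GEMM), with four architecture
# variants that share one head contract:
#
#   downsample224 - inputs downsampled to 224x224; stride-32 trunk ends in a
#                   7x7 feature map; global average pooling (the classical
#                   classification head).
#   avg448        - inputs at 448x448; the trunk ends in a 14x14 map and the
#                   average-pooling kernel is enlarged to cover it.
#   maxavg448     - inputs at 448x448; the original 7x7 average pool is kept
#                   and a max pool is added on the resulting 2x2 grid: a
#                   single "maximum over averages" pooling operation.
#   small_cnn     - a <=6-layer desk-scale network (64x64 inputs) with the
#                   same global-average head, trainable on one CPU in
#                   minutes. This is the default for simulated studies.
#
# The head always ends in a 2-way fully connected layer with softmax, so
# every prediction is a pair of class scores summing to 1.

.VARIANTS <- c("downsample224", "avg448", "maxavg448", "small_cnn")

#' Backbone configuration
#'
#' @param variant One of `"downsample224"`, `"avg448"`, `"maxavg448"`,
#'   `"small_cnn"`.
#' @param n_outputs Number of output labels; fixed at 2 (ablation vs not)
#'   for this detector.
#' @param pretrained Request externally supplied pre-trained trunk weights.
#'   No weights ship with the package, so `TRUE` raises an explicit error
#'   rather than silently falling back to random initialisation.
#' @return A `feto_backbone_config` list.
#' @export
backbone_config <- function(variant = "small_cnn", n_outputs = 2L,
                            pretrained = FALSE) {
  variant <- match.arg(variant, .VARIANTS)
  if (n_outputs != 2L) {
    stop("This detector is binary: n_outputs must be 2.", call. = FALSE)
  }
  structure(list(variant = variant, n_outputs = 2L, pretrained = pretrained),
            class = "feto_backbone_config")
}

#' Training configuration
#'
#' Two named profiles: `"desk"` (the package default for simulated studies:
#' 1000 iterations, batch 8, learning rate 0.05 with momentum 0.9 — sized
#' for the small_cnn on one CPU) and `"paper"` (the full-scale fine-tuning
#' recipe: 30000 iterations, learning rate 1e-5, batch 4). Any field can be
#' overridden individually.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param iterations,learning_rate,batch_size,momentum,seed Optional
#'   overrides.
#' @param augment Apply a fresh random rotation to every sampled training
#'   image (default `TRUE`).
#' @return A `feto_train_config` list.
#' @export
train_config <- function(profile = c("desk", "paper"),
                         iterations = NULL, learning_rate = NULL,
                         batch_size = NULL, momentum = 0.9,
                         seed = 1L, augment = TRUE) {
  profile <- match.arg(profile)
  base <- switch(profile,
    desk  = list(iterations = 1000L, learning_rate = 0.05, batch_size = 8L),
    paper = list(iterations = 30000L, learning_rate = 1e-5, batch_size = 4L)
  )
  cfg <- list(
    profile = profile,
    iterations = as.integer(iterations %||% base$iterations),
    learning_rate = learning_rate %||% base$learning_rate,
    batch_size = as.integer(batch_size %||% base$batch_size),
    momentum = momentum,
    seed = as.integer(seed),
    augment = isTRUE(augment)
  )
  stopifnot(cfg$iterations > 0, cfg$learning_rate > 0, cfg$batch_size > 0,
            cfg$momentum >= 0, cfg$momentum < 1)
  structure(cfg, class = "feto_train_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- pooling operators ------------------------------------------------------

#' Global average pooling over the full feature map
#'
#' Channel-wise mean over all spatial positions of a square `K x K x C`
#' feature map — the "enlarged kernel" average pool that connects a
#' higher-resolution trunk output directly to the classification layer.
#'
#' @param feature_map Numeric array `K x K x C` (square spatial dims).
#' @return Numeric vector of length `C`.
#' @export
pool_avg_full <- function(feature_map) {
  d <- dim(feature_map)
  if (length(d) != 3 || d[1] != d[2]) {
    stop("pool_avg_full() needs a square K x K x C feature map.",
         call. = FALSE)
  }
  colMeans(matrix(feature_map, d[1] * d[2], d[3]))
}

#' Maximum-over-averages pooling
#'
#' Keeps the original 7x7 average-pooling kernel (stride 7) and follows it
#' with a spatial max: on a `14 x 14 x C` map this averages each of the four
#' 7x7 blocks and takes the channel-wise maximum of the block means, acting
#' as a single pooling layer adapting the head to doubled input resolution.
#'
#' @param feature_map Numeric array `K x K x C` with `K` divisible by 7.
#' @return Numeric vector of length `C`.
#' @export
pool_max_of_avg <- function(feature_map) {
  d <- dim(feature_map)
  if (length(d) != 3 || d[1] != d[2]) {
    stop("pool_max_of_avg() needs a square K x K x C feature map.",
         call. = FALSE)
  }
  if (d[1] %% 7 != 0) {
    stop("Spatial size must be divisible by 7 (7x7 average kernel).",
         call. = FALSE)
  }
  nb <- d[1] %/% 7
  out <- numeric(d[3])
  for (c in seq_len(d[3])) {
    bm <- matrix(NA_real_, nb, nb)
    for (i in seq_len(nb)) {
      for (j in seq_len(nb)) {
        bm[i, j] <- mean(feature_map[(i - 1) * 7 + 1:7,
                                     (j - 1) * 7 + 1:7, c])
      }
    }
    out[c] <- max(bm)
  }
  out
}

# ---- input resizing ---------------------------------------------------------

#' Resize a frame to a variant's input resolution
#'
#' Bilinear resampling to the network input size: 224 for `downsample224`,
#' 448 for the two 448 variants, and the reduced 64-pixel desk-scale input
#' for `small_cnn`. Intensity range is preserved; an input already at the
#' target size passes through pixel-identically.
#'
#' @param frame A [new_frame()] object (square).
#' @param variant Architecture variant name.
#' @return Numeric array `S x S x 3`.
#' @export
resize_input <- function(frame, variant = "small_cnn") {
  variant <- match.arg(variant, .VARIANTS)
  px <- if (inherits(frame, "feto_frame")) frame$pixels else frame
  d <- dim(px)
  if (length(d) != 3 || d[1] != d[2]) {
    stop("resize_input() needs a square H x W x 3 frame.", call. = FALSE)
  }
  target <- switch(variant, downsample224 = 224L, avg448 = 448L,
                   maxavg448 = 448L, small_cnn = 64L)
  .resize_array(px, target)
}

# ---- convolution machinery --------------------------------------------------

# Layer geometry + precomputed im2col indices on the zero-padded image.
.conv_layer <- function(in_size, in_ch, out_ch, k, stride, pad) {
  out_size <- (in_size + 2 * pad - k) / stride + 1
  stopifnot(out_size == round(out_size), out_size >= 1)
  out_size <- as.integer(out_size)
  np <- in_size + 2L * pad
  npos <- out_size^2
  # position p (column-major over output rows/cols) -> patch top-left
  or_ <- rep(seq_len(out_size), times = out_size)
  oc_ <- rep(seq_len(out_size), each = out_size)
  r0 <- (or_ - 1L) * stride
  c0 <- (oc_ - 1L) * stride
  idx <- matrix(0L, npos, k * k)
  e <- 1L
  for (kc in seq_len(k)) {
    for (kr in seq_len(k)) {
      idx[, e] <- (c0 + kc - 1L) * np + (r0 + kr)
      e <- e + 1L
    }
  }
  list(in_size = in_size, out_size = out_size, in_ch = in_ch,
       out_ch = out_ch, k = k, stride = stride, pad = pad, np = np,
       idx = idx)
}

.he_init <- function(layer) {
  fan_in <- layer$k^2 * layer$in_ch
  matrix(stats::rnorm(fan_in * layer$out_ch, 0, sqrt(2 / fan_in)),
         fan_in, layer$out_ch)
}

.pad_channel <- function(ch, pad) {
  if (pad == 0) return(ch)
  n <- nrow(ch)
  out <- matrix(0, n + 2 * pad, n + 2 * pad)
  out[pad + seq_len(n), pad + seq_len(n)] <- ch
  out
}

# im2col for one image (array in_size x in_size x C)
.im2col <- function(img, layer) {
  k2 <- layer$k^2
  col <- matrix(0, nrow(layer$idx), k2 * layer$in_ch)
  for (c in seq_len(layer$in_ch)) {
    pc <- .pad_channel(img[, , c], layer$pad)
    col[, (c - 1L) * k2 + seq_len(k2)] <- pc[layer$idx]
  }
  col
}

# scatter-add a gradient col matrix back to image space (for interior layers)
.col2im <- function(dcol, layer) {
  k2 <- layer$k^2
  np <- layer$np
  dimg <- array(0, c(layer$in_size, layer$in_size, layer$in_ch))
  idx_v <- as.vector(layer$idx)
  for (c in seq_len(layer$in_ch)) {
    block <- dcol[, (c - 1L) * k2 + seq_len(k2)]
    acc <- rowsum(as.vector(block), idx_v)
    gp <- matrix(0, np, np)
    gp[as.integer(rownames(acc))] <- acc
    p <- layer$pad
    dimg[, , c] <- gp[p + seq_len(layer$in_size), p + seq_len(layer$in_size)]
  }
  dimg
}

# ---- model ------------------------------------------------------------------

#' Build a binary ablation classifier
#'
#' Constructs the requested architecture variant with seeded He-normal
#' initialisation. All variants map a square RGB frame to a pair of class
#' scores (softmax, summing to 1); the 448 variants differ only in their
#' pooling head ([pool_avg_full()] vs [pool_max_of_avg()]) over the 14x14
#' trunk output, while `downsample224` pools the 7x7 map of a 224 input.
#'
#' @param cfg A [backbone_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An untrained `feto_model`.
#' @export
build_model <- function(cfg = backbone_config(), seed = 1L) {
  stopifnot(inherits(cfg, "feto_backbone_config"))
  if (isTRUE(cfg$pretrained)) {
    stop("Pre-trained trunk weights are not bundled with this package; ",
         "supply them explicitly or build with pretrained = FALSE ",
         "(random initialisation is never substituted silently).",
         call. = FALSE)
  }
  v <- cfg$variant
  if (v == "small_cnn") {
    input_size <- 64L
    geo <- list(
      .conv_layer(64L, 3L, 12L, k = 4L, stride = 2L, pad = 1L),   # -> 32
      .conv_layer(32L, 12L, 24L, k = 4L, stride = 2L, pad = 1L),  # -> 16
      .conv_layer(16L, 24L, 32L, k = 4L, stride = 2L, pad = 1L)   # -> 8
    )
    pool_type <- "avg"
  } else {
    input_size <- if (v == "downsample224") 224L else 448L
    ch <- c(3L, 8L, 8L, 16L, 16L, 16L)
    sz <- input_size
    geo <- vector("list", 5L)
    for (i in 1:5) {
      geo[[i]] <- .conv_layer(sz, ch[i], ch[i + 1], k = 4L, stride = 2L,
                              pad = 1L)
      sz <- geo[[i]]$out_size
    }
    pool_type <- if (v == "maxavg448") "maxavg" else "avg"
  }
  n_feat <- geo[[length(geo)]]$out_ch
  params <- withr::with_seed(seed, {
    list(
      W = lapply(geo, .he_init),
      b = lapply(geo, function(l) numeric(l$out_ch)),
      Wfc = matrix(stats::rnorm(n_feat * 2, 0, sqrt(1 / n_feat)), n_feat, 2),
      bfc = numeric(2)
    )
  })
  structure(
    list(variant = v, input_size = input_size, layers = geo,
         pool_type = pool_type, params = params, n_outputs = 2L,
         trained = FALSE, loss_trace = NULL, config = cfg,
         init_seed = as.integer(seed)),
    class = "feto_model"
  )
}

#' @export
print.feto_model <- function(x, ...) {
  np <- sum(vapply(x$params$W, length, numeric(1))) +
    sum(vapply(x$params$b, length, numeric(1))) + length(x$params$Wfc) + 2
  cat("<feto_model> variant: ", x$variant, " | input ", x$input_size,
      " | head: ", x$pool_type, " pooling | ", np, " parameters | ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# head pooling for one feature map array, with backward bookkeeping
.pool_forward <- function(fmap, pool_type) {
  if (pool_type == "avg") {
    list(pooled = pool_avg_full(fmap), info = NULL)
  } else {
    d <- dim(fmap)
    nb <- d[1] %/% 7L
    C <- d[3]
    pooled <- numeric(C)
    arg <- matrix(0L, C, 2)
    for (c in seq_len(C)) {
      bm <- matrix(NA_real_, nb, nb)
      for (i in seq_len(nb)) for (j in seq_len(nb)) {
        bm[i, j] <- mean(fmap[(i - 1) * 7 + 1:7, (j - 1) * 7 + 1:7, c])
      }
      w <- which.max(bm)  # first max: deterministic tie-break
      pooled[c] <- bm[w]
      arg[c, ] <- c((w - 1L) %% nb + 1L, (w - 1L) %/% nb + 1L)
    }
    list(pooled = pooled, info = arg)
  }
}

.pool_backward <- function(dpooled, fmap_dim, pool_type, info) {
  K <- fmap_dim[1]; C <- fmap_dim[3]
  dfmap <- array(0, fmap_dim)
  if (pool_type == "avg") {
    for (c in seq_len(C)) dfmap[, , c] <- dpooled[c] / (K * K)
  } else {
    for (c in seq_len(C)) {
      i <- info[c, 1]; j <- info[c, 2]
      dfmap[(i - 1) * 7 + 1:7, (j - 1) * 7 + 1:7, c] <- dpooled[c] / 49
    }
  }
  dfmap
}

# full forward pass over a list of input arrays; returns scores and,
# optionally, the caches needed for backprop
.model_forward <- function(model, xs, keep_cache = FALSE) {
  N <- length(xs)
  L <- length(model$layers)
  caches <- if (keep_cache) vector("list", N)
  pooled <- matrix(0, N, model$layers[[L]]$out_ch)
  pool_info <- vector("list", N)
  for (i in seq_len(N)) {
    a <- xs[[i]] - 0.5  # centre intensities about zero
    cache_i <- if (keep_cache) vector("list", L)
    for (l in seq_len(L)) {
      lay <- model$layers[[l]]
      col <- .im2col(a, lay)
      z <- sweep(col %*% model$params$W[[l]], 2, model$params$b[[l]], "+")
      a_out <- pmax(z, 0)
      if (keep_cache) cache_i[[l]] <- list(col = col, pre = z)
      a <- array(a_out, c(lay$out_size, lay$out_size, lay$out_ch))
    }
    pf <- .pool_forward(a, model$pool_type)
    pooled[i, ] <- pf$pooled
    pool_info[[i]] <- pf$info
    if (keep_cache) caches[[i]] <- cache_i
  }
  logits <- sweep(pooled %*% model$params$Wfc, 2, model$params$bfc, "+")
  scores <- .softmax_rows(logits)
  list(scores = scores, pooled = pooled, caches = caches,
       pool_info = pool_info)
}

#' Train a binary ablation classifier
#'
#' Minimises softmax cross-entropy with stochastic gradient descent
#' (momentum 0.9 by default), updating the weights of all layers. Each
#' iteration samples a mini-batch from the training set and, when
#' `cfg$augment` is on, applies a fresh uniform random rotation to every
#' sampled image, so the network cannot latch onto the per-procedure tool
#' orientation. The per-iteration loss is logged. Given a seed the run is
#' deterministic.
#'
#' @param model An untrained (or previously trained) `feto_model`.
#' @param train_set Dataset tibble with a logical `binary` column; it should
#'   be class-balanced (see [balanced_subsample()]) — a warning is issued
#'   otherwise.
#' @param cfg A [train_config()].
#' @return The trained model, with a `loss_trace` tibble
#'   (`iteration`, `loss`).
#' @export
train <- function(model, train_set, cfg = train_config()) {
  stopifnot(inherits(model, "feto_model"), inherits(cfg, "feto_train_config"))
  if (nrow(train_set) == 0) stop("Empty training set.", call. = FALSE)
  n_pos <- sum(train_set$binary)
  n_neg <- sum(!train_set$binary)
  if (n_pos == 0 || n_neg == 0) {
    stop("Training set contains a single class (",
         if (n_pos == 0) "no ablation" else "no not-ablation",
         " frames); the binary objective is degenerate.", call. = FALSE)
  }
  if (n_pos != n_neg) {
    warning("Training set is not class-balanced (", n_pos, " ablation vs ",
            n_neg, " not-ablation); consider balanced_subsample().",
            call. = FALSE)
  }

  xs <- lapply(train_set$frame, resize_input, variant = model$variant)
  y <- as.integer(train_set$binary)  # 1 = ablation
  L <- length(model$layers)
  vel <- list(W = lapply(model$params$W, function(w) w * 0),
              b = lapply(model$params$b, function(b) b * 0),
              Wfc = model$params$Wfc * 0, bfc = c(0, 0))
  losses <- numeric(cfg$iterations)

  withr::with_seed(cfg$seed, {
    for (it in seq_len(cfg$iterations)) {
      bi <- sample.int(length(xs), cfg$batch_size, replace = TRUE)
      xb <- lapply(bi, function(j) {
        if (cfg$augment) {
          .rotate_array(xs[[j]], stats::runif(1, 0, 360))
        } else {
          xs[[j]]
        }
      })
      yb <- y[bi]
      fw <- .model_forward(model, xb, keep_cache = TRUE)
      p <- pmax(fw$scores, 1e-12)
      # column 2 = positive (ablation) class
      picked <- ifelse(yb == 1L, p[, 2], p[, 1])
      losses[it] <- -mean(log(picked))

      N <- length(xb)
      onehot <- matrix(c(1 - yb, yb), ncol = 2)
      dlogits <- (fw$scores - onehot) / N
      gWfc <- t(fw$pooled) %*% dlogits
      gbfc <- colSums(dlogits)
      dpooled <- dlogits %*% t(model$params$Wfc)

      gW <- lapply(model$params$W, function(w) w * 0)
      gb <- lapply(model$params$b, function(b) b * 0)
      for (i in seq_len(N)) {
        lay_last <- model$layers[[L]]
        fdim <- c(lay_last$out_size, lay_last$out_size, lay_last$out_ch)
        da <- .pool_backward(dpooled[i, ], fdim, model$pool_type,
                             fw$pool_info[[i]])
        for (l in rev(seq_len(L))) {
          lay <- model$layers[[l]]
          cache <- fw$caches[[i]][[l]]
          dz <- matrix(da, lay$out_size^2, lay$out_ch) * (cache$pre > 0)
          gW[[l]] <- gW[[l]] + t(cache$col) %*% dz
          gb[[l]] <- gb[[l]] + colSums(dz)
          if (l > 1L) {
            dcol <- dz %*% t(model$params$W[[l]])
            da <- .col2im(dcol, lay)
          }
        }
      }

      lr <- cfg$learning_rate; mom <- cfg$momentum
      for (l in seq_len(L)) {
        vel$W[[l]] <- mom * vel$W[[l]] - lr * gW[[l]]
        vel$b[[l]] <- mom * vel$b[[l]] - lr * gb[[l]]
        model$params$W[[l]] <- model$params$W[[l]] + vel$W[[l]]
        model$params$b[[l]] <- model$params$b[[l]] + vel$b[[l]]
      }
      vel$Wfc <- mom * vel$Wfc - lr * gWfc
      vel$bfc <- mom * vel$bfc - lr * gbfc
      model$params$Wfc <- model$params$Wfc + vel$Wfc
      model$params$bfc <- model$params$bfc + vel$bfc
    }
  })

  model$trained <- TRUE
  model$loss_trace <- tibble::tibble(iteration = seq_len(cfg$iterations),
                                     loss = losses)
  model$train_config <- cfg
  model
}

#' Class scores for frames
#'
#' Runs the forward pass (no augmentation) and returns the two softmax
#' scores per frame. Accepts a single frame, a list of frames, or a dataset
#' tibble with a `frame` column.
#'
#' @param model A `feto_model`.
#' @param frames Frame(s) to score.
#' @param require_trained Error on an untrained model (default `TRUE`).
#' @return A tibble with columns `score_positive` (ablation) and
#'   `score_negative`, each row summing to 1.
#' @export
predict_scores <- function(model, frames, require_trained = TRUE) {
  stopifnot(inherits(model, "feto_model"))
  if (require_trained && !isTRUE(model$trained)) {
    stop("Model has not been trained; train() it or load a checkpoint.",
         call. = FALSE)
  }
  fl <- if (inherits(frames, "feto_frame")) {
    list(frames)
  } else if (is.data.frame(frames)) {
    frames$frame
  } else {
    frames
  }
  xs <- lapply(fl, resize_input, variant = model$variant)
  sc <- .model_forward(model, xs)$scores
  tibble::tibble(score_positive = unname(sc[, 2]),
                 score_negative = unname(sc[, 1]))
}

#' Save / load a model checkpoint
#'
#' @param model A `feto_model`.
#' @param path Checkpoint file path (`.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "feto_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "feto_model")) {
    stop("Not a feto_model checkpoint: ", path, call. = FALSE)
  }
  m
}
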