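# Synthetic fetoscopy rendering. The goal is not photorealism but a
# controllable scene that reproduces the appearance factors reported for
# clinical TTTS sequences: bright vs dim light sources, amniotic-fluid
# turbidity, defocus, a laser fibre at a fixed per-procedure orientation,
# a green low-power targeting spot, and a blue high-intensity ablation spot
# over a whitening coagulation blob.

# palette (RGB in [0,1]); green/blue kept nearly equal in non-spot elements
# so the channel-swap heuristic is driven by the laser light, as in vivo.
.COL_PLACENTA <- c(0.50, 0.28, 0.27)
.COL_TOOL     <- c(0.24, 0.25, 0.25)
.COL_OCCLUDER <- c(0.38, 0.24, 0.23)
.COL_HAZE     <- c(0.82, 0.82, 0.82)
.COL_SPOT_TGT <- c(0.10, 0.95, 0.20)   # targeting: green dominant
.COL_SPOT_ABL <- c(0.10, 0.20, 0.95)   # ablation: the same light, blue
.COL_CANNULA  <- c(0.15, 0.30, 0.90)
.SPOT_PEAK    <- 0.55                  # targeting peak amplitude
.ABL_GAIN     <- 2.2                   # ablation peak / targeting peak
.BLOB_AMP     <- 0.40                  # coagulation whitening amplitude

.c3 <- function(col, gray) if (gray) rep(mean(col), 3) else col

# defocus strong enough that the spot is no longer a usable cue
.defocus_limit <- function(n) 0.025 * n

# deterministic placenta-like background texture (per texture_seed):
# a base colour modulated by a handful of smooth random blobs.
.render_background <- function(scene, xg, yg) {
  n <- scene$image_size
  base <- .c3(.COL_PLACENTA, scene$background_gray)
  tex <- withr::with_seed(scene$texture_seed, {
    t <- matrix(0, n, n)
    for (k in 1:6) {
      cx <- stats::runif(1, 0.15 * n, 0.85 * n)
      cy <- stats::runif(1, 0.15 * n, 0.85 * n)
      s  <- stats::runif(1, 0.10 * n, 0.30 * n)
      a  <- stats::runif(1, -0.12, 0.12)
      t <- t + a * exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * s^2))
    }
    t
  })
  px <- array(0, dim = c(n, n, 3))
  for (c in 1:3) px[, , c] <- base[c] * (1 + tex)
  px
}

# additive Gaussian light blob of a given colour
.add_blob <- function(px, xg, yg, cx, cy, sigma, amp, col) {
  g <- amp * exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * sigma^2))
  for (c in 1:3) px[, , c] <- px[, , c] + col[c] * g
  px
}

# opaque-ish element (tool / occluder) blended with a soft-edged alpha
.blend_alpha <- function(px, alpha, col) {
  for (c in 1:3) px[, , c] <- (1 - alpha) * px[, , c] + alpha * col[c]
  px
}

#' Render one synthetic fetoscopic frame
#'
#' Draws the scope disc, a textured placenta background under radial
#' illumination, the laser fibre at the procedure's fixed orientation, and —
#' depending on the phase — the projected laser spot: a green low-power spot
#' while `targeting`, or a brighter blue spot with a whitening coagulation
#' blob during `ablation`. `other` frames have no usable spot, arising from
#' one of three mechanisms: the laser is off (`spot_visible = FALSE`), the
#' spot is covered by an umbilical-cord-like occluder
#' (`occluder_present = TRUE`), or the scene is strongly defocused
#' (`blur_sigma` beyond the defocus limit) with the spot washed out.
#' Rendering is bitwise deterministic for a fixed `(scene, phase, rng_seed)`.
#'
#' @param scene A [scene_params()] object.
#' @param phase `"ablation"`, `"targeting"` or `"other"`.
#' @param rng_seed Integer seed for per-frame jitter, clutter and sensor
#'   noise.
#' @param procedure_id,index Metadata stored on the frame.
#' @return A [new_frame()] object. The `spot` element records the spot
#'   centre, Gaussian sigma and a radius (1.5 sigma) defining the "spot
#'   region" used by diagnostics and tests.
#' @examples
#' fr <- render_frame(scene_params(image_size = 96), "ablation", rng_seed = 1)
#' range(fr$pixels)
#' @export
render_frame <- function(scene, phase, rng_seed = 1L,
                         procedure_id = "proc", index = 0L) {
  stopifnot(inherits(scene, "feto_scene"))
  phase <- check_phase(phase)
  n <- scene$image_size
  c0 <- (n + 1) / 2
  xg <- matrix(rep(seq_len(n), each = n), n, n)   # x = column
  yg <- matrix(rep(seq_len(n), times = n), n, n)  # y = row
  mask <- disc_mask(n, scene$scope_radius_frac)
  R <- scene$scope_radius_frac * n / 2
  gray <- scene$background_gray

  withr::with_seed(rng_seed, {
    px <- .render_background(scene, xg, yg)

    # radial vignette under the given light intensity
    r2 <- ((xg - c0)^2 + (yg - c0)^2) / (R^2)
    vig <- scene$light_intensity * (1 - 0.45 * pmin(r2, 1))
    for (c in 1:3) px[, , c] <- px[, , c] * vig

    # laser fibre: dark rod from the rim towards the centre
    th <- scene$tool_angle_deg * pi / 180
    u <- c(cos(th), sin(th))
    tipd <- 0.50 * R
    p1 <- c(c0, c0) + u * (n / 2)
    p2 <- c(c0, c0) + u * tipd
    seg <- p1 - p2
    len2 <- sum(seg^2)
    tproj <- pmin(pmax(((xg - p2[1]) * seg[1] + (yg - p2[2]) * seg[2]) / len2,
                       0), 1)
    dseg <- sqrt((xg - (p2[1] + tproj * seg[1]))^2 +
                 (yg - (p2[2] + tproj * seg[2]))^2)
    wtool <- 0.045 * n
    alpha <- pmin(pmax((wtool - dseg) / (0.25 * wtool), 0), 1)
    px <- .blend_alpha(px, alpha, .c3(.COL_TOOL, gray) * scene$light_intensity)

    # laser spot position: just beyond the fibre tip, jittered per frame
    jit <- stats::rnorm(2, 0, 0.010 * n)
    spot_c <- c(c0, c0) + u * (tipd - 0.12 * R) + jit
    sigma_spot <- 0.055 * n * stats::runif(1, 0.85, 1.15)

    draw_spot <- FALSE
    spot_col <- NULL
    spot_amp <- 0
    defocused_other <- FALSE
    if (phase == "targeting") {
      draw_spot <- TRUE
      spot_col <- .COL_SPOT_TGT
      spot_amp <- .SPOT_PEAK * scene$spot_gain
    } else if (phase == "ablation") {
      draw_spot <- TRUE
      spot_col <- .COL_SPOT_ABL
      spot_amp <- .SPOT_PEAK * .ABL_GAIN * scene$spot_gain
    } else {
      # "other": laser off, occluded, or defocused-with-faded-spot
      if (scene$spot_visible && scene$occluder_present) {
        draw_spot <- TRUE
        spot_col <- .COL_SPOT_TGT
        spot_amp <- .SPOT_PEAK * scene$spot_gain
      } else if (scene$spot_visible &&
                 scene$blur_sigma >= .defocus_limit(n)) {
        draw_spot <- TRUE
        spot_col <- .COL_SPOT_TGT
        spot_amp <- 0.18 * .SPOT_PEAK * scene$spot_gain
        defocused_other <- TRUE
      }
    }

    if (draw_spot) {
      px <- .add_blob(px, xg, yg, spot_c[1], spot_c[2], sigma_spot,
                      spot_amp, spot_col)
      if (phase == "ablation") {
        # whitening coagulated vessel under the blue spot
        px <- .add_blob(px, xg, yg, spot_c[1], spot_c[2], 0.55 * sigma_spot,
                        .BLOB_AMP * scene$spot_gain, .c3(c(1, 1, 1), FALSE))
      }
    }

    # occluder covers the spot area (drawn after the spot: in front of it)
    if (phase == "other" && scene$spot_visible && scene$occluder_present) {
      occ_c <- spot_c + stats::rnorm(2, 0, 0.02 * n)
      d2 <- ((xg - occ_c[1])^2 + (yg - occ_c[2])^2) / (0.22 * n)^2
      alpha_o <- pmin(pmax((1.1 - d2) / 0.2, 0), 1)
      px <- .blend_alpha(px, alpha_o,
                         .c3(.COL_OCCLUDER, gray) * scene$light_intensity)
    }

    # specular highlights (achromatic, anywhere but the spot region)
    n_spec <- stats::rbinom(1, 2, 0.4)
    for (k in seq_len(n_spec)) {
      repeat {
        sc_ <- c(stats::runif(1, 0.2 * n, 0.8 * n),
                 stats::runif(1, 0.2 * n, 0.8 * n))
        if (!draw_spot ||
            sum((sc_ - spot_c)^2) > (4 * sigma_spot)^2) break
      }
      px <- .add_blob(px, xg, yg, sc_[1], sc_[2], 0.012 * n,
                      stats::runif(1, 0.2, 0.5), c(1, 1, 1))
    }

    # coloured clutter (e.g. bluish cannula) with probability scene$clutter
    clutter_p <- if (is.null(scene$clutter)) 0 else scene$clutter
    if (clutter_p > 0 && stats::runif(1) < clutter_p) {
      repeat {
        cc <- c(stats::runif(1, 0.15 * n, 0.85 * n),
                stats::runif(1, 0.15 * n, 0.85 * n))
        if (!draw_spot || sum((cc - spot_c)^2) > (4 * sigma_spot)^2) break
      }
      px <- .add_blob(px, xg, yg, cc[1], cc[2], 0.08 * n,
                      stats::runif(1, 0.2, 0.45), .c3(.COL_CANNULA, gray))
    }

    # amniotic-fluid turbidity: contrast loss towards a milky haze
    if (scene$turbidity > 0) {
      a <- 0.7 * scene$turbidity
      haze <- .c3(.COL_HAZE, FALSE) * scene$light_intensity
      for (c in 1:3) px[, , c] <- (1 - a) * px[, , c] + a * haze[c]
    }

    # defocus, then sensor noise
    px <- .blur_array(px, scene$blur_sigma)
    if (scene$noise_sd > 0) {
      px <- px + array(stats::rnorm(length(px), 0, scene$noise_sd), dim(px))
    }

    px <- .quantize8(px)
    for (c in 1:3) px[, , c] <- px[, , c] * mask

    spot_info <- list(
      cx = spot_c[1], cy = spot_c[2], sigma = sigma_spot,
      region_radius = 1.5 * sigma_spot,
      visible = draw_spot && !defocused_other &&
        !(phase == "other" && scene$occluder_present)
    )
    new_frame(px, mask, phase, procedure_id, index, spot = spot_info)
  })
}

#' Render an exactly channel-swap-related targeting/ablation pair
#'
#' Produces two frames that are pixelwise identical except that the green
#' and blue channels of the whole image are exchanged: the targeting member
#' carries the green spot, the ablation member the blue one. The scene must
#' be achromatic (`background_gray = TRUE`) so that everything outside the
#' spot is a fixed point of the swap; the ablation member is constructed by
#' swapping the composited targeting member, which guarantees the symmetry
#' bitwise (same geometry, same noise realisation).
#'
#' @param scene A [scene_params()] with `background_gray = TRUE`.
#' @param rng_seed Integer seed.
#' @return A list with elements `targeting` and `ablation` (two
#'   [new_frame()] objects).
#' @seealso [swap_green_blue()]
#' @export
render_matched_pair <- function(scene, rng_seed = 1L) {
  stopifnot(inherits(scene, "feto_scene"))
  if (!isTRUE(scene$background_gray)) {
    stop("render_matched_pair() needs background_gray = TRUE; a chromatic ",
         "background breaks the exact swap symmetry.", call. = FALSE)
  }
  tgt <- render_frame(scene, "targeting", rng_seed = rng_seed)
  abl_px <- tgt$pixels[, , c(1, 3, 2)]
  abl <- new_frame(abl_px, tgt$mask, "ablation", tgt$procedure_id,
                   tgt$index, spot = tgt$spot)
  list(targeting = tgt, ablation = abl)
}

#' Generate all frames of one scripted procedure
#'
#' Walks the script's phase segments in order, rendering each frame with
#' per-frame jitter (spot position, illumination flicker, clutter, noise)
#' drawn from the script seed. The laser-tool orientation stays fixed for
#' the whole procedure. `other` frames alternate between the three
#' generating mechanisms (laser off / occluded / defocused).
#'
#' @param script A [procedure_script()].
#' @param procedure_id Identifier stored on every frame.
#' @return A tibble with columns `procedure_id`, `index`, `phase`, `binary`
#'   and a `frame` list-column of [new_frame()] objects.
#' @export
generate_procedure <- function(script, procedure_id = "proc_01") {
  stopifnot(inherits(script, "feto_script"))
  seg <- script$segments
  phases <- rep(seg$phase, seg$n_frames)
  n <- length(phases)
  sc <- script$scene

  plan <- withr::with_seed(script$seed, {
    tibble::tibble(
      index = seq_len(n) - 1L,
      phase = phases,
      rng_seed = sample.int(.Machine$integer.max - 1L, n),
      light_jit = stats::runif(n, 0.95, 1.05),
      mech = sample(c("off", "occluded", "defocused"), n, replace = TRUE)
    )
  })

  frames <- purrr::pmap(plan, function(index, phase, rng_seed, light_jit,
                                       mech) {
    s <- sc
    s$light_intensity <- min(1, sc$light_intensity * light_jit)
    if (phase == "other") {
      if (mech == "off") {
        s$spot_visible <- FALSE
      } else if (mech == "occluded") {
        s$spot_visible <- TRUE
        s$occluder_present <- TRUE
      } else {
        s$spot_visible <- TRUE
        s$occluder_present <- FALSE
        s$blur_sigma <- max(sc$blur_sigma, 1.6 * .defocus_limit(sc$image_size))
      }
    }
    render_frame(s, phase, rng_seed = rng_seed,
                 procedure_id = procedure_id, index = index)
  })

  tibble::tibble(
    procedure_id = procedure_id,
    index = plan$index,
    phase = plan$phase,
    binary = phase_to_binary(plan$phase),
    frame = frames
  )
}

#' Appearance-variability ranges for a simulated study
#'
#' Defaults emulate the reported spread of clinical sequences: mostly bright
#' clear fluid, with (for studies of five or more procedures) one
#' high-turbidity procedure, one dim-light procedure and one weak-laser
#' procedure, mirroring the five-sequence clinical setting.
#'
#' @param light,turbidity,blur_frac,spot_gain Ranges (length-2 numeric) for
#'   the typical procedure; `blur_frac` is blur sigma as a fraction of the
#'   image size.
#' @param dim_light,high_turbidity,weak_spot Ranges for the three atypical
#'   procedures drawn when `n_procedures >= 5`.
#' @param clutter Per-frame probability of a coloured distractor blob.
#' @return A named list of ranges.
#' @export
study_variability <- function(light = c(0.75, 1.0),
                              turbidity = c(0.0, 0.2),
                              blur_frac = c(0.0, 0.012),
                              spot_gain = c(0.8, 1.0),
                              dim_light = c(0.30, 0.45),
                              high_turbidity = c(0.50, 0.80),
                              weak_spot = c(0.25, 0.40),
                              clutter = 0.3) {
  list(light = light, turbidity = turbidity, blur_frac = blur_frac,
       spot_gain = spot_gain, dim_light = dim_light,
       high_turbidity = high_turbidity, weak_spot = weak_spot,
       clutter = clutter)
}

# random phase script totalling exactly n_frames, with ablation bursts
# flanked by targeting, roughly one fifth ablation frames (ablation is the
# minority class, as in annotated clinical sequences); shorter procedures
# fall back to fewer segments
.draw_segments <- function(n_frames) {
  ph <- c("other", "targeting", "ablation", "targeting", "other",
          "targeting", "ablation", "targeting", "other")
  base <- c(0.12, 0.16, 0.10, 0.08, 0.10, 0.12, 0.10, 0.08, 0.14)
  if (n_frames < 2L * length(ph)) {
    ph <- c("other", "targeting", "ablation", "targeting", "other")
    base <- c(0.20, 0.25, 0.20, 0.15, 0.20)
  }
  if (n_frames < length(ph)) {
    ph <- c("targeting", "ablation", "targeting")
    base <- c(0.4, 0.3, 0.3)
  }
  if (n_frames < length(ph)) {
    stop("frames_per_procedure must be >= 3.", call. = FALSE)
  }
  w <- stats::runif(length(ph), 0.6, 1.4) * base
  nf <- pmax(1L, as.integer(floor(w / sum(w) * n_frames)))
  # settle the remainder deterministically, keeping every segment >= 1
  diff <- n_frames - sum(nf)
  j <- 1L
  while (diff != 0L) {
    k <- (j - 1L) %% length(nf) + 1L
    if (diff > 0L) {
      nf[k] <- nf[k] + 1L
      diff <- diff - 1L
    } else if (nf[k] > 1L) {
      nf[k] <- nf[k] - 1L
      diff <- diff + 1L
    }
    j <- j + 1L
  }
  tibble::tibble(phase = ph, n_frames = nf)
}

#' Generate a multi-procedure synthetic study on disk
#'
#' Draws distinct scene parameters per procedure from the given variability
#' ranges, renders every procedure, and writes the dataset layout
#' `<root>/<procedure_id>/frames/%06d.png` plus per-procedure `labels.csv`
#' (columns `index`, `phase`, `binary`) and a study-level `manifest.json`
#' recording every scene parameter, seed and segment script.
#'
#' For `n_procedures >= 5` the third, fourth and fifth procedures are the
#' atypical ones (high turbidity, dim light, weak laser respectively);
#' remaining procedures draw from the typical ranges.
#'
#' @param n_procedures Number of procedures (>= 2).
#' @param root Output directory (created; must not exist unless
#'   `overwrite = TRUE`).
#' @param seed Integer master seed.
#' @param variability See [study_variability()].
#' @param frames_per_procedure Frames rendered per procedure.
#' @param image_size Rendered image side in pixels.
#' @param overwrite Replace an existing `root`.
#' @return (Invisibly) the manifest as a list.
#' @export
generate_study <- function(n_procedures, root, seed = 1L,
                           variability = study_variability(),
                           frames_per_procedure = 60L,
                           image_size = 448L,
                           overwrite = FALSE) {
  if (n_procedures < 2) {
    stop("A study needs n_procedures >= 2 (cross-validation by procedure).",
         call. = FALSE)
  }
  if (dir.exists(root)) {
    if (!overwrite) {
      stop("Output directory exists: ", root,
           " (pass overwrite = TRUE to replace it).", call. = FALSE)
    }
    unlink(root, recursive = TRUE)
  }
  dir.create(root, recursive = TRUE)

  v <- variability
  draws <- withr::with_seed(seed, {
    ids <- sprintf("proc_%02d", seq_len(n_procedures))
    angle <- stats::runif(n_procedures, 0, 360)
    kind <- rep("typical", n_procedures)
    if (n_procedures >= 5) kind[3:5] <- c("turbid", "dim", "weak")
    tibble::tibble(
      procedure_id = ids,
      kind = kind,
      tool_angle_deg = angle,
      light = ifelse(kind == "dim",
                     stats::runif(n_procedures, v$dim_light[1], v$dim_light[2]),
                     stats::runif(n_procedures, v$light[1], v$light[2])),
      turbidity = ifelse(kind == "turbid",
                         stats::runif(n_procedures, v$high_turbidity[1],
                                      v$high_turbidity[2]),
                         stats::runif(n_procedures, v$turbidity[1],
                                      v$turbidity[2])),
      blur_sigma = stats::runif(n_procedures, v$blur_frac[1],
                                v$blur_frac[2]) * image_size,
      spot_gain = ifelse(kind == "weak",
                         stats::runif(n_procedures, v$weak_spot[1],
                                      v$weak_spot[2]),
                         stats::runif(n_procedures, v$spot_gain[1],
                                      v$spot_gain[2])),
      texture_seed = sample.int(1e6, n_procedures),
      script_seed = sample.int(.Machine$integer.max - 1L, n_procedures),
      segment_seed = sample.int(.Machine$integer.max - 1L, n_procedures)
    )
  })

  manifest <- list(
    seed = seed,
    n_procedures = n_procedures,
    frames_per_procedure = frames_per_procedure,
    image_size = image_size,
    variability = v,
    procedures = list()
  )

  for (i in seq_len(n_procedures)) {
    d <- draws[i, ]
    scene <- scene_params(
      image_size = image_size,
      light_intensity = d$light,
      turbidity = d$turbidity,
      blur_sigma = d$blur_sigma,
      tool_angle_deg = d$tool_angle_deg,
      texture_seed = d$texture_seed,
      spot_gain = d$spot_gain
    )
    scene$clutter <- v$clutter
    seg <- withr::with_seed(d$segment_seed,
                            .draw_segments(frames_per_procedure))
    script <- procedure_script(seg, scene, seed = d$script_seed)
    proc <- generate_procedure(script, procedure_id = d$procedure_id)
    write_procedure(proc, root)
    manifest$procedures[[d$procedure_id]] <- list(
      kind = d$kind,
      scene = unclass(scene),
      seed = d$script_seed,
      segments = as.data.frame(seg)
    )
  }

  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
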