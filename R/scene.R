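#' Scene parameters for the fetoscopy simulator
#'
#' Bundles the appearance factors that vary between (and within) TTTS
#' procedures: lighting, amniotic-fluid turbidity, defocus, the fixed
#' laser-tool orientation, and the state of the projected laser spot.
#'
#' @param image_size Square image side in pixels (default 448).
#' @param scope_radius_frac Scope-disc radius as a fraction of the image
#'   half-width, in (0, 1].
#' @param light_intensity Overall illumination scalar in (0, 1]; the paper's
#'   sequences range from bright to very dim.
#' @param turbidity Amniotic-fluid haze strength in \[0, 1\]; 0 is clear fluid.
#' @param blur_sigma Defocus blur (Gaussian sigma, pixels, >= 0).
#' @param tool_angle_deg Orientation of the laser fibre entering the field of
#'   view, degrees in \[0, 360). Fixed within one procedure, arbitrary between
#'   procedures.
#' @param spot_visible Is the laser pointer turned on? Phases `targeting` and
#'   `ablation` always draw the spot; for `other` frames `FALSE` means
#'   "laser off".
#' @param occluder_present Draw an umbilical-cord-like occluder over the spot
#'   position (one of the ways an `other` frame arises).
#' @param background_gray Render an achromatic background/tool (R = G = B)
#'   so the green/blue channel swap is an exact pixel symmetry; used by
#'   [render_matched_pair()].
#' @param texture_seed Integer seed for the placenta background texture
#'   (constant within a procedure).
#' @param spot_gain Laser spot strength in (0, 1]; values well below 1
#'   emulate the weak, barely projected laser of the paper's hardest
#'   sequence.
#' @param noise_sd Per-pixel Gaussian sensor noise standard deviation.
#' @return An object of class `feto_scene` (a validated named list).
#' @examples
#' sc <- scene_params(image_size = 96)
#' fr <- render_frame(sc, "targeting", rng_seed = 1)
#' @export
scene_params <- function(image_size = 448,
                         scope_radius_frac = 0.95,
                         light_intensity = 0.9,
                         turbidity = 0.1,
                         blur_sigma = 0.5,
                         tool_angle_deg = 30,
                         spot_visible = TRUE,
                         occluder_present = FALSE,
                         background_gray = FALSE,
                         texture_seed = 1L,
                         spot_gain = 1,
                         noise_sd = 0.01) {
  if (length(image_size) != 1 || !is.finite(image_size) || image_size < 8 ||
      image_size != round(image_size)) {
    stop("`image_size` must be a single positive integer >= 8 (square images).",
         call. = FALSE)
  }
  stopifnot(
    scope_radius_frac > 0, scope_radius_frac <= 1,
    light_intensity > 0, light_intensity <= 1,
    turbidity >= 0, turbidity <= 1,
    blur_sigma >= 0,
    tool_angle_deg >= 0, tool_angle_deg < 360,
    is.logical(spot_visible), is.logical(occluder_present),
    is.logical(background_gray),
    spot_gain > 0, spot_gain <= 1,
    noise_sd >= 0
  )
  structure(
    list(
      image_size = as.integer(image_size),
      scope_radius_frac = scope_radius_frac,
      light_intensity = light_intensity,
      turbidity = turbidity,
      blur_sigma = blur_sigma,
      tool_angle_deg = tool_angle_deg,
      spot_visible = spot_visible,
      occluder_present = occluder_present,
      background_gray = background_gray,
      texture_seed = as.integer(texture_seed),
      spot_gain = spot_gain,
      noise_sd = noise_sd
    ),
    class = "feto_scene"
  )
}

#' @export
print.feto_scene <- function(x, ...) {
  cat("<feto_scene> ", x$image_size, "x", x$image_size,
      " | light ", x$light_intensity,
      " | turbidity ", x$turbidity,
      " | blur ", x$blur_sigma,
      " | tool ", x$tool_angle_deg, "deg",
      " | spot gain ", x$spot_gain, "\n", sep = "")
  invisible(x)
}

#' Workflow phases
#'
#' The three surgical activity classes, plus the binary projection used for
#' annotation and detection (`ablation` vs everything else).
#' @name phases
#' @keywords internal
NULL

.PHASES <- c("ablation", "targeting", "other")

#' Validate a phase label
#' @param phase Character scalar, one of `"ablation"`, `"targeting"`,
#'   `"other"`.
#' @return The phase, normalised.
#' @keywords internal
check_phase <- function(phase) {
  if (length(phase) != 1 || !phase %in% .PHASES) {
    stop("Unknown phase '", paste(phase, collapse = ","),
         "'; must be one of: ", paste(.PHASES, collapse = ", "), ".",
         call. = FALSE)
  }
  phase
}

#' Binary projection of a phase label
#'
#' `TRUE` iff the phase is `ablation` — the annotation the detector is
#' trained on.
#' @param phase Character vector of phases.
#' @return Logical vector.
#' @export
phase_to_binary <- function(phase) {
  bad <- setdiff(unique(phase), .PHASES)
  if (length(bad)) {
    stop("Unknown phase label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  phase == "ablation"
}

#' Temporal script of a simulated procedure
#'
#' Orders the workflow phases of one synthetic TTTS procedure. Ablation
#' bursts must sit next to targeting segments (the laser is aimed before and
#' after it fires); the constraint can be lifted for deliberately
#' pathological fixtures.
#'
#' @param segments A data frame / tibble with columns `phase` and `n_frames`,
#'   or a list of `c(phase, n_frames)` pairs.
#' @param scene A [scene_params()] object.
#' @param seed Integer seed driving all per-frame jitter.
#' @param check_adjacency Enforce the ablation-next-to-targeting rule
#'   (default `TRUE`).
#' @return An object of class `feto_script`.
#' @examples
#' sc <- scene_params(image_size = 96)
#' scr <- procedure_script(
#'   list(c("targeting", 5), c("ablation", 3), c("other", 4)),
#'   scene = sc, seed = 7
#' )
#' @export
procedure_script <- function(segments, scene, seed = 1L,
                             check_adjacency = TRUE) {
  stopifnot(inherits(scene, "feto_scene"))
  if (is.data.frame(segments)) {
    seg <- tibble::tibble(
      phase = as.character(segments$phase),
      n_frames = as.integer(segments$n_frames)
    )
  } else {
    seg <- tibble::tibble(
      phase = vapply(segments, function(s) as.character(s[[1]]), character(1)),
      n_frames = vapply(segments, function(s) as.integer(s[[2]]), integer(1))
    )
  }
  purrr::walk(seg$phase, check_phase)
  if (any(seg$n_frames < 1)) {
    stop("Every segment needs n_frames >= 1.", call. = FALSE)
  }
  if (check_adjacency && nrow(seg) > 0) {
    abl <- which(seg$phase == "ablation")
    for (i in abl) {
      nb <- c(if (i > 1) seg$phase[i - 1], if (i < nrow(seg)) seg$phase[i + 1])
      if (!"targeting" %in% nb) {
        stop("Ablation segment ", i, " is not adjacent to a targeting ",
             "segment; pass check_adjacency = FALSE to override.",
             call. = FALSE)
      }
    }
  }
  structure(
    list(segments = seg, scene = scene, seed = as.integer(seed)),
    class = "feto_script"
  )
}

#' @export
print.feto_script <- function(x, ...) {
  cat("<feto_script> ", nrow(x$segments), " segments, ",
      sum(x$segments$n_frames), " frames, seed ", x$seed, "\n", sep = "")
  print(x$segments)
  invisible(x)
}

#' Construct a frame object
#'
#' A single RGB fetoscopic image with its scope mask and metadata. Channel
#' order is red-green-blue throughout the package.
#'
#' @param pixels `H x W x 3` numeric array in \[0, 1\].
#' @param mask `H x W` logical scope mask.
#' @param phase Phase label or `NA`.
#' @param procedure_id Procedure identifier.
#' @param index 0-based frame index within the procedure.
#' @param spot Optional list describing the rendered spot (centre, sigma,
#'   visibility) used by diagnostics.
#' @return Object of class `feto_frame`.
#' @export
new_frame <- function(pixels, mask, phase = NA_character_,
                      procedure_id = "proc", index = 0L, spot = NULL) {
  d <- dim(pixels)
  stopifnot(length(d) == 3, d[3] == 3, d[1] == d[2])
  stopifnot(is.logical(mask), all(dim(mask) == d[1:2]))
  structure(
    list(
      pixels = pixels,
      mask = mask,
      phase = phase,
      binary = if (is.na(phase)) NA else phase == "ablation",
      procedure_id = procedure_id,
      index = as.integer(index),
      spot = spot
    ),
    class = "feto_frame"
  )
}

#' @export
print.feto_frame <- function(x, ...) {
  cat("<feto_frame> ", dim(x$pixels)[1], "x", dim(x$pixels)[2],
      " | ", x$procedure_id, "[", x$index, "] | phase: ",
      ifelse(is.na(x$phase), "<unlabelled>", x$phase), "\n", sep = "")
  invisible(x)
}

#' @export
dim.feto_frame <- function(x) dim(x$pixels)
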