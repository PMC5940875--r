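#' Parameters of a synthetic neck-thermogram phantom
#'
#' Describes a frontal-neck surface-temperature field: a baseline with
#' smoothed Gaussian noise mirrored about the vertical midline (so a
#' disease-free neck is bilaterally symmetric up to noise), optionally
#' perturbed on one side by a Gaussian-profile hotspot and/or curvilinear
#' elevated-temperature "vessel" tracks — the unilateral signs a metastatic
#' node produces on a thermogram. Defaults describe the study conditions
#' used throughout the package: a 128 x 128 field at 33 degC baseline with
#' 0.3 degC noise and a 2 degC hotspot for positives.
#'
#' @param height,width Field size in pixels (>= 16).
#' @param baseline_temp Baseline surface temperature, degC.
#' @param noise_sd Standard deviation of the additive Gaussian noise, degC.
#' @param smoothness Box-blur radius (px) applied to the noise field.
#' @param hotspot_amplitude Peak elevation of the hotspot, degC (>= 0).
#' @param hotspot_radius Hotspot scale (px); the Gaussian profile has
#'   standard deviation `hotspot_radius / 2`.
#' @param hotspot_side `"none"`, `"left"` or `"right"`: which side carries
#'   the unilateral perturbations. `"none"` disables them.
#' @param vessel_amplitude Elevation of vessel tracks, degC (>= 0).
#' @param vessel_count Number of vessel tracks.
#' @param mirrored_noise Mirror the noise field about the midline (default
#'   `TRUE`) so negatives are exactly symmetric up to the perturbations;
#'   `FALSE` draws independent noise per side, the harder realistic case.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A list of class `"phantom_params"`.
#' @export
phantom_params <- function(height = 128, width = 128, baseline_temp = 33.0,
                           noise_sd = 0.3, smoothness = 3,
                           hotspot_amplitude = 0, hotspot_radius = 16,
                           hotspot_side = c("none", "left", "right"),
                           vessel_amplitude = 0, vessel_count = 2,
                           mirrored_noise = TRUE, seed = 1L) {
  hotspot_side <- match.arg(hotspot_side)
  if (height < 16 || width < 16) stop_egsvm("phantom dimensions must be >= 16")
  if (noise_sd < 0) stop_egsvm("noise_sd must be >= 0")
  if (hotspot_amplitude < 0 || vessel_amplitude < 0)
    stop_egsvm("amplitudes must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 baseline_temp = baseline_temp, noise_sd = noise_sd,
                 smoothness = smoothness,
                 hotspot_amplitude = hotspot_amplitude,
                 hotspot_radius = hotspot_radius, hotspot_side = hotspot_side,
                 vessel_amplitude = vessel_amplitude,
                 vessel_count = as.integer(vessel_count),
                 mirrored_noise = mirrored_noise, seed = as.integer(seed)),
            class = "phantom_params")
}

phantom_label <- function(p) {
  if (p$hotspot_side != "none" &&
      (p$hotspot_amplitude > 0 || p$vessel_amplitude > 0)) 1L else -1L
}

# Column range of one side. A full-radius margin from both the edge and the
# midline keeps a hotspot's Gaussian tail (sigma = radius/2) at least 4
# sigma away from its mirror image, so the peak mirrored difference equals
# the hotspot amplitude to well under 0.1%.
side_columns <- function(p) {
  half <- floor(p$width / 2)
  margin <- max(2L, as.integer(round(p$hotspot_radius)))
  if (p$hotspot_side == "left") {
    c(min(margin, half), max(half - margin, min(margin, half)))
  } else {
    c(min(half + 1 + margin, p$width), max(p$width - margin, half + 1))
  }
}

#' Generate one synthetic thermogram phantom
#'
#' Builds the temperature field described by the parameters, converts it to
#' an 8-bit gray image with per-image min-max scaling (a constant field maps
#' to all-zero gray), and labels it `+1` when a unilateral perturbation is
#' present, `-1` otherwise. Deterministic given `params$seed`; the caller's
#' RNG state is left untouched.
#'
#' @param params A [phantom_params()].
#' @return A list of class `"phantom_sample"`: `temperature` (degC matrix),
#'   `gray` (integer matrix), `label` (`+1`/`-1`), `params`.
#' @examples
#' s <- generate_phantom(phantom_params(hotspot_amplitude = 2,
#'                                      hotspot_side = "left", seed = 42))
#' s$label
#' @export
generate_phantom <- function(params) {
  if (!inherits(params, "phantom_params"))
    stop_egsvm("params must be built with phantom_params()")
  p <- params
  field <- with_seed(p$seed, {
    f <- matrix(p$baseline_temp, p$height, p$width)
    if (p$noise_sd > 0) {
      noise <- matrix(stats::rnorm(p$height * p$width, 0, p$noise_sd),
                      p$height, p$width)
      if (p$mirrored_noise) {
        half <- floor(p$width / 2)
        if (half >= 1)
          noise[, (p$width - half + 1):p$width] <-
            noise[, half:1, drop = FALSE]
      }
      if (p$smoothness > 0) noise <- box_blur(noise, round(p$smoothness))
      f <- f + noise
    }
    if (p$hotspot_side != "none") {
      cols <- side_columns(p)
      if (p$hotspot_amplitude > 0) {
        cy <- sample(seq(ceiling(p$height * 0.25), floor(p$height * 0.75)), 1)
        cx <- sample(seq(cols[1], cols[2]), 1)
        sigma <- p$hotspot_radius / 2
        dy <- (seq_len(p$height) - cy)^2
        dx <- (seq_len(p$width) - cx)^2
        bump <- p$hotspot_amplitude *
          exp(-outer(dy, dx, "+") / (2 * sigma^2))
        f <- f + bump
      }
      if (p$vessel_amplitude > 0 && p$vessel_count > 0) {
        for (v in seq_len(p$vessel_count)) {
          x <- sample(seq(cols[1], cols[2]), 1)
          sigma_v <- 1.5
          for (y in seq_len(p$height)) {
            x <- clip(x + sample(-1:1, 1), cols[1], cols[2])
            dx2 <- (seq_len(p$width) - x)^2
            f[y, ] <- f[y, ] + p$vessel_amplitude * exp(-dx2 / (2 * sigma_v^2))
          }
        }
      }
    }
    clip(f, 15, 45)
  })
  gray <- if (max(field) > min(field)) {
    temperature_to_gray(field)
  } else {
    matrix(0L, p$height, p$width)
  }
  structure(list(temperature = field, gray = gray,
                 label = phantom_label(p), params = p),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %d x %d, label %+d, seed %d\n",
              nrow(x$temperature), ncol(x$temperature), x$label,
              x$params$seed))
  invisible(x)
}

#' Generate a labelled phantom dataset
#'
#' Draws `n_pos` metastasis-positive and `n_neg` negative phantoms. Each
#' sample gets its own seed, derived deterministically from the master seed,
#' so the whole dataset is bit-reproducible; positives have their perturbed
#' side chosen at random. When `dir` is given, every sample is written to
#' disk as both a temperature CSV and an 8-bit PNG together with a
#' `manifest.csv` (id, label, seed, side, paths).
#'
#' @param n_pos,n_neg Numbers of positive / negative samples
#'   (`n_pos + n_neg >= 2`).
#' @param base A [phantom_params()] supplying size, baseline, noise and
#'   perturbation amplitudes; its `hotspot_side` is overridden per sample
#'   (`"none"` for negatives, random side for positives). If `base` has
#'   `hotspot_amplitude = 0` and `vessel_amplitude = 0`, positives default
#'   to a 2 degC hotspot.
#' @param seed Master seed.
#' @param dir Optional output directory.
#' @return A tibble manifest: `id`, `label`, `seed`, `hotspot_side`, a
#'   `sample` list-column of `"phantom_sample"` objects, a `gray`
#'   list-column, and (when `dir` is given) `temp_path`, `png_path`.
#' @export
generate_dataset <- function(n_pos, n_neg, base = phantom_params(),
                             seed = 1L, dir = NULL) {
  if (n_pos < 0 || n_neg < 0 || n_pos + n_neg < 2)
    stop_egsvm("need at least two samples in total")
  n <- n_pos + n_neg
  pos_base <- base
  if (pos_base$hotspot_amplitude == 0 && pos_base$vessel_amplitude == 0)
    pos_base$hotspot_amplitude <- 2.0
  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    sides = sample(c("left", "right"), n, replace = TRUE)))
  rows <- purrr::map(seq_len(n), function(i) {
    positive <- i <= n_pos
    p <- if (positive) pos_base else base
    p$hotspot_side <- if (positive) draws$sides[i] else "none"
    if (!positive) {
      p$hotspot_amplitude <- 0
      p$vessel_amplitude <- 0
    }
    p$seed <- draws$seeds[i]
    s <- generate_phantom(p)
    tibble::tibble(id = sprintf("phantom_%03d", i), label = s$label,
                   seed = p$seed, hotspot_side = p$hotspot_side,
                   sample = list(s), gray = list(s$gray))
  })
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$temp_path <- file.path(dir, paste0(manifest$id, ".csv"))
    manifest$png_path <- file.path(dir, paste0(manifest$id, ".png"))
    purrr::walk(seq_len(n), function(i) {
      s <- manifest$sample[[i]]
      write_temperature_csv(s$temperature, manifest$temp_path[i])
      write_gray_png(s$gray, manifest$png_path[i])
    })
    utils::write.csv(
      manifest[c("id", "label", "seed", "hotspot_side",
                 "temp_path", "png_path")],
      file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  manifest
}

#' Left-right temperature asymmetry screen
#'
#' Automated form of the thermographic symmetry criterion: after 3 x 3 mean
#' smoothing, the field is compared pixel-wise with its mirror image about
#' the vertical midline, and the map is flagged when the maximum absolute
#' mirrored difference strictly exceeds the threshold (1 degC by default).
#' The smoothing is part of the screen's definition: it suppresses
#' single-pixel noise excursions.
#'
#' @param tmap Numeric temperature matrix (degC), width >= 2.
#' @param threshold Flag threshold in degC (strict `>`).
#' @return A one-row tibble: `flagged` (logical), `max_diff` (degC),
#'   `threshold`.
#' @export
asymmetry_screen <- function(tmap, threshold = 1.0) {
  validate_temperature_map(tmap, physiologic = FALSE)
  sm <- box_blur(tmap, 1)
  d <- abs(sm - sm[, rev(seq_len(ncol(sm))), drop = FALSE])
  max_diff <- max(d)
  tibble::tibble(flagged = max_diff > threshold, max_diff = max_diff,
                 threshold = threshold)
}
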