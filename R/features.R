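#' Centered expanding-window series
#'
#' Builds the nested sequence of `n` centered rectangular windows used by the
#' entropy-gradient features. Window `k` has height `round(k * height / n)`
#' and width `round(k * width / n)` (half-up, floored at 1 px), so the step
#' is `1/n` of each dimension and window `n` is exactly the full image.
#' When the leftover border is odd, the extra row/column goes to the
#' bottom/right.
#'
#' @param height,width Image dimensions in pixels.
#' @param n Number of windows (default 50).
#' @return A tibble with one row per window: `k`, `top`, `left`, `bottom`,
#'   `right` (0-based, half-open), `height`, `width`.
#' @examples
#' expanding_windows(500, 500, n = 50)
#' @export
expanding_windows <- function(height, width, n = 50) {
  if (n < 2 || n != floor(n)) stop_egsvm("window count n must be an integer >= 2")
  if (height < 2 || width < 2) stop_egsvm("image must be at least 2 x 2")
  k <- seq_len(n)
  h <- pmax(1L, as.integer(round_half_up(k * height / n)))
  w <- pmax(1L, as.integer(round_half_up(k * width / n)))
  top <- as.integer(floor((height - h) / 2))
  left <- as.integer(floor((width - w) / 2))
  tibble::tibble(k = as.integer(k), top = top, left = left,
                 bottom = top + h, right = left + w, height = h, width = w)
}

#' Window-max normalization of a sub-image
#'
#' Restricts the image to the window and rescales gray values by
#' `255 / max`, where the maximum is taken over the window, rounding half-up
#' (clipped to 255). The brightest pixel of every non-blank window therefore
#' maps to 255. An all-zero window is returned as zeros.
#'
#' @param img Integer gray-level matrix.
#' @param window An [roi()], length-4 `c(top, left, bottom, right)`, or a
#'   single row of [expanding_windows()].
#' @return Integer matrix of the normalized sub-image.
#' @export
normalize_window <- function(img, window) {
  sub <- crop_roi(img, window)
  normalize_submatrix(sub)
}

normalize_submatrix <- function(sub) {
  m <- max(sub)
  if (m == 0) return(sub)
  out <- clip(round_half_up(sub * (255 / m)), 0, 255)
  storage.mode(out) <- "integer"
  out
}

#' Global histogram equalization
#'
#' Standard cumulative-histogram remapping over the 256 gray levels:
#' `out(v) = round(255 * (cdf(v) - cdf_min) / (N - cdf_min))`, where `N` is
#' the pixel count and `cdf_min` the smallest nonzero cumulative count. The
#' level mapping is monotone non-decreasing; a constant image is returned
#' unchanged (all mass sits in one level, so the mapping is degenerate).
#'
#' @param img Integer gray-level matrix (any size, values 0-255).
#' @return Integer matrix of the equalized image, same shape.
#' @export
equalize_histogram <- function(img) {
  if (length(img) == 0) stop_egsvm("cannot equalize an empty image")
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  n <- length(img)
  cdf_min <- cdf[cdf > 0][1]
  if (n == cdf_min) return(img)  # constant image
  lut <- as.integer(round_half_up(255 * (cdf - cdf_min) / (n - cdf_min)))
  out <- matrix(lut[as.integer(img) + 1L], nrow(img), ncol(img))
  out
}

#' Shannon entropy of a gray image
#'
#' Entropy in bits of the gray-level histogram:
#' `h = -sum(p_i * log2(p_i))` over all 256 levels, with `0 * log 0 = 0`.
#' Lies in `[0, 8]` for 8-bit images.
#'
#' @param img Integer matrix with values 0-255.
#' @return Entropy in bits (scalar).
#' @examples
#' shannon_entropy(matrix(128L, 4, 4))              # 0
#' shannon_entropy(matrix(c(0L, 255L), 4, 4))       # 1 bit
#' @export
shannon_entropy <- function(img) {
  if (length(img) == 0) stop_egsvm("cannot compute entropy of an empty image")
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  p <- counts[counts > 0] / length(img)
  -sum(p * log2(p))
}

#' First differences of an entropy series
#'
#' @param h Numeric vector of entropies, length `n >= 2`.
#' @return Numeric vector of length `n - 1`: element `k` is `h[k+1] - h[k]`.
#' @export
entropy_gradient <- function(h) {
  if (length(h) < 2) stop_egsvm("entropy series must have length >= 2")
  diff(h)
}

#' Entropy-gradient feature vector of a gray image
#'
#' The full feature extraction: build the `n` centered expanding windows;
#' for each window compute the max-normalized sub-image and its
#' histogram-equalized counterpart; take the Shannon entropy of each,
#' giving two entropy series of length `n`; return the concatenated first
#' differences of both series. The result has length `2 * (n - 1)` (98 for
#' the default `n = 50`) and is independent of absolute image size, since
#' window sizes are relative.
#'
#' @param img Integer gray-level matrix, at least 2 x 2.
#' @param n Number of expanding windows (default 50).
#' @return Named numeric vector of length `2 * (n - 1)`; names `dH01..` for
#'   the normalized-image gradients, `dHh01..` for the equalized-image
#'   gradients.
#' @examples
#' img <- matrix(as.integer((0:99) %% 7) * 30L, 10, 10)
#' f <- extract_features(img, n = 10)
#' length(f)  # 2 * (10 - 1) = 18
#' @export
extract_features <- function(img, n = 50) {
  validate_gray_image(img)
  wins <- expanding_windows(nrow(img), ncol(img), n)
  h_norm <- numeric(n)
  h_hist <- numeric(n)
  for (k in seq_len(n)) {
    sub <- img[(wins$top[k] + 1):wins$bottom[k],
               (wins$left[k] + 1):wins$right[k], drop = FALSE]
    nm <- normalize_submatrix(sub)
    h_norm[k] <- shannon_entropy(nm)
    h_hist[k] <- shannon_entropy(equalize_histogram(nm))
  }
  fv <- c(diff(h_norm), diff(h_hist))
  names(fv) <- feature_names(n)
  fv
}

feature_names <- function(n = 50) {
  c(sprintf("dH%02d", seq_len(n - 1)), sprintf("dHh%02d", seq_len(n - 1)))
}

#' Extract features for a whole set of images
#'
#' Data-frame-first wrapper around [extract_features()]: takes a manifest
#' with one row per image and returns it with the feature columns bound on,
#' ready for [egsvm_train()] or [egsvm_cv()].
#'
#' @param manifest A data frame with either a `gray` list-column of
#'   gray-level matrices (as produced by [generate_dataset()]) or a `path`
#'   column of image files readable by [load_gray_image()]. A `label`
#'   column, if present, is carried through.
#' @param n Number of expanding windows (default 50).
#' @param region Optional [roi()] applied to every image before extraction.
#' @return A tibble: `id` and `label` columns from the manifest (when
#'   present) followed by the `2 * (n - 1)` feature columns.
#' @export
extract_feature_table <- function(manifest, n = 50, region = NULL) {
  if (!is.data.frame(manifest)) stop_egsvm("manifest must be a data frame")
  imgs <- if ("gray" %in% names(manifest)) {
    manifest$gray
  } else if ("path" %in% names(manifest)) {
    purrr::map(manifest$path, load_gray_image)
  } else {
    stop_egsvm("manifest needs a 'gray' list-column or a 'path' column")
  }
  if (!is.null(region)) imgs <- purrr::map(imgs, crop_roi, region = region)
  feats <- purrr::map(imgs, extract_features, n = n)
  fmat <- do.call(rbind, feats)
  out <- tibble::as_tibble(fmat)
  meta <- manifest[intersect(c("id", "label"), names(manifest))]
  dplyr::bind_cols(tibble::as_tibble(meta), out)
}
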