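#' Laplacian-of-Gaussian kernel
#'
#' Discrete LoG kernel of scale `sigma` on a `(2r+1)` square support with
#' `r = ceiling(4 sigma)`, sign-flipped so a bright Gaussian blob of
#' matching scale produces a positive response, and mean-subtracted so the
#' response to a constant image is exactly zero.
#'
#' @param sigma scale in pixels.
#' @return numeric matrix of odd dimensions.
#' @keywords internal
log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  ax <- (-r):r
  g <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  r2 <- outer(ax^2, ax^2, "+")
  k <- (1 - r2 / (2 * sigma^2)) * g / (pi * sigma^4)
  k - mean(k)
}

# shifted copies padded with -Inf; used for 8-neighbour maxima
shift_pad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(-Inf, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

neighbour_max_2d <- function(m) {
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- pmax(out, shift_pad(m, dr, dc))
  }
  out
}

#' Detect protein spots by scale-normalized LoG blob detection
#'
#' Computes the scale-normalized Laplacian-of-Gaussian response
#' (`sigma^2 * (LoG * I)`) of the polarity-corrected image over a geometric
#' ladder of `n_scales` scales between `sigma_min` and `sigma_max`, keeps
#' local maxima of the 3D scale-space response exceeding
#' `threshold_rel * max(response)`, and suppresses overlaps greedily by
#' descending response: a candidate within `sqrt(2) * sigma` of an already
#' accepted spot (the accepted spot's zero-crossing radius) is discarded.
#'
#' Each accepted spot's region is the disk of radius `sqrt(2) * sigma`
#' around its center, clipped to the image, and its raw intensity is the
#' sum of polarity-corrected pixels over that region.
#'
#' @param image a [gel_image()].
#' @param sigma_min,sigma_max detection scale range, pixels.
#' @param n_scales number of scales on the geometric ladder.
#' @param threshold_rel response threshold as a fraction of the global
#'   maximum response, in (0, 1).
#' @return A `spot_list`: data.frame with columns `spot_id`, `x`, `y`
#'   (0-based pixel centers), `sigma`, `response`, `raw_intensity`,
#'   `normalized_intensity` (`NA` until [normalize_intensities()]), ordered
#'   by descending response; attributes `gel_id` and `detection_params`.
#' @export
#' @examples
#' tr <- place_spots(3, c(64, 64), psf_sigma = 2, seed = 1)
#' img <- render_gel_image(tr, c(64, 64))
#' detect_spots(img, sigma_min = 1.5, sigma_max = 3, n_scales = 4)
detect_spots <- function(image, sigma_min = 2, sigma_max = 8, n_scales = 6,
                         threshold_rel = 0.1) {
  stopifnot(inherits(image, "gel_image"))
  if (!(sigma_min < sigma_max)) stop("sigma_min must be < sigma_max")
  if (threshold_rel <= 0 || threshold_rel >= 1)
    stop("threshold_rel must lie in (0, 1)")
  corr <- corrected_pixels(image)
  support <- 2L * ceiling(4 * sigma_max) + 1L
  if (any(dim(corr) < support))
    stop("image (", nrow(corr), " x ", ncol(corr),
         ") smaller than the largest filter support (", support, " px)")
  sigmas <- exp(seq(log(sigma_min), log(sigma_max), length.out = n_scales))
  resp <- lapply(sigmas, function(s)
    s^2 * EBImage::filter2(corr, log_kernel(s), boundary = "replicate"))
  gmax <- max(vapply(resp, max, numeric(1)))
  params <- list(sigma_min = sigma_min, sigma_max = sigma_max,
                 n_scales = n_scales, threshold_rel = threshold_rel)
  empty <- data.frame(spot_id = integer(0), x = numeric(0), y = numeric(0),
                      sigma = numeric(0), response = numeric(0),
                      raw_intensity = numeric(0),
                      normalized_intensity = numeric(0))
  if (gmax <= 0) return(new_spot_list(empty, image$sample_id, params))
  thr <- threshold_rel * gmax
  cand <- list()
  for (s in seq_along(sigmas)) {
    nb <- neighbour_max_2d(resp[[s]])
    if (s > 1L) nb <- pmax(nb, resp[[s - 1L]], neighbour_max_2d(resp[[s - 1L]]))
    if (s < n_scales) nb <- pmax(nb, resp[[s + 1L]], neighbour_max_2d(resp[[s + 1L]]))
    hit <- which(resp[[s]] >= nb & resp[[s]] >= thr, arr.ind = TRUE)
    if (nrow(hit) > 0)
      cand[[length(cand) + 1L]] <- data.frame(
        row = hit[, 1L], col = hit[, 2L], sigma = sigmas[s],
        response = resp[[s]][hit])
  }
  cand <- do.call(rbind, cand)
  # greedy non-maximum suppression, descending response (ties: scale, y, x)
  cand <- cand[order(-cand$response, cand$sigma, cand$row, cand$col), ]
  acc <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(acc) > 0) {
      d2 <- (cand$row[acc] - cand$row[i])^2 + (cand$col[acc] - cand$col[i])^2
      if (any(d2 <= 2 * cand$sigma[acc]^2)) next
    }
    acc <- c(acc, i)
  }
  kept <- cand[acc, , drop = FALSE]
  spots <- data.frame(
    spot_id = seq_len(nrow(kept)),
    x = kept$col - 1, y = kept$row - 1,
    sigma = kept$sigma, response = kept$response,
    raw_intensity = NA_real_, normalized_intensity = NA_real_)
  for (i in seq_len(nrow(spots))) {
    reg <- spot_region(spots$x[i], spots$y[i], spots$sigma[i], dim(corr))
    spots$raw_intensity[i] <- sum(corr[reg])
  }
  new_spot_list(spots, image$sample_id, params)
}

new_spot_list <- function(df, gel_id, params) {
  rownames(df) <- NULL
  structure(df, gel_id = gel_id, detection_params = params,
            class = c("spot_list", "data.frame"))
}

#' @export
print.spot_list <- function(x, ...) {
  cat(sprintf("spot_list '%s': %d spots\n", attr(x, "gel_id") %||% "", nrow(x)))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pixel region of a detected spot
#'
#' The disk of radius `sqrt(2) * sigma` (the LoG zero-crossing radius at
#' the detected scale) around a 0-based center, intersected with the image.
#'
#' @param x,y 0-based center coordinates.
#' @param sigma detection scale, pixels.
#' @param dim image dimensions `c(rows, cols)`.
#' @return two-column integer matrix of 1-based `(row, col)` pixel indices.
#' @export
spot_region <- function(x, y, sigma, dim) {
  r <- sqrt(2) * sigma
  rows <- max(1L, floor(y + 1 - r)):min(dim[1L], ceiling(y + 1 + r))
  cols <- max(1L, floor(x + 1 - r)):min(dim[2L], ceiling(x + 1 + r))
  grid <- expand.grid(row = rows, col = cols)
  keep <- ((grid$row - 1) - y)^2 + ((grid$col - 1) - x)^2 <= r^2
  as.matrix(grid[keep, , drop = FALSE])
}

#' Measure a spot's raw intensity
#'
#' The raw intensity of a spot is the sum of polarity-corrected pixel
#' values over its region, additive over disjoint regions.
#'
#' @param image a [gel_image()].
#' @param region two-column matrix of 1-based `(row, col)` pixel indices,
#'   e.g. from [spot_region()].
#' @return numeric scalar.
#' @export
measure_spot_intensity <- function(image, region) {
  stopifnot(inherits(image, "gel_image"))
  if (is.null(dim(region)) || nrow(region) == 0L) stop("empty spot region")
  if (any(region[, 1L] < 1L | region[, 1L] > nrow(image$pixels) |
          region[, 2L] < 1L | region[, 2L] > ncol(image$pixels)))
    stop("spot region outside image bounds")
  sum(corrected_pixels(image)[region])
}

#' Fill per-gel normalized intensities over the matched spot set
#'
#' Each matched spot's normalized intensity is its raw intensity divided by
#' the total raw intensity of all matched spots on the same gel; unmatched
#' spots keep `NA`. This is the per-gel normalisation that makes spot
#' intensities comparable across gels.
#'
#' @param spots a `spot_list` from [detect_spots()].
#' @param matched_ids spot ids over which to normalize (default: all).
#' @return the `spot_list` with `normalized_intensity` filled.
#' @export
normalize_intensities <- function(spots, matched_ids = spots$spot_id) {
  if (length(matched_ids) == 0L) stop("`matched_ids` must be nonempty")
  if (!all(matched_ids %in% spots$spot_id))
    stop("matched_ids absent from the spot list: ",
         paste(setdiff(matched_ids, spots$spot_id), collapse = ", "))
  idx <- spots$spot_id %in% matched_ids
  total <- sum(spots$raw_intensity[idx])
  if (!is.finite(total) || total <= 0)
    stop("total raw intensity over matched spots is not positive")
  spots$normalized_intensity <- NA_real_
  spots$normalized_intensity[idx] <- spots$raw_intensity[idx] / total
  spots
}
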