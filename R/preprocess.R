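# Pre-processing: multiplicative bias-field correction, inter-visit
# histogram matching, and resampling (see resample() in volume.R).

#' Estimate and remove a smooth multiplicative bias field
#'
#' Iterative smooth-field estimation in the log-intensity domain: the
#' low-frequency component of the current corrected log image (Gaussian
#' smoothing at `smoothness_mm`) is accumulated into the field estimate and
#' divided out, until the field update falls below `tol` or `max_iter`
#' passes. The returned field is strictly positive and scaled so that the
#' corrected image keeps the mask-mean intensity of the input (which also
#' pins the field's mask mean to 1 up to first order).
#'
#' @param vol a [volume_grid()]; intensities must be strictly positive on
#'   the mask.
#' @param smoothness_mm Gaussian smoothing scale of the field estimate (mm);
#'   should exceed the anatomical scale of interest.
#' @param mask optional estimation mask (default: whole volume).
#' @param tol convergence threshold on the max log-field update.
#' @param max_iter iteration cap.
#' @return A list with `corrected` (`vol / estimated_field`) and
#'   `estimated_field`, both [volume_grid()]s.
#' @export
correct_bias <- function(vol, smoothness_mm = 24, mask = NULL, tol = 1e-4,
                         max_iter = 20L) {
  stopifnot(is_volume_grid(vol))
  d <- dim(vol$values)
  m <- as_mask_array(mask, d)
  if (any(vol$values[m] <= 0))
    stop("correct_bias: nonpositive intensities inside the mask")
  vals <- pmax(vol$values, .Machine$double.eps)
  logI <- log(vals)
  logfield <- array(0, dim = d)
  for (it in seq_len(max_iter)) {
    resid <- logI - logfield
    upd <- gauss_smooth3(resid, smoothness_mm, vol$spacing)
    upd <- upd - mean(upd[m])
    delta <- max(abs(upd))
    logfield <- logfield + upd
    if (delta < tol) break
  }
  field <- exp(logfield)
  corrected <- vol$values / field
  # preserve the mask-mean intensity exactly
  scale <- mean(corrected[m]) / mean(vol$values[m])
  field <- field * scale
  corrected <- vol$values / field
  list(corrected = volume_grid(corrected, vol$spacing, vol$origin),
       estimated_field = volume_grid(field, vol$spacing, vol$origin))
}

#' Match the intensity histogram of one volume to a reference
#'
#' Monotone piecewise-linear quantile mapping: the `n_quantiles` empirical
#' quantiles of the moving volume (over the mask) are mapped onto the
#' matching quantiles of the reference, and all voxels are remapped through
#' linear interpolation between those knots. Rank order is preserved. A
#' constant moving image (degenerate quantile function) maps to the
#' reference median.
#'
#' @param moving,reference [volume_grid()]s.
#' @param n_quantiles number of quantile knots (>= 2).
#' @param mask optional mask over which quantiles are computed (default:
#'   whole volume); the remapping is applied everywhere.
#' @return The remapped moving volume.
#' @export
match_histogram <- function(moving, reference, n_quantiles = 256L,
                            mask = NULL) {
  stopifnot(is_volume_grid(moving), is_volume_grid(reference))
  if (n_quantiles < 2L) stop("n_quantiles must be >= 2")
  d <- dim(moving$values)
  m_mov <- as_mask_array(mask, d)
  m_ref <- if (is.null(mask)) array(TRUE, dim = dim(reference$values))
  else as_mask_array(mask, dim(reference$values))
  probs <- seq(0, 1, length.out = n_quantiles)
  qm <- stats::quantile(moving$values[m_mov], probs, names = FALSE, type = 7)
  qr <- stats::quantile(reference$values[m_ref], probs, names = FALSE, type = 7)
  if (max(qm) - min(qm) <= 0) {
    out <- array(stats::median(reference$values[m_ref]), dim = d)
    return(volume_grid(out, moving$spacing, moving$origin))
  }
  # collapse duplicate knots so approx() sees a strictly increasing x grid
  keep <- !duplicated(qm)
  qm_u <- qm[keep]
  qr_u <- vapply(qm_u, function(q) mean(qr[qm == q]), numeric(1))
  mapped <- stats::approx(qm_u, qr_u, xout = as.vector(moving$values),
                          rule = 2)$y
  volume_grid(array(mapped, dim = d), moving$spacing, moving$origin)
}
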