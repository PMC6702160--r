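# Per-tumour heterogeneity indices: fraction of increasing voxels for the
# Jacobian and the kinetic-feature response maps, histogram entropy for the
# anisotropy maps, and the assembly of the 7 + 5 feature vector.

#' Fraction of voxels whose value increased
#'
#' `count(value > threshold) / count(valid voxels)`, with strict inequality
#' (ties do not count as increased). The natural thresholds are 0 for
#' response maps (a positive value means the feature increased between
#' visits) and 1 for the Jacobian map (an increase means local expansion).
#'
#' @param map a [feature_map()].
#' @param threshold the "no change" value.
#' @return A scalar in `[0, 1]`; `NA` with a warning when the map has no
#'   valid voxels.
#' @export
fraction_increased <- function(map, threshold = 0) {
  stopifnot(inherits(map, "feature_map"))
  v <- map$values[map$valid]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    warning("fraction_increased: no valid voxels")
    return(NA_real_)
  }
  sum(v > threshold) / length(v)
}

#' Histogram entropy of a feature map
#'
#' Bins the valid voxel values into `n_bins` equal-width bins over the
#' per-tumour observed range and returns `sum(P * log2(P))` over occupied
#' bins. The default convention `"as_printed"` keeps the sign of that sum
#' (nonpositive, minimised by a uniform histogram, zero at a point mass);
#' `"shannon"` returns its negative, the conventional Shannon entropy.
#' A constant map occupies a single bin and scores 0 under both conventions.
#'
#' @param map a [feature_map()].
#' @param n_bins number of equal-width bins (>= 1).
#' @param convention `"as_printed"` or `"shannon"`.
#' @return A scalar; `NA` with a warning when no valid voxels exist.
#' @export
entropy_index <- function(map, n_bins = 32L,
                          convention = c("as_printed", "shannon")) {
  convention <- match.arg(convention)
  stopifnot(inherits(map, "feature_map"))
  if (n_bins < 1L) stop("n_bins must be >= 1")
  v <- map$values[map$valid]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    warning("entropy_index: no valid voxels")
    return(NA_real_)
  }
  rng <- range(v)
  if (rng[1] == rng[2]) return(0)
  # half-open equal-width bins; the top edge closed so max(v) lands in bin n
  b <- pmin.int(floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  p <- tabulate(b, nbins = n_bins) / length(v)
  p <- p[p > 0]
  h <- sum(p * log2(p))
  if (convention == "shannon") -h else h
}

#' Per-tumour summary: 7 voxel-wise indices + 5 aggregate features
#'
#' Collapses the eleven feature maps of one tumour to the seven voxel-wise
#' indices (fraction of expanding voxels for the Jacobian; fraction of
#' increasing voxels for each kinetic response map; histogram entropy of the
#' ADI and SRI maps) and carries the five aggregate features alongside.
#'
#' @param maps named list of [feature_map()]s; must contain `Jacobian`,
#'   `ADI`, `SRI`, `PRM_PE`, `PRM_WIS`, `PRM_WOS`, `PRM_SER`.
#' @param aggregates the five-value vector from [aggregate_features()].
#' @param ftv1_cm3,ftv2_cm3 segmented volumes (cm^3).
#' @param entropy_bins bins for [entropy_index()].
#' @param entropy_convention passed to [entropy_index()].
#' @param prm_deadband optional threshold `delta`: a response-map voxel
#'   counts as increased only when its value exceeds `delta` (default 0, no
#'   dead-band).
#' @return An object of class `tumor_summary`: `voxelwise` (named length-7
#'   numeric), `aggregate` (named length-5 numeric), `ftv1_cm3`, `ftv2_cm3`,
#'   `n_valid` (valid voxel count per map), and `flags`.
#' @export
summarize_tumor <- function(maps, aggregates, ftv1_cm3, ftv2_cm3,
                            entropy_bins = 32L,
                            entropy_convention = "as_printed",
                            prm_deadband = 0) {
  need <- c("Jacobian", "ADI", "SRI", "PRM_PE", "PRM_WIS", "PRM_WOS",
            "PRM_SER")
  missing_maps <- setdiff(need, names(maps))
  if (length(missing_maps))
    stop("missing feature map(s): ", paste(missing_maps, collapse = ", "))
  voxelwise <- c(
    frac_jacobian = fraction_increased(maps$Jacobian, threshold = 1),
    frac_PRM_PE   = fraction_increased(maps$PRM_PE, threshold = prm_deadband),
    frac_PRM_WIS  = fraction_increased(maps$PRM_WIS, threshold = prm_deadband),
    frac_PRM_WOS  = fraction_increased(maps$PRM_WOS, threshold = prm_deadband),
    frac_PRM_SER  = fraction_increased(maps$PRM_SER, threshold = prm_deadband),
    entropy_ADI   = entropy_index(maps$ADI, entropy_bins, entropy_convention),
    entropy_SRI   = entropy_index(maps$SRI, entropy_bins, entropy_convention))
  agg_names <- c("ftv_ratio", "d_PE", "d_WIS", "d_WOS", "d_SER")
  aggregate <- as.numeric(aggregates[agg_names])
  names(aggregate) <- agg_names
  structure(list(
    voxelwise = voxelwise,
    aggregate = aggregate,
    ftv1_cm3 = ftv1_cm3, ftv2_cm3 = ftv2_cm3,
    n_valid = vapply(maps[need], function(m) sum(m$valid), integer(1)),
    flags = attr(aggregates, "flags")),
    class = "tumor_summary")
}

#' @export
print.tumor_summary <- function(x, ...) {
  cat("<tumor_summary>\n  voxel-wise indices:\n")
  print(round(x$voxelwise, 4))
  cat("  aggregate features:\n")
  print(round(x$aggregate, 4))
  cat(sprintf("  FTV1 %.2f cm^3, FTV2 %.2f cm^3\n", x$ftv1_cm3, x$ftv2_cm3))
  invisible(x)
}
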