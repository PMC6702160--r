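# Three-timepoint kinetic features, SER-based functional tumour volume
# segmentation, Jacobian-scaled parametric response maps, and the aggregate
# longitudinal features.

# Kinetic features of three-timepoint curves, vectorised over voxels.
# I is a list of three numeric vectors (intensities at t0, t1, t2).
curve_kinetics <- function(I, times,
                           wis_condition = c("interpreted", "literal"),
                           wos_denominator = c("t2_minus_tpe", "t2_minus_t1"),
                           ser_eps = 1e-3) {
  wis_condition <- match.arg(wis_condition)
  wos_denominator <- match.arg(wos_denominator)
  I0 <- I[[1]]; I1 <- I[[2]]; I2 <- I[[3]]
  t0 <- times[1]; t1 <- times[2]; t2 <- times[3]
  n <- length(I0)
  bad_t0 <- !(I0 > 0)
  I0s <- ifelse(bad_t0, 1, I0)  # placeholder; flagged voxels zeroed below
  rel1 <- (I1 - I0s) / I0s
  rel2 <- (I2 - I0s) / I0s
  # peak over the two post-contrast frames; ties to the earlier time
  peak_at_t1 <- rel1 >= rel2
  PE <- pmax(rel1, rel2)
  t_peak <- ifelse(peak_at_t1, t1, t2)
  pos_peak <- PE > 0
  WIS <- if (wis_condition == "interpreted")
    ifelse(pos_peak, PE / (t_peak - t0), 0)
  else
    ifelse(t_peak != 0, PE / (t_peak - t0), 0)
  WOS <- if (wos_denominator == "t2_minus_tpe")
    ifelse(t2 != t_peak, (I2 - I1) / (t2 - t_peak), 0)
  else
    (I2 - I1) / (t2 - t1)
  denom <- I1 - I0s
  ser_guarded <- abs(denom) < ser_eps * abs(I0s)
  SER <- ifelse(ser_guarded, 0, (I2 - I0s) / ifelse(ser_guarded, 1, denom))
  for (v in c("PE", "WIS", "WOS", "SER")) {
    x <- get(v); x[bad_t0] <- 0; assign(v, x)
  }
  t_PE <- ifelse(pos_peak & !bad_t0, t_peak, NA_real_)
  list(PE = PE, WIS = WIS, WOS = WOS, SER = SER, t_PE = t_PE,
       flags = list(nonpositive_t0 = bad_t0,
                    no_enhancement = !pos_peak & !bad_t0,
                    ser_guarded = ser_guarded & !bad_t0))
}

#' Voxel-wise kinetic feature maps of one DCE visit
#'
#' Computes, per voxel of the mask, the four enhancement-curve features:
#' peak enhancement `PE = max_t (I(t) - I(t0)) / I(t0)` over the two
#' post-contrast frames, wash-in slope `WIS = PE / (t_PE - t0)` (zero when no
#' positive peak exists), wash-out slope `WOS = (I(t2) - I(t1)) / (t2 - t_PE)`
#' (zero when the peak is at t2), and signal enhancement ratio
#' `SER = (I(t2) - I(t0)) / (I(t1) - I(t0))` (guarded to zero when the first
#' post-contrast uptake is negligible). Slopes are per minute.
#'
#' @param study a [dce_study()].
#' @param mask optional support mask (array or [volume_grid()]).
#' @param wis_condition `"interpreted"` (default: a positive peak must exist)
#'   or `"literal"` (peak time nonzero).
#' @param wos_denominator `"t2_minus_tpe"` (default, as the index is defined)
#'   or `"t2_minus_t1"`.
#' @param ser_eps relative uptake threshold below which SER is guarded to 0.
#' @return An object of class `kinetic_set`: feature maps `PE`, `WIS`,
#'   `WOS`, `SER`, the per-voxel peak time `t_PE` (minutes; `NA` where no
#'   positive enhancement), and flag arrays.
#' @export
kinetic_maps <- function(study, mask = NULL,
                         wis_condition = c("interpreted", "literal"),
                         wos_denominator = c("t2_minus_tpe", "t2_minus_t1"),
                         ser_eps = 1e-3) {
  stopifnot(inherits(study, "dce_study"))
  d <- dim(study$vol_t0$values)
  m <- as_mask_array(mask, d)
  kk <- curve_kinetics(list(as.vector(study$vol_t0$values),
                            as.vector(study$vol_t1$values),
                            as.vector(study$vol_t2$values)),
                       study$times, wis_condition, wos_denominator, ser_eps)
  ok <- !kk$flags$nonpositive_t0
  valid <- array(ok, dim = d) & m
  mk <- function(nm) feature_map(nm, array(kk[[nm]], dim = d), m, valid,
                                 study$vol_t0$spacing, study$vol_t0$origin)
  structure(list(PE = mk("PE"), WIS = mk("WIS"), WOS = mk("WOS"),
                 SER = mk("SER"),
                 t_PE = array(kk$t_PE, dim = d),
                 flags = lapply(kk$flags, function(f) array(f, dim = d) & m),
                 times = study$times),
            class = "kinetic_set")
}

#' @export
print.kinetic_set <- function(x, ...) {
  cat(sprintf("<kinetic_set> %d mask voxels; times %s min\n",
              sum(x$PE$mask), paste(x$times, collapse = ", ")))
  invisible(x)
}

# 26-connected components of a logical 3D array; returns integer labels.
label_components_26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  labels <- integer(length(mask))
  if (length(idx) == 0L) return(array(labels, dim = d))
  nxy <- d[1] * d[2]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  in_set <- logical(length(mask)); in_set[idx] <- TRUE
  coord <- arrayInd(idx, d)
  coord_of <- matrix(0L, nrow = length(mask), ncol = 3L)
  coord_of[idx, ] <- coord
  cur <- 0L
  for (s in idx) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    queue <- s; labels[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      cv <- coord_of[v, ]
      for (o in seq_len(nrow(offs))) {
        nc <- cv + offs[o, ]
        if (any(nc < 1L) || any(nc > d)) next
        ni <- (nc[3] - 1L) * nxy + (nc[2] - 1L) * d[1] + nc[1]
        if (in_set[ni] && labels[ni] == 0L) {
          labels[ni] <- cur
          queue <- c(queue, ni)
        }
      }
    }
  }
  array(labels, dim = d)
}

#' Segment the functional tumour volume (FTV) of a visit
#'
#' Signal-enhancement-ratio style segmentation: voxels of the region of
#' interest whose peak enhancement reaches `pe_min` and whose SER lies in
#' `ser_range` are retained; optionally only the largest 26-connected
#' component is kept. Thresholds are configurable; the defaults
#' (`pe_min = 0.7`, unbounded positive SER) are working placeholders, not a
#' published operating point.
#'
#' @param study a [dce_study()].
#' @param roi_mask region of interest (array or [volume_grid()]); must be
#'   nonempty.
#' @param pe_min minimum peak enhancement (relative units).
#' @param ser_range length-2 numeric, inclusive SER interval.
#' @param keep_largest keep only the largest 26-connected component.
#' @return A binary [volume_grid()] with attributes `volume_cm3` (segmented
#'   volume) and `empty` (logical: segmentation found nothing; also raises a
#'   warning).
#' @export
segment_ftv <- function(study, roi_mask = NULL, pe_min = 0.7,
                        ser_range = c(0, Inf), keep_largest = TRUE) {
  stopifnot(inherits(study, "dce_study"))
  d <- dim(study$vol_t0$values)
  roi <- as_mask_array(roi_mask, d)
  if (!any(roi)) stop("roi_mask is empty")
  kin <- kinetic_maps(study, roi)
  sel <- roi & !is.na(kin$PE$values) & kin$PE$values >= pe_min &
    kin$SER$values >= ser_range[1] & kin$SER$values <= ser_range[2]
  sel[is.na(sel)] <- FALSE
  if (keep_largest && any(sel)) {
    lab <- label_components_26(sel)
    tab <- tabulate(lab[lab > 0])
    sel <- lab == which.max(tab)
  }
  empty <- !any(sel)
  if (empty)
    warning("FTV segmentation produced an empty mask")
  out <- volume_grid(array(as.numeric(sel), dim = d),
                     study$vol_t0$spacing, study$vol_t0$origin)
  attr(out, "volume_cm3") <- sum(sel) * prod(study$vol_t0$spacing) / 1000
  attr(out, "empty") <- empty
  out
}

#' Parametric response map (PRM) of a kinetic feature
#'
#' `PRM(x) = J(x) * F_early(T(x)) - F_pre(x)` on the pre-treatment tumour
#' support: the early-visit feature is sampled at the registered position
#' `T(x)` by trilinear interpolation and scaled by the local volume ratio
#' `J`, so that a voxel mapping to a larger or smaller volume contributes
#' proportionally. Voxels mapped outside the early image are flagged invalid
#' and excluded from downstream summaries.
#'
#' @param F_pre [feature_map()] on the pre-treatment grid (support = FTV1).
#' @param F_early [feature_map()] on the early-treatment grid.
#' @param T a [displacement_field()] on the pre-treatment grid.
#' @param J the Jacobian [feature_map()] (same grid as `F_pre`).
#' @return A [feature_map()] named `PRM_<feature>`.
#' @export
prm_map <- function(F_pre, F_early, T, J) {
  stopifnot(inherits(F_pre, "feature_map"), inherits(F_early, "feature_map"),
            inherits(T, "displacement_field"), inherits(J, "feature_map"))
  d <- dim(F_pre$values)
  geom <- volume_grid(array(0, dim = d), T$spacing, T$origin)
  pts <- apply_transform(T, grid_world_coords(geom))
  early_geom <- list(spacing = F_early$spacing, origin = F_early$origin)
  ev <- F_early$values
  ev[is.na(ev)] <- 0  # outside early support; sampled values there are invalid anyway
  smp <- interp3(ev, world_to_index(pts, early_geom), "linear")
  prm <- J$values * array(smp$values, dim = d) - F_pre$values
  valid <- F_pre$valid & J$valid & array(smp$inside, dim = d)
  feature_map(paste0("PRM_", F_pre$name), prm, F_pre$mask, valid,
              F_pre$spacing, F_pre$origin)
}

#' Aggregate longitudinal features
#'
#' The tumour-wide analogues of the voxel-wise maps: the volume ratio
#' `FTV2/FTV1`, and for each kinetic feature `f` the relative change
#' `Delta_f = (f_early - f_pre) / f_early`, where each visit's mean is taken
#' over its own functional tumour volume.
#'
#' @param kin_pre [kinetic_maps()] of the pre-treatment visit over FTV1.
#' @param kin_early [kinetic_maps()] of the early-treatment visit over FTV2.
#' @param ftv1_cm3,ftv2_cm3 segmented volumes in cm^3 (`ftv1_cm3 > 0`).
#' @param eps threshold on `|f_early|` below which `Delta_f` is undefined.
#' @return A named numeric vector of exactly five values (`ftv_ratio`,
#'   `d_PE`, `d_WIS`, `d_WOS`, `d_SER`), with attribute `"flags"` naming any
#'   undefined entries (returned as `NA`).
#' @export
aggregate_features <- function(kin_pre, kin_early, ftv1_cm3, ftv2_cm3,
                               eps = 1e-8) {
  stopifnot(inherits(kin_pre, "kinetic_set"), inherits(kin_early, "kinetic_set"))
  if (!(ftv1_cm3 > 0)) stop("ftv1_cm3 must be > 0")
  flags <- character(0)
  out <- c(ftv_ratio = ftv2_cm3 / ftv1_cm3)
  if (ftv2_cm3 <= 0) flags <- c(flags, "empty_ftv2")
  for (f in c("PE", "WIS", "WOS", "SER")) {
    nm <- paste0("d_", f)
    if (ftv2_cm3 <= 0 || !any(kin_early[[f]]$valid)) {
      out[nm] <- NA_real_; flags <- c(flags, nm); next
    }
    m_pre <- mean(kin_pre[[f]]$values[kin_pre[[f]]$valid])
    m_early <- mean(kin_early[[f]]$values[kin_early[[f]]$valid])
    if (abs(m_early) < eps) {
      out[nm] <- NA_real_; flags <- c(flags, nm)
    } else {
      out[nm] <- (m_early - m_pre) / m_early
    }
  }
  attr(out, "flags") <- flags
  out
}
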