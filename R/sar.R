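# Pointwise, region-averaged and 10 g mass-averaged SAR, plus the
# normalization bookkeeping and the position-shift experiment.

#' Pointwise SAR from an exposure field
#'
#' SAR(v) = sigma(v) |E(v)|^2 / rho(v), with |E| an RMS magnitude (so no
#' factor 1/2).  Air and blanket voxels get SAR 0.
#'
#' @param field An \linkS4class{ExposureField}.
#' @param model A \linkS4class{VoxelModel}.
#' @param table A \linkS4class{TissueTable}.
#' @param frequency MHz for the conductivity lookup.
#' @return 3-D SAR array (W/kg).
#' @export
pointwiseSAR <- function(field, model, table, frequency = 297) {
  if (!identical(dim(field@Emag), dim(model@labels)))
    stop("field and model grids differ")
  sigma <- conductivityGrid(model, table, frequency)
  rho <- densityGrid(model)
  tissue <- model@masks$whole_body
  if (any(tissue & rho <= 0))
    stop("zero density in a tissue voxel")
  sar <- array(0, dim(rho))
  sar[tissue] <- sigma[tissue] * field@Emag[tissue]^2 / rho[tissue]
  sar
}

#' Mass-weighted region-average SAR
#'
#' @param sar SAR grid (W/kg).
#' @param model A \linkS4class{VoxelModel}.
#' @param mask logical mask over which to average.
#' @return Mass-weighted mean SAR (W/kg).
#' @export
regionAverageSAR <- function(sar, model, mask) {
  if (!any(mask)) stop("empty mask")
  rho <- densityGrid(model)
  sum(sar[mask] * rho[mask]) / sum(rho[mask])
}

#' 10 g mass-averaged SAR by centred cube growth
#'
#' For each tissue voxel a cube centred on the voxel is grown until the
#' enclosed tissue mass reaches the target (10 g by default); the outermost
#' shell is fractionally weighted so the enclosed mass equals the target
#' exactly (an IEC 62704-1-style simplification).  Air voxels inside the
#' cube contribute zero mass and zero SAR.  The cube may only contain
#' grid-interior content: voxels whose cube would have to leave the grid
#' before reaching the target mass are marked invalid and excluded from the
#' peak.  Ties for the peak break to the lowest linear (column-major) index.
#'
#' @param sar SAR grid (W/kg).
#' @param model A \linkS4class{VoxelModel}.
#' @param targetMass averaging mass in kg (default 0.010).
#' @return list(sar10g, validMask, psSAR10g, location).
#' @export
massAveragedSAR <- function(sar, model, targetMass = 0.010) {
  rho <- densityGrid(model)
  tissue <- model@masks$whole_body
  massGrid <- rho * voxelVolume(model)
  massGrid[!tissue] <- 0
  if (sum(massGrid) < targetMass)
    stop(sprintf("total tissue mass %.4g kg below averaging mass %.4g kg",
                 sum(massGrid), targetMass))
  res <- cpp_sar10g(sar, massGrid, as.integer(tissue), dim(sar), targetMass)
  d <- dim(sar)
  sar10g <- array(res$sar10g, d)
  valid <- array(res$valid > 0, d)
  sar10g[!valid] <- NA_real_
  loc <- if (res$peak_index > 0) linearIndexToXYZ(res$peak_index, d)
         else c(NA_integer_, NA_integer_, NA_integer_)
  list(sar10g = sar10g, validMask = valid,
       psSAR10g = res$peak, location = loc)
}

#' Full SAR evaluation of a field on a model
#'
#' Computes the pointwise SAR grid, head and whole-body mass-weighted
#' averages, the 10 g peak (with location and validity mask) and the mean
#' |B1+| over tissue voxels in the central axial slice, packaged as a
#' \linkS4class{SARResult} carrying the power budget for later
#' normalization.
#'
#' @inheritParams pointwiseSAR
#' @param headMask mask for the head average; defaults to the model's
#'   \code{head} mask.
#' @param targetMass averaging mass (kg).
#' @param slice z index of the normalization slice; defaults to the field's
#'   central slice.
#' @return A \linkS4class{SARResult}.
#' @export
computeSAR <- function(field, model, table, frequency = 297,
                       headMask = NULL, targetMass = 0.010, slice = NULL) {
  sar <- pointwiseSAR(field, model, table, frequency)
  if (is.null(headMask)) headMask <- model@masks$head
  if (is.null(headMask)) stop("no head mask available")
  wb <- model@masks$whole_body
  ps <- massAveragedSAR(sar, model, targetMass)
  if (is.null(slice)) slice <- field@centralSlice
  b1slice <- meanB1Slice(field, model, slice)
  new("SARResult", sar = sar, sar10g = ps$sar10g, validMask = ps$validMask,
      headAvg = regionAverageSAR(sar, model, headMask),
      wholeBodyAvg = regionAverageSAR(sar, model, wb),
      psSAR10g = ps$psSAR10g, psLocation = ps$location,
      meanB1Slice = b1slice, budget = field@budget, Pin = field@Pin,
      meta = list(slice = slice))
}

#' Mean |B1+| over tissue voxels in an axial slice
#'
#' Air carries no meaningful exposure, so the average is over tissue voxels
#' only.
#'
#' @param field An \linkS4class{ExposureField}.
#' @param model A \linkS4class{VoxelModel}.
#' @param slice z index.
#' @return Mean |B1+| in uT.
#' @export
meanB1Slice <- function(field, model, slice = NULL) {
  if (is.null(slice)) slice <- field@centralSlice
  d <- dim(model@labels)
  if (slice < 1 || slice > d[3]) stop("slice index out of range")
  tis <- model@masks$whole_body[, , slice]
  if (!any(tis)) stop("no tissue voxels in slice ", slice)
  mean(Mod(field@B1[, , slice][tis]))
}

#' Normalize SAR summaries
#'
#' Divides the head-average, whole-body-average and 10 g peak by the chosen
#' denominator: total input power (\code{input_power}, W/kg/W), net forward
#' power forward - reflected (\code{net_forward}), absorbed power
#' (\code{absorbed}), or the squared mean slice |B1+|
#' (\code{b1_slice}, W/kg/uT^2).  Per-B1+^2 values are invariant to the
#' drive power.
#'
#' @param sarres A \linkS4class{SARResult}.
#' @param mode normalization mode.
#' @return Named numeric vector (head_avg, whole_body_avg, psSAR10g) plus a
#'   \code{denominator} attribute.
#' @export
normalizeSAR <- function(sarres, mode = c("input_power", "net_forward",
                                          "absorbed", "b1_slice")) {
  mode <- match.arg(mode)
  b <- sarres@budget
  den <- switch(mode,
    input_power = sarres@Pin,
    net_forward = b[["forward"]] - b[["reflected"]],
    absorbed = b[["absorbed"]],
    b1_slice = sarres@meanB1Slice^2)
  if (!is.finite(den) || den <= 0)
    stop("cannot normalize: ", mode, " denominator is ", den)
  out <- c(head_avg = sarres@headAvg, whole_body_avg = sarres@wholeBodyAvg,
           psSAR10g = sarres@psSAR10g) / den
  attr(out, "denominator") <- unname(den)
  attr(out, "mode") <- mode
  out
}

#' Position-shift experiment
#'
#' Shifts the model within the fixed coil-frame field, recomputes the SAR
#' summaries for every shift, and normalizes to mean |B1+|^2 within the
#' translated anatomical slice (the slice shifts with the model, emulating
#' imaging of the same anatomy at a different position).  Rows where the
#' shift clips more than 20 percent of tissue voxels are flagged.
#'
#' @param model A \linkS4class{VoxelModel}.
#' @param field An \linkS4class{ExposureField} in the fixed coil frame.
#' @param shifts numeric matrix (n x 3) of shifts in mm.
#' @param table A \linkS4class{TissueTable}.
#' @param file optional CSV output path.
#' @return data.frame with one row per shift.
#' @export
shiftExperiment <- function(model, field, shifts, table, file = NULL) {
  shifts <- matrix(as.numeric(shifts), ncol = 3)
  n0 <- sum(model@labels > 0L)
  rows <- lapply(seq_len(nrow(shifts)), function(i) {
    sh <- shifts[i, ]
    shifted <- withCallingHandlers(shiftModel(model, sh),
                                   warning = function(w) invokeRestart("muffleWarning"))
    clipped <- 1 - sum(shifted@labels > 0L) / n0
    if (clipped > 0.2)
      warning(sprintf("shift (%g, %g, %g) mm clips %.0f%% of tissue voxels",
                      sh[1], sh[2], sh[3], 100 * clipped))
    res <- computeSAR(field, shifted, table, slice = shifted@refSlice)
    nb <- normalizeSAR(res, "b1_slice")
    data.frame(shift_x_mm = sh[1], shift_y_mm = sh[2], shift_z_mm = sh[3],
               slice = shifted@refSlice,
               head_avg_perB1sq = nb[["head_avg"]],
               whole_body_perB1sq = nb[["whole_body_avg"]],
               psSAR10g_perB1sq = nb[["psSAR10g"]],
               mean_B1_slice_uT = res@meanB1Slice,
               clipped_frac = clipped, flagged = clipped > 0.2)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
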