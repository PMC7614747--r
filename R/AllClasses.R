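#' @import methods
#' @importFrom stats approx runif setNames
#' @importFrom utils read.csv write.csv modifyList
#' @useDynLib neodose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Coordinate convention used throughout the package: arrays are indexed
# [x, y, z] with 1-based voxel indices; axis order is x = left-right,
# y = posterior-anterior, z = inferior-superior.  The world coordinate of
# voxel centre (i, j, k) is ((i, j, k) - 0.5) * voxelSize(model), in mm,
# measured from the grid corner.

#' TissueTable: per-tissue dielectric and thermal properties
#'
#' Holds one row per tissue with relative permittivity \code{eps_r} and
#' conductivity \code{sigma_S_per_m} at a stated frequency, density
#' \code{rho_kg_m3}, thermal conductivity \code{k_W_m_K}, specific heat
#' \code{c_J_kg_K}, perfusion \code{perfusion_ml_min_kg} (mL blood per minute
#' per kg tissue) and metabolic rate \code{qmet_W_kg}, plus a provenance
#' string per entry.
#'
#' @slot props data.frame with the columns listed above plus \code{tissue},
#'   \code{freq_MHz} and \code{source}.
#' @export
setClass("TissueTable", representation(props = "data.frame"))

.tissue_cols <- c("tissue", "freq_MHz", "eps_r", "sigma_S_per_m", "rho_kg_m3",
                  "k_W_m_K", "c_J_kg_K", "perfusion_ml_min_kg", "qmet_W_kg",
                  "source")

setValidity("TissueTable", function(object) {
  p <- object@props
  miss <- setdiff(.tissue_cols, names(p))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(p$tissue)) return("duplicate tissue names")
  num <- c("freq_MHz", "eps_r", "sigma_S_per_m", "rho_kg_m3", "k_W_m_K",
           "c_J_kg_K", "perfusion_ml_min_kg", "qmet_W_kg")
  for (cn in num) {
    v <- p[[cn]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      return(paste("column", cn, "must be finite and >= 0"))
  }
  if (any(p$eps_r < 1)) return("eps_r must be >= 1 for all materials")
  TRUE
})

#' ScalingTable: newborn/adult dielectric property ratios
#'
#' Multiplicative ratios applied to adult permittivity and conductivity to
#' obtain age-adjusted neonatal values, at a stated frequency.
#'
#' @slot ratios data.frame with columns \code{tissue}, \code{freq_MHz},
#'   \code{ratio_eps}, \code{ratio_sigma}, \code{source}.
#' @export
setClass("ScalingTable", representation(ratios = "data.frame"))

setValidity("ScalingTable", function(object) {
  r <- object@ratios
  need <- c("tissue", "freq_MHz", "ratio_eps", "ratio_sigma")
  miss <- setdiff(need, names(r))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (any(!is.finite(r$ratio_eps)) || any(r$ratio_eps <= 0) ||
      any(!is.finite(r$ratio_sigma)) || any(r$ratio_sigma <= 0))
    return("ratios must be finite and > 0")
  TRUE
})

#' VoxelModel: labelled 3-D tissue grid
#'
#' @slot labels integer 3-D array, 0 = air, other values index tissues via
#'   \code{tissueNames}.
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @slot tissueNames named character vector mapping label id (as character)
#'   to tissue name.
#' @slot density named numeric vector mapping label id to density (kg/m3).
#' @slot masks named list of logical arrays (head, core, skin, blanket,
#'   whole_body, ...), all with the shape of \code{labels}.
#' @slot refSlice integer, z index of the anatomical reference axial slice
#'   (translated when the model is shifted).
#' @slot meta list of free-form metadata (generation spec, shift residuals).
#' @export
setClass("VoxelModel",
         representation(labels = "array", voxelSize = "numeric",
                        tissueNames = "character", density = "numeric",
                        masks = "list", refSlice = "integer", meta = "list"))

setValidity("VoxelModel", function(object) {
  lab <- object@labels
  if (length(dim(lab)) != 3L) return("labels must be a 3-D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values (mm)")
  used <- setdiff(unique(as.integer(lab)), 0L)
  miss <- setdiff(as.character(used), names(object@tissueNames))
  if (length(miss))
    return(paste("labels with no tissueNames entry:", paste(miss, collapse = ", ")))
  miss <- setdiff(as.character(used), names(object@density))
  if (length(miss))
    return(paste("labels with no density entry:", paste(miss, collapse = ", ")))
  for (nm in names(object@masks)) {
    m <- object@masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), dim(lab)))
      return(paste("mask", nm, "must be a logical array with the shape of labels"))
  }
  if (!is.null(object@masks$whole_body) && !is.null(object@masks$blanket)) {
    if (any(object@masks$whole_body & object@masks$blanket))
      return("blanket mask must be disjoint from whole_body")
  }
  if (length(used)) {
    tm <- totalMass(object)
    if (!is.finite(tm) || tm <= 0) return("total tissue mass must be finite and > 0")
  }
  TRUE
})

#' ExposureField: RF exposure on a voxel grid
#'
#' @slot Emag 3-D array, RMS electric field magnitude (V/m).  The RMS
#'   convention means pointwise SAR is sigma |E|^2 / rho with no factor 1/2.
#' @slot B1 3-D complex array, transmit field B1+ (microtesla).
#' @slot budget named numeric: forward, reflected, radiated, absorbed (W);
#'   must close to within 1 percent of forward.
#' @slot Pin numeric, reference input power (W), equal to forward power.
#' @slot centralSlice integer, z index of the central axial slice used for
#'   B1+ normalization.
#' @slot meta list.
#' @export
setClass("ExposureField",
         representation(Emag = "array", B1 = "array", budget = "numeric",
                        Pin = "numeric", centralSlice = "integer",
                        meta = "list"))

setValidity("ExposureField", function(object) {
  if (length(dim(object@Emag)) != 3L) return("Emag must be a 3-D array")
  if (!identical(dim(object@Emag), dim(object@B1)))
    return("Emag and B1 must share a grid")
  need <- c("forward", "reflected", "radiated", "absorbed")
  miss <- setdiff(need, names(object@budget))
  if (length(miss)) return(paste("budget terms missing:", paste(miss, collapse = ", ")))
  b <- object@budget
  if (any(b < 0)) return("budget terms must be >= 0")
  gap <- abs(b[["forward"]] - (b[["reflected"]] + b[["radiated"]] + b[["absorbed"]]))
  if (b[["forward"]] > 0 && gap > 0.01 * b[["forward"]])
    return(sprintf("power budget does not close: forward %.4g vs components %.4g",
                   b[["forward"]], b[["reflected"]] + b[["radiated"]] + b[["absorbed"]]))
  if (any(object@Emag < 0)) return("Emag must be >= 0 (RMS magnitude)")
  TRUE
})

#' SARResult: pointwise and summarized specific absorption rate
#'
#' @slot sar 3-D array, pointwise SAR (W/kg) at the drive power \code{Pin}.
#' @slot sar10g 3-D array, 10 g cube-averaged SAR; NA where the averaging
#'   cube cannot reach the target mass inside the grid.
#' @slot validMask logical array marking voxels with a valid 10 g average.
#' @slot headAvg,wholeBodyAvg,psSAR10g numeric summaries (W/kg).
#' @slot psLocation integer length-3 voxel index of the 10 g peak.
#' @slot meanB1Slice numeric, mean |B1+| (microtesla) over tissue voxels in
#'   the central axial slice at the same drive.
#' @slot budget,Pin power bookkeeping copied from the field.
#' @slot meta list.
#' @export
setClass("SARResult",
         representation(sar = "array", sar10g = "array", validMask = "array",
                        headAvg = "numeric", wholeBodyAvg = "numeric",
                        psSAR10g = "numeric", psLocation = "integer",
                        meanB1Slice = "numeric", budget = "numeric",
                        Pin = "numeric", meta = "list"))

setValidity("SARResult", function(object) {
  if (any(object@sar < 0, na.rm = TRUE)) return("SAR must be >= 0")
  vals <- c(object@headAvg, object@wholeBodyAvg, object@psSAR10g)
  if (any(!is.finite(vals)) || any(vals < 0)) return("summary SAR must be finite and >= 0")
  # averaging over a superset cannot exceed the peak 10 g average
  if (object@headAvg > object@psSAR10g * (1 + 1e-9))
    return("headAvg exceeds psSAR10g, which is impossible for a mass average")
  TRUE
})

#' ThermalState: temperature field plus blood-pool state
#'
#' @slot Tgrid 3-D numeric array, temperature (degrees C) on tissue and
#'   blanket voxels; NA on air voxels (ambient acts only through the
#'   convective boundary condition).
#' @slot Tblood numeric, lumped blood-pool temperature (degrees C).
#' @slot time numeric, simulated time (s).
#' @export
setClass("ThermalState",
         representation(Tgrid = "array", Tblood = "numeric", time = "numeric"))

setValidity("ThermalState", function(object) {
  if (length(dim(object@Tgrid)) != 3L) return("Tgrid must be a 3-D array")
  v <- object@Tgrid[!is.na(object@Tgrid)]
  if (length(v) && any(!is.finite(v))) return("temperatures must be finite")
  if (!is.finite(object@Tblood)) return("Tblood must be finite")
  TRUE
})

#' ThermalConfig: bioheat solver configuration
#'
#' @slot h surface heat-transfer coefficient (W m-2 K-1).
#' @slot Tambient ambient temperature (degrees C).
#' @slot dt time step (s); NA means automatic (stability-bound) choice.
#' @slot duration simulated duration (s).
#' @slot variableCore logical, evolve the blood-pool temperature.
#' @slot tempDependentPerfusion logical, enable the perfusion ramp (adult
#'   mode only; neonatal runs keep temperature-independent perfusion).
#' @slot bloodVolume blood-pool volume (mL); 324 mL for a term neonate.
#' @slot rhoBlood,cBlood blood density (kg/m3) and specific heat (J/kg/K).
#' @slot recordEvery cadence of time-series records (s).
#' @export
setClass("ThermalConfig",
         representation(h = "numeric", Tambient = "numeric", dt = "numeric",
                        duration = "numeric", variableCore = "logical",
                        tempDependentPerfusion = "logical",
                        bloodVolume = "numeric", rhoBlood = "numeric",
                        cBlood = "numeric", recordEvery = "numeric"))

setValidity("ThermalConfig", function(object) {
  if (object@h < 0) return("h must be >= 0")
  if (object@duration < 0) return("duration must be >= 0")
  if (!is.na(object@dt) && object@dt <= 0) return("dt must be > 0 or NA (auto)")
  if (object@variableCore && object@bloodVolume <= 0)
    return("bloodVolume must be > 0 when variableCore is on")
  if (object@rhoBlood <= 0 || object@cBlood <= 0)
    return("blood density and specific heat must be > 0")
  TRUE
})

#' PhantomSpec: parametric synthetic phantom description
#'
#' @slot targetMass target body mass (kg); NA disables mass calibration.
#' @slot gridDim integer length-3 grid shape.
#' @slot voxelSize numeric length-3 voxel size (mm).
#' @slot parts named list of geometric parts (see \code{\link{generatePhantom}}).
#' @slot headTargetVolume head-region target volume (mL); NA disables check.
#' @slot calibrate logical, scale torso/limb cross-sections to hit targetMass.
#' @slot seed integer random seed; fixes the phantom bit-exactly.
#' @slot jitter relative geometric jitter applied per seed (0 disables).
#' @export
setClass("PhantomSpec",
         representation(targetMass = "numeric", gridDim = "integer",
                        voxelSize = "numeric", parts = "list",
                        headTargetVolume = "numeric", calibrate = "logical",
                        seed = "integer", jitter = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridDim) != 3L || any(object@gridDim < 1))
    return("gridDim must be 3 positive integers")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be > 0")
  if (!is.na(object@targetMass) && object@targetMass <= 0)
    return("targetMass must be > 0")
  if (!length(object@parts)) return("spec must contain at least one part")
  TRUE
})

#' LimitSet: exposure and temperature limits
#'
#' Defaults follow the operative IEC-style values used for head-coil
#' exposure: head-average SAR 3.2 W/kg, psSAR10g 10 W/kg, whole-body SAR
#' 4 W/kg, core-temperature rise 0.5 degrees C, absolute local temperature
#' 39 degrees C.
#'
#' @slot headAvg,psSAR10g,wholeBody SAR limits (W/kg).
#' @slot coreRise allowed core-temperature rise (degrees C).
#' @slot absoluteT absolute local temperature limit (degrees C).
#' @export
setClass("LimitSet",
         representation(headAvg = "numeric", psSAR10g = "numeric",
                        wholeBody = "numeric", coreRise = "numeric",
                        absoluteT = "numeric"))

setValidity("LimitSet", function(object) {
  v <- c(object@headAvg, object@psSAR10g, object@wholeBody,
         object@coreRise, object@absoluteT)
  if (any(v <= 0)) return("all limits must be > 0")
  TRUE
})

setMethod("show", "VoxelModel", function(object) {
  d <- dim(object@labels)
  cat(sprintf("VoxelModel: %d x %d x %d voxels at %s mm\n", d[1], d[2], d[3],
              paste(format(object@voxelSize), collapse = " x ")))
  cat(sprintf("  tissues: %s\n", paste(object@tissueNames, collapse = ", ")))
  cat(sprintf("  masks: %s\n", paste(names(object@masks), collapse = ", ")))
  cat(sprintf("  total mass: %.3f kg\n", totalMass(object)))
})

setMethod("show", "TissueTable", function(object) {
  cat(sprintf("TissueTable: %d tissues at %s MHz\n", nrow(object@props),
              paste(unique(object@props$freq_MHz), collapse = "/")))
})

setMethod("show", "ExposureField", function(object) {
  b <- object@budget
  cat(sprintf("ExposureField: %s grid, Pin = %.3g W (refl %.3g, rad %.3g, abs %.3g)\n",
              paste(dim(object@Emag), collapse = "x"), object@Pin,
              b[["reflected"]], b[["radiated"]], b[["absorbed"]]))
})

setMethod("show", "SARResult", function(object) {
  cat(sprintf("SARResult at Pin = %.3g W\n", object@Pin))
  cat(sprintf("  head avg %.4g  whole-body avg %.4g  psSAR10g %.4g W/kg\n",
              object@headAvg, object@wholeBodyAvg, object@psSAR10g))
  cat(sprintf("  mean slice |B1+| = %.4g uT\n", object@meanB1Slice))
})

setMethod("show", "ThermalState", function(object) {
  v <- object@Tgrid[!is.na(object@Tgrid)]
  cat(sprintf("ThermalState at t = %.0f s: T in [%.2f, %.2f] C, Tblood = %.3f C\n",
              object@time, min(v), max(v), object@Tblood))
})
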