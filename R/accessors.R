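#' Accessors for VoxelModel and friends
#'
#' Small accessor functions are preferred over direct slot access.
#'
#' @param model A \linkS4class{VoxelModel}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
voxelLabels <- function(model) model@labels

#' @rdname accessors
#' @export
voxelSize <- function(model) model@voxelSize

#' Voxel volume in cubic metres
#' @rdname accessors
#' @export
voxelVolume <- function(model) prod(model@voxelSize) * 1e-9

#' @rdname accessors
#' @export
tissueNames <- function(model) model@tissueNames

#' @rdname accessors
#' @export
tissueDensity <- function(model) model@density

#' @param name Mask name; NULL returns the whole list.
#' @rdname accessors
#' @export
modelMask <- function(model, name = NULL) {
  if (is.null(name)) return(model@masks)
  m <- model@masks[[name]]
  if (is.null(m)) stop("model has no mask named '", name, "'")
  m
}

#' @rdname accessors
#' @export
refSlice <- function(model) model@refSlice

#' Per-voxel density grid (kg/m3), 0 in air
#' @rdname accessors
#' @export
densityGrid <- function(model) {
  lab <- model@labels
  rho <- array(0, dim(lab))
  for (id in names(model@density)) {
    sel <- lab == as.integer(id)
    if (any(sel)) rho[sel] <- model@density[[id]]
  }
  rho
}

#' Total tissue mass (kg) over the whole_body mask (blanket excluded)
#' @rdname accessors
#' @export
totalMass <- function(model) {
  rho <- densityGrid(model)
  wb <- model@masks$whole_body
  if (is.null(wb)) wb <- model@labels > 0L
  sum(rho[wb]) * voxelVolume(model)
}

#' Look up the integer label of a tissue by name
#' @param tissue Tissue name.
#' @rdname accessors
#' @export
labelOf <- function(model, tissue) {
  hit <- names(model@tissueNames)[model@tissueNames == tissue]
  if (!length(hit)) stop("model has no tissue named '", tissue, "'")
  as.integer(hit[1])
}

#' Pointwise SAR grid of a SARResult
#' @param x A \linkS4class{SARResult}.
#' @export
sarGrid <- function(x) x@sar

#' 10 g averaged SAR grid (NA where invalid)
#' @rdname sarGrid
#' @export
sar10gGrid <- function(x) x@sar10g

#' Peak spatial 10 g SAR and its voxel location
#' @rdname sarGrid
#' @export
psSAR10g <- function(x) x@psSAR10g

#' @rdname sarGrid
#' @export
psLocation <- function(x) x@psLocation

#' Temperature grid of a ThermalState
#' @param state A \linkS4class{ThermalState}.
#' @export
temperatureGrid <- function(state) state@Tgrid

#' @rdname temperatureGrid
#' @export
bloodTemperature <- function(state) state@Tblood

#' @rdname temperatureGrid
#' @export
simTime <- function(state) state@time
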