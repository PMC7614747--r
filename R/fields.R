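# Parametric surrogate exposure fields.
#
# Full-wave electromagnetic simulation of the coil is out of scope; these
# surrogates provide deterministic |E| / B1+ grids with a self-consistent
# power budget so that the dosimetry and thermal machinery can be exercised
# and validated.  The |E| grids are RMS magnitudes: SAR = sigma |E|^2 / rho.

#' Construct a surrogate exposure field
#'
#' The raw |E| shape is scaled so that the power absorbed in tissue,
#' computed by integrating sigma |E|^2 over the model, equals
#' forward - reflected - radiated.  The budget therefore closes exactly by
#' construction; externally supplied budgets are validated to 1 percent.
#'
#' @param model A \linkS4class{VoxelModel} defining the grid and tissues.
#' @param table A \linkS4class{TissueTable} for conductivities.
#' @param kind one of \code{"uniform"}, \code{"radial_gradient"},
#'   \code{"superficial_hotspot"}.
#' @param Pin forward (input) power at the coil, W.
#' @param reflectedFrac,radiatedFrac fractions of \code{Pin} reflected at
#'   the ports and radiated past the subject.  Defaults follow a
#'   neonate-in-head-coil-like budget (11 percent reflected, ~30 percent
#'   radiated, i.e. 59 percent absorbed).
#' @param b1PerSqrtW mean achievable |B1+| per square-root watt (uT/sqrt(W)).
#' @param b1Shape relative parabolic depression of |B1+| towards the grid
#'   edge (0 = uniform).
#' @param hotspot for \code{superficial_hotspot}: list(centre_mm, sigma_mm,
#'   amplitude) Gaussian added to a baseline of 1; the default sits on the
#'   posterior surface of the head (the back of the neck), where local SAR
#'   maxima are seen in head-coil exposure.
#' @param axialSigma_mm axial (z) Gaussian envelope of the field about the
#'   coil centre (taken at the head reference slice), emulating the finite
#'   sensitive length of a head transmit coil; NULL disables.  Applied to
#'   the non-uniform kinds only.
#' @param frequency MHz used for conductivity lookup.
#' @return An \linkS4class{ExposureField}.
#' @export
surrogateField <- function(model, table, kind = c("radial_gradient", "uniform",
                                                  "superficial_hotspot"),
                           Pin = 1, reflectedFrac = 0.11, radiatedFrac = 0.30,
                           b1PerSqrtW = 0.53, b1Shape = 0.3,
                           hotspot = NULL, axialSigma_mm = 70,
                           frequency = 297) {
  kind <- match.arg(kind)
  if (reflectedFrac < 0 || radiatedFrac < 0 || reflectedFrac + radiatedFrac >= 1)
    stop("reflected + radiated fractions must lie in [0, 1)")
  d <- dim(model@labels)
  vs <- model@voxelSize
  g <- coordGrids(d, vs)
  cx <- d[1] * vs[1] / 2; cy <- d[2] * vs[2] / 2
  rxy <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  Rref <- max(cx, cy)
  shape <- switch(kind,
    uniform = array(1, d),
    radial_gradient = rxy / Rref,
    superficial_hotspot = {
      hs <- hotspot
      if (is.null(hs)) {
        hc <- model@meta$headCentre
        if (is.null(hc)) hc <- c(cx, cy, model@refSlice * vs[3])
        headR <- 0.4 * min(cx, cy)
        if (!is.null(model@masks$head))
          headR <- (3 * sum(model@masks$head) * prod(vs) / (4 * pi))^(1 / 3)
        # default hotspot: posterior neck surface (back of the head region)
        hs <- list(centre_mm = hc + c(0, -headR, -0.6 * headR),
                   sigma_mm = 30, amplitude = 0.8)
      }
      r2 <- (g$x - hs$centre_mm[1])^2 + (g$y - hs$centre_mm[2])^2 +
        (g$z - hs$centre_mm[3])^2
      1 + hs$amplitude * exp(-r2 / (2 * hs$sigma_mm^2))
    })
  if (kind != "uniform" && !is.null(axialSigma_mm)) {
    zc <- model@refSlice * vs[3]
    shape <- shape * exp(-(g$z - zc)^2 / (2 * axialSigma_mm^2))
  }
  sigma <- conductivityGrid(model, table, frequency)
  Pabs_target <- Pin * (1 - reflectedFrac - radiatedFrac)
  Praw <- sum(sigma * shape^2) * voxelVolume(model)
  if (Praw <= 0) stop("surrogate shape deposits no power in tissue")
  Emag <- shape * sqrt(Pabs_target / Praw)
  b1mag <- b1PerSqrtW * sqrt(Pin) * (1 - b1Shape * (rxy / Rref)^2)
  B1 <- array(complex(real = b1mag, imaginary = 0), d)
  budget <- c(forward = Pin, reflected = reflectedFrac * Pin,
              radiated = radiatedFrac * Pin, absorbed = Pabs_target)
  new("ExposureField", Emag = Emag, B1 = B1, budget = budget, Pin = Pin,
      centralSlice = model@refSlice,
      meta = list(kind = kind, b1PerSqrtW = b1PerSqrtW))
}

# Per-voxel conductivity (S/m) resolved from labels at a frequency.
conductivityGrid <- function(model, table, frequency = 297) {
  lab <- model@labels
  sigma <- array(0, dim(lab))
  for (id in names(model@tissueNames)) {
    nm <- model@tissueNames[[id]]
    if (nm == "blanket_wool") next
    row <- tissueLookup(table, nm, frequency)
    sigma[lab == as.integer(id)] <- row$sigma_S_per_m
  }
  sigma
}

#' Build an ExposureField from explicit grids and a budget
#'
#' Validates budget closure to 1 percent instead of constructing the
#' absorbed power.
#'
#' @param Emag RMS |E| grid (V/m).
#' @param B1 complex B1+ grid (uT).
#' @param budget named numeric (forward, reflected, radiated, absorbed), W.
#' @param centralSlice z index of the central axial slice.
#' @param meta list.
#' @return An \linkS4class{ExposureField}.
#' @export
exposureField <- function(Emag, B1, budget, centralSlice, meta = list()) {
  new("ExposureField", Emag = Emag, B1 = B1, budget = budget,
      Pin = unname(budget[["forward"]]),
      centralSlice = as.integer(centralSlice), meta = meta)
}

#' Write / read an exposure field (NIfTI grids + JSON budget sidecar)
#'
#' Grids are stored as \code{E_rms.nii.gz}, \code{B1_real.nii.gz},
#' \code{B1_imag.nii.gz}; the power budget and slice index go into
#' \code{field.json}.
#'
#' @param field An \linkS4class{ExposureField}.
#' @param dir Directory.
#' @export
writeField <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(field@Emag), file.path(dir, "E_rms.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(Re(field@B1)), file.path(dir, "B1_real.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(Im(field@B1)), file.path(dir, "B1_imag.nii.gz"))
  side <- list(budget_W = as.list(field@budget), Pin_W = field@Pin,
               centralSlice = field@centralSlice)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA),
             file.path(dir, "field.json"))
  invisible(dir)
}

#' @rdname writeField
#' @export
readField <- function(dir) {
  side <- jsonlite::fromJSON(file.path(dir, "field.json"))
  E <- RNifti::readNifti(file.path(dir, "E_rms.nii.gz"))
  br <- RNifti::readNifti(file.path(dir, "B1_real.nii.gz"))
  bi <- RNifti::readNifti(file.path(dir, "B1_imag.nii.gz"))
  d <- dim(E)
  exposureField(array(as.numeric(E), d),
                array(complex(real = as.numeric(br), imaginary = as.numeric(bi)), d),
                budget = unlist(side$budget_W),
                centralSlice = side$centralSlice)
}
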