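#' Load a tissue property table
#'
#' Reads a CSV of per-tissue dielectric and thermal properties.  The packaged
#' default (\code{tissues_adult.csv}) carries literature-representative adult
#' values at 297 MHz with a provenance string per entry; it is an editable
#' input, not a hard-coded constant table.
#'
#' @param path CSV path; default is the packaged adult table.
#' @return A \linkS4class{TissueTable}.
#' @export
tissueTable <- function(path = system.file("extdata", "tissues_adult.csv",
                                           package = "neodose")) {
  props <- read.csv(path, stringsAsFactors = FALSE)
  new("TissueTable", props = props)
}

#' Load a dielectric age-scaling table
#'
#' The packaged default (\code{scaling_neonate.csv}) is a clearly-labelled
#' synthetic default constructed from the water-content-driven approach used
#' in the literature (ratios >= 1 for permittivity and conductivity of
#' low-water adult tissues).  Authoritative newborn/adult ratios should be
#' supplied via this CSV interface for publication-grade use.
#'
#' @param path CSV path; default is the packaged neonatal scaling table.
#' @return A \linkS4class{ScalingTable}.
#' @export
scalingTable <- function(path = system.file("extdata", "scaling_neonate.csv",
                                            package = "neodose")) {
  new("ScalingTable", ratios = read.csv(path, stringsAsFactors = FALSE))
}

#' Identity scaling table for a tissue table
#'
#' @param table A \linkS4class{TissueTable}.
#' @return A \linkS4class{ScalingTable} with all ratios 1.
#' @export
identityScalingTable <- function(table) {
  p <- table@props
  new("ScalingTable",
      ratios = data.frame(tissue = p$tissue, freq_MHz = p$freq_MHz,
                          ratio_eps = 1, ratio_sigma = 1,
                          source = "identity", stringsAsFactors = FALSE))
}

#' Apply age-adjustment scaling to dielectric properties
#'
#' Multiplies permittivity by \code{ratio_eps} and conductivity by
#' \code{ratio_sigma}, tissue by tissue.  Thermal properties and density are
#' left unchanged: adult thermal values are retained as a conservative
#' choice, since higher neonatal water content would raise conductivity and
#' heat capacity and so lower predicted temperatures.
#'
#' @param adult A \linkS4class{TissueTable} of adult properties.
#' @param ratios A \linkS4class{ScalingTable}.  Tissues present in
#'   \code{adult} but absent from \code{ratios} default to ratio 1 with a
#'   warning.
#' @return A scaled \linkS4class{TissueTable}.
#' @export
applyAgeScaling <- function(adult, ratios) {
  stopifnot(is(adult, "TissueTable"), is(ratios, "ScalingTable"))
  p <- adult@props
  r <- ratios@ratios
  idx <- match(p$tissue, r$tissue)
  if (anyNA(idx))
    warning("no scaling ratio for: ",
            paste(p$tissue[is.na(idx)], collapse = ", "),
            "; using ratio 1")
  re <- ifelse(is.na(idx), 1, r$ratio_eps[idx])
  rs <- ifelse(is.na(idx), 1, r$ratio_sigma[idx])
  if (any(re <= 0) || any(rs <= 0)) stop("scaling ratios must be > 0")
  p$eps_r <- p$eps_r * re
  p$sigma_S_per_m <- p$sigma_S_per_m * rs
  new("TissueTable", props = p)
}

#' Neonatal metabolic-rate scaling
#'
#' Scales the per-tissue metabolic heat production for neonatal thermal
#' runs.  Adult per-tissue rates combined with neonatal body proportions
#' (the brain is ~15 percent of body mass) overstate whole-body heat
#' production; the default factor 0.5 brings the packaged phantom to a
#' basal metabolic rate of ~1.6 W per kg body mass, within the literature
#' range for term neonates.  Dielectric and other thermal fields are
#' unchanged.
#'
#' @param table A \linkS4class{TissueTable}.
#' @param factor multiplier applied to \code{qmet_W_kg}.
#' @return A \linkS4class{TissueTable}.
#' @export
neonatalMetabolicScaling <- function(table, factor = 0.5) {
  stopifnot(factor >= 0)
  table@props$qmet_W_kg <- table@props$qmet_W_kg * factor
  table
}

#' Elementwise reciprocal of a scaling table
#' @param ratios A \linkS4class{ScalingTable}.
#' @export
reciprocalScalingTable <- function(ratios) {
  r <- ratios@ratios
  r$ratio_eps <- 1 / r$ratio_eps
  r$ratio_sigma <- 1 / r$ratio_sigma
  new("ScalingTable", ratios = r)
}

#' Look up properties for one tissue at a frequency
#'
#' No interpolation is performed across frequencies: the requested frequency
#' must lie within 10 percent of a stored entry.
#'
#' @param table A \linkS4class{TissueTable}.
#' @param tissue Tissue name.
#' @param frequency Frequency in MHz.
#' @return One-row data.frame of properties.
#' @export
tissueLookup <- function(table, tissue, frequency) {
  p <- table@props
  row <- p[p$tissue == tissue, , drop = FALSE]
  if (!nrow(row)) stop("unknown tissue '", tissue, "'")
  ok <- abs(row$freq_MHz - frequency) <= 0.1 * row$freq_MHz
  if (!any(ok))
    stop(sprintf("no entry for '%s' within 10%% of %g MHz (stored: %s MHz)",
                 tissue, frequency, paste(row$freq_MHz, collapse = ", ")))
  row[which(ok)[1], , drop = FALSE]
}

#' Simplify a model's segmentation via a fallback tissue
#'
#' Remaps every label whose tissue is not in \code{keep} to the label of
#' \code{fallback} (the connective-tissue fallback used when a finely
#' segmented model is reduced to a coarser tissue set).  Masks are
#' recomputed; voxel count is conserved.
#'
#' @param model A \linkS4class{VoxelModel}.
#' @param keep Character vector of tissue names to keep.
#' @param fallback Tissue name to which all other labels are remapped.
#' @return A \linkS4class{VoxelModel}.
#' @export
simplifySegmentation <- function(model, keep, fallback = "connective") {
  if (!length(keep)) stop("keep set must not be empty")
  if (!fallback %in% model@tissueNames)
    stop("fallback tissue '", fallback, "' not present in the model")
  fallbackLab <- labelOf(model, fallback)
  lab <- model@labels
  dropNames <- setdiff(model@tissueNames, c(keep, fallback))
  # never remap the blanket layer: it is insulation, not anatomy
  dropNames <- setdiff(dropNames, "blanket_wool")
  for (nm in dropNames) {
    lab[lab == labelOf(model, nm)] <- fallbackLab
  }
  keepIds <- names(model@tissueNames)[model@tissueNames %in%
                                        c(keep, fallback, "blanket_wool")]
  out <- model
  out@labels <- lab
  out@tissueNames <- model@tissueNames[keepIds]
  out@density <- model@density[keepIds]
  out@masks <- recomputeMasks(out)
  validObject(out)
  out
}

# Rebuild the derived masks from labels, preserving geometric masks (head,
# face) that are not label-driven.
recomputeMasks <- function(model) {
  masks <- model@masks
  lab <- model@labels
  blanketLab <- suppressWarnings(tryCatch(labelOf(model, "blanket_wool"),
                                          error = function(e) NA_integer_))
  blanket <- if (!is.na(blanketLab)) lab == blanketLab else array(FALSE, dim(lab))
  masks$blanket <- blanket
  masks$whole_body <- lab > 0L & !blanket
  if ("skin" %in% model@tissueNames)
    masks$skin <- lab == labelOf(model, "skin")
  masks
}
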