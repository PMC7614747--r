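# Synthetic voxel phantoms built from nested ellipsoid parts.
#
# The phantoms are deliberately parametric (nested ellipsoids, not
# MRI-derived anatomy): the analysis pipeline only needs a labelled grid
# with realistic masses, masks and tissue classes, and parametric geometry
# keeps every phantom reproducible bit-exactly from a PhantomSpec.

.tissueLabelMap <- c(skin = 1L, fat = 2L, muscle = 3L, bone = 4L, brain = 5L,
                     csf = 6L, blood = 7L, heart = 8L, lung = 9L, liver = 10L,
                     cartilage = 11L, connective = 12L, eye = 13L,
                     blanket_wool = 99L)

#' Construct a VoxelModel directly from a label array
#'
#' Masks (whole_body, skin, blanket) are derived from the labels; head and
#' core masks can be supplied or added later.
#'
#' @param labels integer 3-D array (0 = air), values from the package label
#'   map (skin=1, fat=2, muscle=3, bone=4, brain=5, csf=6, blood=7, heart=8,
#'   lung=9, liver=10, cartilage=11, connective=12, eye=13, blanket=99) or a
#'   custom \code{tissueNames} map.
#' @param voxelSize voxel edge lengths (mm), scalar or length 3.
#' @param tissueNames named character label->name map; defaults to the
#'   package map restricted to the labels present.
#' @param density named numeric label->density (kg/m3); defaults to the
#'   packaged adult table.
#' @param refSlice z index of the anatomical reference slice; defaults to
#'   the mid-slice of the tissue extent.
#' @param masks optional extra masks (e.g. head).
#' @param meta metadata list.
#' @return A \linkS4class{VoxelModel}.
#' @export
voxelModel <- function(labels, voxelSize, tissueNames = NULL, density = NULL,
                       refSlice = NULL, masks = list(), meta = list()) {
  storage.mode(labels) <- "integer"
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  used <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (is.null(tissueNames)) {
    nm <- names(.tissueLabelMap)[match(used, .tissueLabelMap)]
    if (anyNA(nm)) stop("labels not in the package tissue map: ",
                        paste(used[is.na(nm)], collapse = ", "),
                        "; supply tissueNames explicitly")
    tissueNames <- setNames(nm, as.character(used))
  }
  if (is.null(density)) {
    tt <- tissueTable()
    idx <- match(tissueNames, tt@props$tissue)
    if (anyNA(idx)) stop("no packaged density for tissue(s): ",
                         paste(tissueNames[is.na(idx)], collapse = ", "))
    density <- setNames(tt@props$rho_kg_m3[idx], names(tissueNames))
  }
  m <- new("VoxelModel", labels = labels, voxelSize = as.numeric(voxelSize),
           tissueNames = tissueNames, density = density, masks = masks,
           refSlice = 0L, meta = meta)
  m@masks <- recomputeMasks(m)
  for (nm in names(masks)) m@masks[[nm]] <- masks[[nm]]
  if (is.null(refSlice)) {
    zAny <- which(apply(m@masks$whole_body, 3, any))
    refSlice <- if (length(zAny)) as.integer(round(mean(range(zAny)))) else 1L
  }
  m@refSlice <- as.integer(refSlice)
  validObject(m)
  m
}

# ---- PhantomSpec constructors ------------------------------------------------

.part <- function(centre, semi, layers, scalable = FALSE, role = NA_character_) {
  list(centre = centre, semi = semi, layers = layers, scalable = scalable,
       role = role)
}

#' Default term-neonate phantom specification
#'
#' A ~3.5 kg term-neonate stand-in built from nested ellipsoids: layered
#' head (skin/fat/skull/CSF/brain) with a ~1030 mL head region, layered
#' torso with heart (wall + chamber blood), lungs, liver and a bony spine,
#' flexed limbs, eyes, a cartilaginous nose and an optional hand near the
#' face.  The torso and limb cross-sections are calibrated so the total
#' mass matches \code{targetMass} within 2 percent.
#'
#' @param targetMass target body mass (kg); default 3.50.
#' @param voxel voxel edge (mm), isotropic; default 2.
#' @param gridDim grid shape; default c(96, 96, 136) at 2 mm.
#' @param headVolume target head-region volume (mL); default 1030.
#' @param handNearFace include the hand-near-the-face feature.
#' @param seed integer seed (fixes the phantom bit-exactly).
#' @param jitter relative geometry jitter (default 0.02).
#' @return A \linkS4class{PhantomSpec}.
#' @export
neonatePhantomSpec <- function(targetMass = 3.50, voxel = 2,
                               gridDim = c(96L, 96L, 136L),
                               headVolume = 1030, handNearFace = TRUE,
                               seed = 1L, jitter = 0.02) {
  vs <- rep(voxel, 3L)
  dom <- gridDim * vs
  cx <- dom[1] / 2
  cy <- dom[2] / 2
  headR <- (3 * headVolume * 1000 / (4 * pi))^(1 / 3)  # mm
  headC <- c(cx, cy, 200)
  parts <- list(
    torso = .part(c(cx, cy, 95), c(70, 55, 90),
                  c(skin = 2, fat = 5, muscle = 10, connective = Inf),
                  scalable = TRUE),
    leg_l = .part(c(cx - 30, cy + 24, 42), c(20, 20, 36),
                  c(skin = 2, fat = 3, muscle = 10, bone = Inf),
                  scalable = TRUE),
    leg_r = .part(c(cx + 30, cy + 24, 42), c(20, 20, 36),
                  c(skin = 2, fat = 3, muscle = 10, bone = Inf),
                  scalable = TRUE),
    arm_l = .part(c(cx - 38, cy + 40, 150), c(15, 15, 45),
                  c(skin = 2, fat = 2, muscle = 8, bone = Inf),
                  scalable = TRUE),
    arm_r = .part(c(cx + 38, cy + 40, 150), c(15, 15, 45),
                  c(skin = 2, fat = 2, muscle = 8, bone = Inf),
                  scalable = TRUE),
    spine = .part(c(cx, cy - 34, 95), c(7, 7, 86), c(bone = Inf)),
    lung_l = .part(c(cx - 18, cy, 110), c(14, 18, 24), c(lung = Inf)),
    lung_r = .part(c(cx + 18, cy, 110), c(14, 18, 24), c(lung = Inf)),
    liver = .part(c(cx + 10, cy - 4, 88), c(26, 20, 16), c(liver = Inf)),
    heart = .part(c(cx, cy + 4, 118), c(16, 16, 18),
                  c(heart = 5, blood = Inf)),
    head = .part(headC, rep(headR, 3),
                 c(skin = 2, fat = 2, bone = 6, csf = 4, brain = Inf),
                 role = "head"),
    eye_l = .part(c(cx - 20, cy + 52, 206), c(7, 7, 7), c(eye = Inf)),
    eye_r = .part(c(cx + 20, cy + 52, 206), c(7, 7, 7), c(eye = Inf)),
    nose = .part(c(cx, cy + 59, 206), c(6, 5, 8), c(cartilage = Inf))
  )
  if (handNearFace)
    parts$hand <- .part(c(cx + 24, cy + 64, 196), c(16, 12, 22),
                        c(skin = 2, fat = 2, muscle = Inf), role = "hand")
  new("PhantomSpec", targetMass = targetMass, gridDim = as.integer(gridDim),
      voxelSize = vs, parts = parts, headTargetVolume = headVolume,
      calibrate = TRUE, seed = as.integer(seed), jitter = jitter)
}

#' Sphere-only phantom specification
#'
#' A single homogeneous sphere; useful for analytic volume/mass checks and
#' solver validation.
#'
#' @param radius sphere radius (mm).
#' @param tissue tissue name for the whole sphere.
#' @param voxel voxel edge (mm).
#' @param margin air margin around the sphere (mm).
#' @param layers optional named layer vector overriding the homogeneous fill.
#' @param seed integer seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
spherePhantomSpec <- function(radius, tissue = "muscle", voxel = 2,
                              margin = 6, layers = NULL, seed = 1L) {
  n <- as.integer(ceiling((2 * radius + 2 * margin) / voxel))
  dom <- n * voxel
  if (is.null(layers)) layers <- setNames(Inf, tissue)
  parts <- list(sphere = .part(rep(dom / 2, 3), rep(radius, 3), layers,
                               role = "head"))
  new("PhantomSpec", targetMass = NA_real_, gridDim = rep(n, 3L),
      voxelSize = rep(voxel, 3L), parts = parts,
      headTargetVolume = NA_real_, calibrate = FALSE,
      seed = as.integer(seed), jitter = 0)
}

# ---- rasterization -----------------------------------------------------------

# Rasterize one part into `labels`, restricted to its bounding box.
.rasterizePart <- function(labels, part, vs) {
  d <- dim(labels)
  lo <- pmax(1L, as.integer(floor((part$centre - part$semi) / vs)) )
  hi <- pmin(d, as.integer(ceiling((part$centre + part$semi) / vs)) + 1L)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  xs <- (ix - 0.5) * vs[1]; ys <- (iy - 0.5) * vs[2]; zs <- (iz - 0.5) * vs[3]
  dl <- c(length(ix), length(iy), length(iz))
  gx <- array(rep((xs - part$centre[1]), times = dl[2] * dl[3]), dl)
  gy <- array(rep(rep((ys - part$centre[2]), each = dl[1]), times = dl[3]), dl)
  gz <- array(rep((zs - part$centre[3]), each = dl[1] * dl[2]), dl)
  sub <- labels[ix, iy, iz, drop = FALSE]
  insideOf <- function(semi)
    (gx / semi[1])^2 + (gy / semi[2])^2 + (gz / semi[3])^2 <= 1
  t <- 0
  inOuter <- insideOf(part$semi)
  for (li in seq_along(part$layers)) {
    lab <- .tissueLabelMap[[names(part$layers)[li]]]
    if (!is.finite(part$layers[li])) {        # innermost fill
      sub[inOuter] <- lab
      break
    }
    t2 <- t + part$layers[li]
    innerSemi <- part$semi - t2
    inInner <- if (any(innerSemi <= 0)) array(FALSE, dl) else insideOf(innerSemi)
    sub[inOuter & !inInner] <- lab
    inOuter <- inInner
    t <- t2
    if (!any(inOuter)) break
  }
  labels[ix, iy, iz] <- sub
  labels
}

.checkGeometry <- function(spec, parts) {
  dom <- spec@gridDim * spec@voxelSize
  for (nm in names(parts)) {
    p <- parts[[nm]]
    if (any(p$semi <= 0))
      stop("geometry error: part '", nm, "' has a non-positive semi-axis")
    if (any(p$centre - p$semi < 0) || any(p$centre + p$semi > dom))
      stop("geometry error: part '", nm, "' does not fit inside the ",
           paste(dom, collapse = " x "), " mm grid")
  }
  invisible(TRUE)
}

.rasterizeAll <- function(spec, parts) {
  labels <- array(0L, spec@gridDim)
  for (p in parts) labels <- .rasterizePart(labels, p, spec@voxelSize)
  labels
}

.scaleParts <- function(parts, s) {
  for (nm in names(parts)) {
    if (isTRUE(parts[[nm]]$scalable))
      parts[[nm]]$semi[1:2] <- parts[[nm]]$semi[1:2] * s
  }
  parts
}

.modelMassFromLabels <- function(labels, vs, density) {
  used <- setdiff(unique(as.integer(labels)), 0L)
  m <- 0
  for (id in used) m <- m + sum(labels == id) * density[[as.character(id)]]
  m * prod(vs) * 1e-9
}

#' Generate a synthetic voxel phantom
#'
#' Rasterizes the parts of a \linkS4class{PhantomSpec} into a labelled voxel
#' grid, applies seed-driven geometric jitter, optionally calibrates the
#' torso/limb cross-sections so the total mass hits the spec target within
#' 2 percent, and builds the head / skin / whole-body / core masks.
#' Deterministic for a fixed spec (including seed).
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @return A \linkS4class{VoxelModel}.
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  parts <- spec@parts
  if (spec@jitter > 0) {
    set.seed(spec@seed)
    for (nm in names(parts)) {
      j <- 1 + runif(3, -spec@jitter, spec@jitter)
      parts[[nm]]$semi <- parts[[nm]]$semi * j
    }
  }
  .checkGeometry(spec, parts)
  tt <- tissueTable()
  dens <- setNames(tt@props$rho_kg_m3[match(names(.tissueLabelMap), tt@props$tissue)],
                   as.character(.tissueLabelMap))
  if (spec@calibrate && is.finite(spec@targetMass)) {
    lo <- 0.7; hi <- 1.35
    f <- function(s) {
      ps <- .scaleParts(parts, s)
      .checkGeometry(spec, ps)
      .modelMassFromLabels(.rasterizeAll(spec, ps), spec@voxelSize, dens) -
        spec@targetMass
    }
    feasible <- function(s)
      !inherits(try(.checkGeometry(spec, .scaleParts(parts, s)),
                    silent = TRUE), "try-error")
    while (hi > lo && !feasible(hi)) hi <- hi * 0.97
    if (hi <= lo)
      stop("geometry error: no feasible scale range for mass calibration")
    flo <- f(lo); fhi <- f(hi)
    if (flo > 0 || fhi < 0)
      stop("geometry error: cannot calibrate mass to ", spec@targetMass,
           " kg within the allowed scale range")
    for (i in 1:12) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) <= 0.005 * spec@targetMass) { lo <- hi <- mid; break }
      if (fm > 0) hi <- mid else lo <- mid
    }
    parts <- .scaleParts(parts, (lo + hi) / 2)
  }
  labels <- .rasterizeAll(spec, parts)
  usedNames <- names(.tissueLabelMap)[.tissueLabelMap %in% unique(as.integer(labels))]
  tn <- setNames(usedNames, as.character(.tissueLabelMap[usedNames]))
  density <- dens[names(tn)]
  masks <- list()
  headPart <- Filter(function(p) identical(p$role, "head"), parts)
  if (length(headPart)) {
    hp <- headPart[[1]]
    d <- dim(labels)
    g <- coordGrids(d, spec@voxelSize)
    masks$head <- inEllipsoid(g, hp$centre, hp$semi) & labels > 0L
  }
  refSlice <- if (length(headPart))
    as.integer(round(headPart[[1]]$centre[3] / spec@voxelSize[3]))
  else NULL
  model <- voxelModel(labels, spec@voxelSize, tissueNames = tn,
                      density = density, refSlice = refSlice, masks = masks,
                      meta = list(spec = list(seed = spec@seed,
                                              targetMass = spec@targetMass),
                                  headCentre = if (length(headPart)) headPart[[1]]$centre))
  if (all(c("heart", "brain") %in% tn) || all(c("blood", "brain") %in% tn))
    model@masks$core <- defineCoreMask(model)
  if (is.finite(spec@targetMass)) {
    m <- totalMass(model)
    if (abs(m - spec@targetMass) > 0.05 * spec@targetMass)
      stop(sprintf("calibrated mass %.3f kg misses target %.2f kg by > 5%%",
                   m, spec@targetMass))
  }
  if (is.finite(spec@headTargetVolume) && !is.null(model@masks$head)) {
    hv <- sum(model@masks$head) * voxelVolume(model) * 1e6  # mL
    if (abs(hv - spec@headTargetVolume) > 0.1 * spec@headTargetVolume)
      warning(sprintf("head mask volume %.0f mL misses target %.0f mL by > 10%%",
                      hv, spec@headTargetVolume))
  }
  model
}

#' Add an insulating blanket shell
#'
#' Wraps the body in a wool shell of the given thickness, adjacent to the
#' exterior surface, leaving the face aperture uncovered.  Tissue labels are
#' unchanged; the blanket carries zero perfusion and zero metabolic heat and
#' insulates through its low thermal conductivity.
#'
#' @param model A \linkS4class{VoxelModel}.
#' @param thickness_mm blanket thickness (mm); 0 returns the model unchanged.
#' @param faceAperture either NULL (full coverage) or a list with
#'   \code{apex} (mm, defaults to the head centre), \code{direction}
#'   (defaults to anterior, +y) and \code{halfAngleDeg}: blanket voxels whose
#'   direction from the apex lies within the cone are removed.
#' @return A \linkS4class{VoxelModel} with a blanket layer and mask.
#' @export
addBlanket <- function(model, thickness_mm,
                       faceAperture = list(direction = c(0, 1, 0),
                                           halfAngleDeg = 55)) {
  if (is.null(model@masks$skin)) stop("model has no skin mask")
  if (thickness_mm == 0) return(model)
  vs <- mean(model@voxelSize)
  nvox <- round(thickness_mm / vs)
  if (nvox < 1) stop("blanket thickness ", thickness_mm,
                     " mm is less than one voxel (", vs, " mm)")
  body <- model@labels > 0L
  shell <- dilateEuclidean(body, nvox) & !body
  if (!is.null(faceAperture)) {
    apex <- faceAperture$apex
    if (is.null(apex)) apex <- model@meta$headCentre
    if (is.null(apex)) stop("faceAperture needs an apex (none stored in model)")
    dir <- faceAperture$direction / sqrt(sum(faceAperture$direction^2))
    g <- coordGrids(dim(body), model@voxelSize)
    dx <- g$x - apex[1]; dy <- g$y - apex[2]; dz <- g$z - apex[3]
    nrm <- sqrt(dx^2 + dy^2 + dz^2)
    nrm[nrm == 0] <- 1
    cosang <- (dx * dir[1] + dy * dir[2] + dz * dir[3]) / nrm
    inCone <- cosang >= cos(faceAperture$halfAngleDeg * pi / 180)
    shell <- shell & !inCone
  }
  out <- model
  lab <- model@labels
  lab[shell] <- .tissueLabelMap[["blanket_wool"]]
  out@labels <- lab
  if (!"blanket_wool" %in% out@tissueNames) {
    out@tissueNames <- c(out@tissueNames,
                         setNames("blanket_wool",
                                  as.character(.tissueLabelMap[["blanket_wool"]])))
    tt <- tissueTable()
    out@density <- c(out@density,
                     setNames(tt@props$rho_kg_m3[tt@props$tissue == "blanket_wool"],
                              as.character(.tissueLabelMap[["blanket_wool"]])))
  }
  out@masks <- recomputeMasks(out)
  for (nm in setdiff(names(model@masks), names(out@masks)))
    out@masks[[nm]] <- model@masks[[nm]]
  out@masks$head <- model@masks$head
  out@masks$core <- model@masks$core
  out@masks <- Filter(Negate(is.null), out@masks)
  validObject(out)
  out
}

#' Define the core (heart + brain interior) mask
#'
#' The core region is the union of the morphologically eroded (one voxel,
#' 6-neighbourhood) heart and brain compartments; chamber blood counts as
#' part of the heart compartment.  If erosion empties a compartment (e.g. a
#' single-voxel heart in a toy grid), the un-eroded compartment is used for
#' that part.
#'
#' @param model A \linkS4class{VoxelModel}.
#' @return Logical mask array.
#' @export
defineCoreMask <- function(model) {
  tn <- model@tissueNames
  heartNames <- intersect(c("heart", "blood"), tn)
  if (!length(heartNames)) stop("model lacks a heart/blood tissue")
  if (!"brain" %in% tn) stop("model lacks a brain tissue")
  lab <- model@labels
  heart <- array(FALSE, dim(lab))
  for (nm in heartNames) heart <- heart | lab == labelOf(model, nm)
  brain <- lab == labelOf(model, "brain")
  eh <- erode6(heart); if (!any(eh) && any(heart)) eh <- heart
  eb <- erode6(brain); if (!any(eb) && any(brain)) eb <- brain
  eh | eb
}

#' Translate a model on its grid
#'
#' The shift is quantized to whole voxels (rounded; the residual is recorded
#' in \code{meta$shiftResidual_mm}).  Labels and all masks are translated
#' identically; voxels shifted outside the grid are dropped with a warning,
#' and the anatomical reference slice index moves with the model.
#'
#' @param model A \linkS4class{VoxelModel}.
#' @param shift_mm numeric length-3 shift in mm (x, y, z).
#' @return A translated \linkS4class{VoxelModel}.
#' @export
shiftModel <- function(model, shift_mm) {
  d <- dim(model@labels)
  sv <- as.integer(round(shift_mm / model@voxelSize))
  if (any(abs(sv) >= d)) stop("shift larger than the grid")
  resid <- shift_mm - sv * model@voxelSize
  out <- model
  nBefore <- sum(model@labels > 0L)
  out@labels <- shiftArray(model@labels, sv, fill = 0L)
  for (nm in names(model@masks))
    out@masks[[nm]] <- shiftArray(model@masks[[nm]], sv, fill = FALSE)
  nAfter <- sum(out@labels > 0L)
  if (nAfter < nBefore)
    warning(sprintf("shift clipped %d voxels (%.1f%% of tissue)",
                    nBefore - nAfter, 100 * (nBefore - nAfter) / nBefore))
  out@refSlice <- as.integer(min(max(model@refSlice + sv[3], 1L), d[3]))
  out@meta$shiftResidual_mm <- resid
  if (!is.null(out@meta$headCentre))
    out@meta$headCentre <- out@meta$headCentre + sv * model@voxelSize
  out
}

# ---- I/O ---------------------------------------------------------------------

#' Write / read a voxel model (NIfTI + JSON sidecar)
#'
#' The label grid and each mask are written as NIfTI volumes; tissue names,
#' densities, voxel size, reference slice and metadata go into a
#' \code{model.json} sidecar.  The round trip is bit-exact for labels, voxel
#' size, masks and metadata.
#'
#' @param model A \linkS4class{VoxelModel}.
#' @param dir Output directory (created if needed).
#' @return \code{writeVoxelModel} returns \code{dir} invisibly;
#'   \code{readVoxelModel} returns a \linkS4class{VoxelModel}.
#' @export
writeVoxelModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(model@labels, pixdim = model@voxelSize),
                     file.path(dir, "labels.nii.gz"))
  for (nm in names(model@masks)) {
    m <- array(as.integer(model@masks[[nm]]), dim(model@labels))
    RNifti::writeNifti(RNifti::asNifti(m, pixdim = model@voxelSize),
                       file.path(dir, paste0("mask_", nm, ".nii.gz")))
  }
  side <- list(voxelSize_mm = model@voxelSize,
               tissueNames = as.list(model@tissueNames),
               density_kg_m3 = as.list(model@density),
               refSlice = model@refSlice,
               masks = names(model@masks),
               meta = model@meta)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(dir, "model.json"))
  invisible(dir)
}

#' @param recomputeMissingMasks if the sidecar lists no masks (external
#'   models), derive whole_body/skin/blanket from the labels.
#' @rdname writeVoxelModel
#' @export
readVoxelModel <- function(dir, recomputeMissingMasks = TRUE) {
  side <- jsonlite::fromJSON(file.path(dir, "model.json"),
                             simplifyVector = TRUE)
  lab <- RNifti::readNifti(file.path(dir, "labels.nii.gz"))
  labels <- array(as.integer(lab), dim(lab))
  used <- setdiff(unique(as.integer(labels)), 0L)
  tn <- unlist(side$tissueNames)
  dens <- unlist(side$density_kg_m3)
  missing <- setdiff(as.character(used), names(tn))
  if (length(missing))
    stop("validation error: labels present in grid but absent from sidecar: ",
         paste(missing, collapse = ", "))
  missing <- setdiff(as.character(used), names(dens))
  if (length(missing))
    stop("validation error: sidecar missing density for label(s): ",
         paste(missing, collapse = ", "))
  masks <- list()
  for (nm in side$masks) {
    f <- file.path(dir, paste0("mask_", nm, ".nii.gz"))
    if (file.exists(f)) {
      m <- RNifti::readNifti(f)
      masks[[nm]] <- array(as.integer(m) > 0L, dim(m))
    }
  }
  meta <- side$meta
  if (is.null(meta)) meta <- list()
  m <- new("VoxelModel", labels = labels,
           voxelSize = as.numeric(side$voxelSize_mm),
           tissueNames = tn, density = dens, masks = masks,
           refSlice = as.integer(side$refSlice), meta = as.list(meta))
  if (!length(masks) && recomputeMissingMasks) m@masks <- recomputeMasks(m)
  validObject(m)
  m
}
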