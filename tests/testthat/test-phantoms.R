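test_that("sphere-only phantom mass matches the analytic volume", {
  m <- generatePhantom(spherePhantomSpec(50, voxel = 1))
  rho <- tissueLookup(tissueTable(), "muscle", 297)$rho_kg_m3
  analytic <- 4 / 3 * pi * 0.05^3 * rho
  expect_lt(abs(totalMass(m) - analytic) / analytic, 0.02)
})

test_that("halving the voxel size changes the sphere volume by < 3%", {
  v <- sapply(c(2, 1), function(vx) {
    m <- generatePhantom(spherePhantomSpec(40, voxel = vx))
    sum(voxelLabels(m) > 0) * voxelVolume(m)
  })
  expect_lt(abs(v[2] - v[1]) / v[1], 0.03)
})

test_that("the default neonate phantom meets its bookkeeping targets", {
  m <- neonateModel()
  expect_gte(totalMass(m), 3.325)   # 3.50 kg within 5%
  expect_lte(totalMass(m), 3.675)
  headVol <- sum(modelMask(m, "head")) * voxelVolume(m) * 1e6
  expect_lt(abs(headVol - 1030) / 1030, 0.10)
  needed <- c("skin", "fat", "muscle", "bone", "brain", "csf", "blood",
              "heart", "connective")
  expect_true(all(needed %in% tissueNames(m)))
  # mask algebra
  wb <- modelMask(m, "whole_body")
  expect_true(all(wb[modelMask(m, "head")]))
  expect_true(all(wb[modelMask(m, "core")]))
})

test_that("phantom generation is deterministic for a fixed spec", {
  s1 <- generatePhantom(spherePhantomSpec(25, voxel = 2, seed = 7L))
  s2 <- generatePhantom(spherePhantomSpec(25, voxel = 2, seed = 7L))
  expect_identical(voxelLabels(s1), voxelLabels(s2))
  expect_identical(modelMask(s1), modelMask(s2))
})

test_that("degenerate and oversized geometry raises a geometry error", {
  expect_error(generatePhantom(spherePhantomSpec(0)), "geometry")
  sp <- spherePhantomSpec(30, voxel = 2)
  sp@parts$sphere$semi <- c(500, 500, 500)
  expect_error(generatePhantom(sp), "geometry")
})

test_that("blanket shell is adjacent to skin, respects the aperture, and is disjoint from tissue", {
  m <- skinSphere(30)
  expect_identical(addBlanket(m, 0), m)
  expect_error(addBlanket(m, 0.5), "less than one voxel")

  mb <- addBlanket(m, 8, faceAperture = NULL)
  shell <- modelMask(mb, "blanket")
  expect_false(any(shell & modelMask(mb, "whole_body")))
  expect_identical(voxelLabels(mb)[modelMask(m, "whole_body")],
                   voxelLabels(m)[modelMask(m, "whole_body")])
  # voxel count close to the analytic spherical shell volume; checked at
  # 1 mm, where surface discretization of the offset has converged
  m1 <- generatePhantom(spherePhantomSpec(30, voxel = 1,
                                          layers = c(skin = 2, muscle = Inf)))
  shell1 <- modelMask(addBlanket(m1, 8, faceAperture = NULL), "blanket")
  R <- 30; t <- 8
  analytic <- 4 / 3 * pi * ((R + t)^3 - R^3) / prod(voxelSize(m1))
  expect_lt(abs(sum(shell1) - analytic) / analytic, 0.10)

  # aperture: no blanket voxels inside the +y cone from the sphere centre
  mA <- addBlanket(m, 8, faceAperture = list(direction = c(0, 1, 0),
                                             halfAngleDeg = 45))
  shellA <- modelMask(mA, "blanket")
  g <- which(shellA, arr.ind = TRUE)
  ctr <- dim(voxelLabels(m)) / 2 + 0.5
  v <- sweep(g, 2, ctr)
  cosang <- v[, 2] / sqrt(rowSums(v^2))
  expect_true(all(cosang < cos(45 * pi / 180) + 1e-9))
  expect_lt(sum(shellA), sum(shell))
})

test_that("core mask is the eroded heart+brain interior, with degenerate fallback", {
  # hand-enumerated erosion: 3^3 heart block -> single interior voxel
  lab <- array(0L, c(7, 7, 7))
  lab[2:4, 2:4, 2:4] <- 8L           # heart
  lab[5:7, 5:7, 5:7] <- 5L           # brain block in the corner (clipped)
  m <- voxelModel(lab, 2)
  core <- defineCoreMask(m)
  expect_true(core[3, 3, 3])
  expect_equal(sum(core[2:4, 2:4, 2:4]), 1)
  expect_true(all(lab[core] %in% c(5L, 8L)))

  # single-voxel heart: erosion empties it; falls back to the voxel itself
  lab2 <- array(0L, c(5, 5, 5))
  lab2[3, 3, 3] <- 8L
  lab2[1:2, 1:2, 1:2] <- 5L
  core2 <- defineCoreMask(voxelModel(lab2, 2))
  expect_true(core2[3, 3, 3])

  lab3 <- array(0L, c(3, 3, 3)); lab3[2, 2, 2] <- 8L
  expect_error(defineCoreMask(voxelModel(lab3, 2)), "brain")
})

test_that("model shifts are exact voxel translations with clip warnings", {
  m <- generatePhantom(spherePhantomSpec(20, voxel = 2, margin = 24))
  expect_identical(voxelLabels(shiftModel(m, c(0, 0, 0))), voxelLabels(m))

  there <- shiftModel(m, c(10, 0, 0) * voxelSize(m)[1])
  back <- shiftModel(there, c(-10, 0, 0) * voxelSize(m)[1])
  expect_identical(voxelLabels(back), voxelLabels(m))
  expect_identical(modelMask(back, "whole_body"), modelMask(m, "whole_body"))

  # +50 mm at 2 mm voxels moves the centroid by exactly 25 voxels
  big <- generatePhantom(spherePhantomSpec(20, voxel = 2, margin = 60))
  sh <- shiftModel(big, c(0, 0, 50))
  cz0 <- mean(which(modelMask(big, "whole_body"), arr.ind = TRUE)[, 3])
  cz1 <- mean(which(modelMask(sh, "whole_body"), arr.ind = TRUE)[, 3])
  expect_equal(cz1 - cz0, 25)
  expect_equal(refSlice(sh), refSlice(big) + 25L)

  small <- sphereModel(20)
  expect_warning(shiftModel(small, c(0, 0, 30)), "clipped")
  expect_error(shiftModel(small, c(0, 0, 1e5)), "larger than the grid")
})

test_that("voxel models round-trip through NIfTI + JSON sidecar", {
  m <- sphereModel(20)
  dir <- withr::local_tempdir()
  writeVoxelModel(m, dir)
  m2 <- readVoxelModel(dir)
  expect_identical(voxelLabels(m2), voxelLabels(m))
  expect_identical(voxelSize(m2), voxelSize(m))
  expect_identical(modelMask(m2), modelMask(m))
  expect_identical(tissueDensity(m2)[order(names(tissueDensity(m2)))],
                   tissueDensity(m)[order(names(tissueDensity(m)))])
  expect_identical(refSlice(m2), refSlice(m))

  # sidecar missing a density -> validation error
  side <- jsonlite::fromJSON(file.path(dir, "model.json"), simplifyVector = FALSE)
  side$density_kg_m3[["3"]] <- NULL
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA),
             file.path(dir, "model.json"))
  expect_error(readVoxelModel(dir), "density")

  # external model without masks: masks recomputed from labels
  dir2 <- withr::local_tempdir()
  writeVoxelModel(m, dir2)
  side <- jsonlite::fromJSON(file.path(dir2, "model.json"), simplifyVector = FALSE)
  side$masks <- list()
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA),
             file.path(dir2, "model.json"))
  m3 <- readVoxelModel(dir2)
  expect_identical(modelMask(m3, "whole_body"), modelMask(m, "whole_body"))
})
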