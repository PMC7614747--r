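test_that("pointwise SAR implements sigma E^2 / rho with zero in air and blanket", {
  tt <- customTable(sigma = 0.5, rho = 1000)
  m <- uniformModel(n = 6, rho = 1000)
  E <- array(100, dim(voxelLabels(m)))
  f <- exposureField(E, array(0.5 + 0i, dim(E)),
                     budget = c(forward = 1, reflected = 0, radiated = 1 - 0.6,
                                absorbed = 0.6),
                     centralSlice = 3)
  # budget here is nominal; pointwiseSAR does not use it
  sar <- pointwiseSAR(f, m, tt)
  expect_equal(unique(as.numeric(sar)), 5.0)

  mb <- addBlanket(skinSphere(16), 6, faceAperture = NULL)
  fb <- surrogateField(mb, tissueTable(), "uniform")
  sarb <- pointwiseSAR(fb, mb, tissueTable())
  expect_true(all(sarb[modelMask(mb, "blanket")] == 0))
  expect_true(all(sarb[voxelLabels(mb) == 0L] == 0))

  f0 <- exposureField(array(0, dim(E)), array(0i, dim(E)),
                      budget = c(forward = 0, reflected = 0, radiated = 0,
                                 absorbed = 0), centralSlice = 3)
  expect_true(all(pointwiseSAR(f0, m, tt) == 0))
})

test_that("surrogate fields deposit exactly the absorbed-power budget", {
  m <- sphereModel(30)
  tt <- tissueTable()
  for (kind in c("uniform", "radial_gradient", "superficial_hotspot")) {
    f <- surrogateField(m, tt, kind, Pin = 2, reflectedFrac = 0.1,
                        radiatedFrac = 0.3)
    sar <- pointwiseSAR(f, m, tt)
    rho <- densityGrid(m)
    Pdep <- sum(sar * rho) * voxelVolume(m)
    expect_equal(Pdep, f@budget[["absorbed"]], tolerance = 1e-9)
    b <- f@budget
    expect_lt(abs(b[["forward"]] - sum(b[c("reflected", "radiated", "absorbed")])),
              0.01 * b[["forward"]])
  }
  expect_error(exposureField(array(1, c(2, 2, 2)), array(0i, c(2, 2, 2)),
                             budget = c(forward = 1, reflected = 0.5,
                                        radiated = 0.1, absorbed = 0.1),
                             centralSlice = 1),
               "budget")
})

test_that("region averages are mass-weighted means", {
  tt <- customTable(rho = 1000)
  m <- uniformModel(n = 4, rho = 1000)
  sar <- array(2, dim(voxelLabels(m)))
  expect_equal(regionAverageSAR(sar, m, modelMask(m, "whole_body")), 2)

  sar[1:2, , ] <- 1; sar[3:4, , ] <- 3   # equal-mass halves
  expect_equal(regionAverageSAR(sar, m, modelMask(m, "whole_body")), 2)

  # independent summation oracle on a heterogeneous phantom
  m2 <- sphereModel(16)
  set.seed(42)
  sar2 <- array(runif(length(voxelLabels(m2))), dim(voxelLabels(m2)))
  mask <- modelMask(m2, "whole_body")
  rho <- densityGrid(m2)
  oracle <- sum(sar2[mask] * rho[mask]) / sum(rho[mask])
  expect_equal(regionAverageSAR(sar2, m2, mask), oracle, tolerance = 1e-12)
  expect_error(regionAverageSAR(sar2, m2, array(FALSE, dim(rho))), "empty")
})

test_that("10 g cube averaging: uniform case, insufficient mass, oracle agreement", {
  m <- uniformModel(n = 12, voxel = 3, rho = 1000)
  sar <- array(2, dim(voxelLabels(m)))
  res <- massAveragedSAR(sar, m)
  expect_equal(res$psSAR10g, 2)
  expect_true(all(abs(res$sar10g[res$validMask] - 2) < 1e-12))

  tiny <- uniformModel(n = 2, voxel = 1, rho = 600)  # ~5 mg of tissue
  expect_error(massAveragedSAR(array(1, c(2, 2, 2)), tiny), "below")

  for (seed in 1:5) {
    cs <- randomSARCase(seed)
    got <- massAveragedSAR(cs$sar, cs$model)
    rho <- densityGrid(cs$model)
    massGrid <- rho * voxelVolume(cs$model)
    ora <- oracleSAR10g(cs$sar, massGrid, modelMask(cs$model, "whole_body"), 0.010)
    expect_equal(got$psSAR10g, ora$psSAR10g, tolerance = 1e-9)
    expect_equal(which(got$validMask), which(!is.na(ora$sar10g)))
    expect_equal(got$sar10g[got$validMask], ora$sar10g[!is.na(ora$sar10g)],
                 tolerance = 1e-9)
  }
})

test_that("mass-averaged peak is monotone non-increasing in averaging mass", {
  cs <- randomSARCase(99)
  m <- cs$model
  peaks <- sapply(c(0.001, 0.005, 0.010), function(tm)
    massAveragedSAR(cs$sar, m, targetMass = tm)$psSAR10g)
  expect_true(all(diff(peaks) <= 1e-12))
  regionAvg <- regionAverageSAR(cs$sar, m, modelMask(m, "whole_body"))
  expect_lte(min(peaks), max(peaks) + 1e-12)  # and the region mean bounds below
  expect_lte(regionAvg, peaks[1] + 1e-12)
})

test_that("summaries order as head_avg <= psSAR10g <= pointwise max", {
  m <- sphereModel(30)
  tt <- tissueTable()
  for (kind in c("radial_gradient", "superficial_hotspot")) {
    res <- computeSAR(surrogateField(m, tt, kind), m, tt)
    expect_lte(res@headAvg, res@psSAR10g)
    expect_lte(res@psSAR10g, max(sarGrid(res)) + 1e-12)
  }
})

test_that("normalized SAR is invariant to the drive power", {
  m <- sphereModel(30)
  tt <- tissueTable()
  r1 <- computeSAR(surrogateField(m, tt, "radial_gradient", Pin = 1), m, tt)
  r2 <- computeSAR(surrogateField(m, tt, "radial_gradient", Pin = 2), m, tt)
  for (mode in c("input_power", "net_forward", "absorbed", "b1_slice")) {
    n1 <- normalizeSAR(r1, mode)
    n2 <- normalizeSAR(r2, mode)
    expect_equal(as.numeric(n1), as.numeric(n2), tolerance = 1e-9,
                 label = mode)
  }
  # raw SAR itself scales linearly with power
  expect_equal(r2@headAvg, 2 * r1@headAvg, tolerance = 1e-9)
})

test_that("exposure fields round-trip through NIfTI + JSON", {
  m <- sphereModel(16)
  f <- surrogateField(m, tissueTable(), "superficial_hotspot", Pin = 1.5)
  dir <- withr::local_tempdir()
  writeField(f, dir)
  f2 <- readField(dir)
  expect_identical(f2@Emag, f@Emag)
  expect_identical(f2@B1, f@B1)
  expect_equal(f2@budget, f@budget)
  expect_equal(f2@centralSlice, f@centralSlice)
})

test_that("shift experiment: zero shift reproduces the baseline, uniform field is shift-invariant", {
  m <- generatePhantom(spherePhantomSpec(24, margin = 14))
  tt <- tissueTable()
  f <- surrogateField(m, tt, "uniform", b1Shape = 0)
  base <- computeSAR(f, m, tt)
  tab <- shiftExperiment(m, f, rbind(c(0, 0, 0), c(6, 0, 0), c(0, 0, -8)), tt)
  expect_equal(tab$psSAR10g_perB1sq[1],
               as.numeric(normalizeSAR(base, "b1_slice")[["psSAR10g"]]),
               tolerance = 1e-12)
  # no spatial structure: all shifts give the same normalized values
  expect_lt(diff(range(tab$head_avg_perB1sq)), 1e-9)
  expect_lt(diff(range(tab$psSAR10g_perB1sq)), 1e-9)
  expect_false(any(tab$flagged))
})

test_that("gradient fields change the head average under shift as the overlap integral predicts", {
  # 3-voxel toy rod in a linear-gradient field, hand-enumerated
  lab <- array(0L, c(9, 3, 3)); lab[4:6, 2, 2] <- 3L
  m <- voxelModel(lab, 2)
  m@masks$head <- lab == 3L
  d <- dim(lab)
  E <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)  # E = x index
  B1 <- array(1 + 0i, d)
  Pabs <- sum(0.77 * E[lab == 3L]^2) * voxelVolume(m)  # muscle sigma
  f <- exposureField(E, B1, c(forward = Pabs, reflected = 0, radiated = 0,
                              absorbed = Pabs), centralSlice = 2)
  tt <- tissueTable()
  base <- computeSAR(f, m, tt, targetMass = 1e-5)
  sh <- shiftModel(m, c(2, 0, 0))   # one voxel in +x
  shifted <- computeSAR(f, sh, tt, targetMass = 1e-5, slice = refSlice(sh))
  rho <- tissueLookup(tt, "muscle", 297)$rho_kg_m3
  handBase <- mean(0.77 * c(4, 5, 6)^2 / rho)
  handShift <- mean(0.77 * c(5, 6, 7)^2 / rho)
  expect_equal(base@headAvg, handBase, tolerance = 1e-12)
  expect_equal(shifted@headAvg, handShift, tolerance = 1e-12)
})
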