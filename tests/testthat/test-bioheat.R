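# Closed-form validation of the explicit Pennes solver.

test_that("equilibrium states are fixed points; perfusion vanishes when T = T_blood", {
  tt <- customTable(w = 50)
  m <- uniformModel(n = 5)
  cfg <- thermalConfig(h = 0, variableCore = TRUE, recordEvery = 1)
  sys <- buildThermalSystem(m, tt, cfg)
  st <- initialState(sys, Tuniform = 37, Tblood = 37)
  st2 <- thermalStep(st, sys, dt = 1, n = 10)
  expect_equal(temperatureGrid(st2)[sys$solid], rep(37, sum(sys$solid)),
               tolerance = 1e-12)
  expect_equal(bloodTemperature(st2), 37, tolerance = 1e-12)
})

test_that("interface flux uses the harmonic-mean conductance (4-voxel rod)", {
  # rod along x filling the grid: domain-edge faces are adiabatic, so the
  # only fluxes are the three internal faces
  lab <- array(c(3L, 3L, 2L, 2L), c(4, 1, 1))  # muscle | muscle | fat | fat
  tt <- tissueTable()
  m <- voxelModel(lab, 2)
  cfg <- thermalConfig(h = 0, variableCore = FALSE, recordEvery = 1)
  sys <- buildThermalSystem(m, tt, cfg)
  st <- initialState(sys, 37)
  T0 <- c(40, 38, 36, 34)
  st@Tgrid[] <- T0
  dt <- 0.05
  st1 <- thermalStep(st, sys, dt = dt)
  km <- tissueLookup(tt, "muscle", 297); kf <- tissueLookup(tt, "fat", 297)
  dx2 <- (2e-3)^2
  kmm <- km$k_W_m_K                                  # muscle-muscle face
  kmf <- 2 * km$k_W_m_K * kf$k_W_m_K / (km$k_W_m_K + kf$k_W_m_K)
  kff <- kf$k_W_m_K
  qm <- km$qmet_W_kg; qf <- kf$qmet_W_kg
  rcm <- km$rho_kg_m3 * km$c_J_kg_K; rcf <- kf$rho_kg_m3 * kf$c_J_kg_K
  wm <- km$rho_kg_m3 * km$perfusion_ml_min_kg * 1050 * 1e-6 / 60 * 3617
  wf <- kf$rho_kg_m3 * kf$perfusion_ml_min_kg * 1050 * 1e-6 / 60 * 3617
  hand <- c(
    T0[1] + dt / rcm * (kmm * (T0[2] - T0[1]) / dx2 +
                          km$rho_kg_m3 * qm + wm * (37 - T0[1])),
    T0[2] + dt / rcm * (kmm * (T0[1] - T0[2]) / dx2 +
                          kmf * (T0[3] - T0[2]) / dx2 +
                          km$rho_kg_m3 * qm + wm * (37 - T0[2])),
    T0[3] + dt / rcf * (kmf * (T0[2] - T0[3]) / dx2 +
                          kff * (T0[4] - T0[3]) / dx2 +
                          kf$rho_kg_m3 * qf + wf * (37 - T0[3])),
    T0[4] + dt / rcf * (kff * (T0[3] - T0[4]) / dx2 +
                          kf$rho_kg_m3 * qf + wf * (37 - T0[4])))
  expect_equal(as.numeric(temperatureGrid(st1)), hand, tolerance = 1e-12)
})

test_that("uniform adiabatic heating follows dT/dt = SAR/c exactly", {
  ch <- 3500
  tt <- customTable(rho = 1000, ch = ch, w = 0, qmet = 0)
  m <- uniformModel(n = 6, rho = 1000)
  cfg <- thermalConfig(h = 0, variableCore = FALSE, recordEvery = 10)
  sys <- buildThermalSystem(m, tt, cfg)
  st <- initialState(sys, 37)
  S <- 2                                  # W/kg
  sar <- array(S, dim(voxelLabels(m)))
  out <- runExposure(st, sys, sar = sar, duration = 100, h = 0)
  Tend <- temperatureGrid(out$finalState)[sys$solid]
  expect_equal(unique(round(Tend, 12)), 37 + 100 * S / ch, tolerance = 1e-12)
})

test_that("perfused uniform medium reaches dT = rho SAR / (W_b c_b) steady state", {
  rho <- 1050; w <- 30; cB <- 3617
  tt <- customTable(rho = rho, w = w, qmet = 0)
  m <- uniformModel(n = 3, rho = rho)
  cfg <- thermalConfig(h = 0, variableCore = FALSE, rhoBlood = 1050,
                       cBlood = cB, recordEvery = 600)
  sys <- buildThermalSystem(m, tt, cfg)
  Wb <- rho * w * 1050 * 1e-6 / 60
  tau <- rho * 3500 / (Wb * cB)
  S <- 3
  st <- initialState(sys, 37)
  out <- runExposure(st, sys, sar = array(S, dim(voxelLabels(m))),
                     duration = ceiling(12 * tau), h = 0)
  dT <- temperatureGrid(out$finalState)[sys$solid] - 37
  expect_equal(unique(dT), rep(rho * S / (Wb * cB), length(unique(dT))),
               tolerance = 1e-4)
})

test_that("1-D slab with Robin surfaces matches the closed-form steady profile within 1%", {
  # column of tissue with one air voxel at each z end; lateral domain faces
  # are adiabatic, so the problem is exactly 1-D
  n <- 40; dx <- 1  # mm
  lab <- array(0L, c(1, 1, n + 2))
  lab[1, 1, 2:(n + 1)] <- 3L
  k <- 0.6; rho <- 1000; ch <- 3500; q <- 1  # W/kg metabolic source
  tt <- customTable(rho = rho, k = k, ch = ch, w = 0, qmet = q)
  m <- voxelModel(lab, dx, density = c("3" = rho))
  h <- 8; Tamb <- 22
  cfg <- thermalConfig(h = h, Tambient = Tamb, variableCore = FALSE,
                       recordEvery = 3600)
  sys <- buildThermalSystem(m, tt, cfg)
  st <- initialState(sys, 30)
  out <- runExposure(st, sys, duration = 60000)
  Tz <- temperatureGrid(out$finalState)[1, 1, 2:(n + 1)]
  L <- n * dx * 1e-3
  Q <- rho * q                                   # W/m^3
  zc <- (seq_len(n) - (n + 1) / 2) * dx * 1e-3   # z from slab centre
  analytic <- Tamb + Q * L / (2 * h) + Q / (2 * k) * ((L / 2)^2 - zc^2)
  scale <- max(analytic - Tamb)
  expect_lt(max(abs(Tz - analytic)) / scale, 0.01)
})

test_that("single-voxel + blood pool relaxes with the closed-form two-box rate", {
  rho <- 1000; ch <- 3600; w <- 400; cB <- 3617; rhoB <- 1050
  dxmm <- 10
  tt <- customTable(rho = rho, ch = ch, w = w, qmet = 0)
  lab <- array(3L, c(1, 1, 1))
  m <- voxelModel(lab, dxmm, density = c("3" = rho))
  Vb_mL <- 200
  cfg <- thermalConfig(h = 0, variableCore = TRUE, bloodVolume = Vb_mL,
                       rhoBlood = rhoB, cBlood = cB, recordEvery = 1)
  sys <- buildThermalSystem(m, tt, cfg)
  Wb <- rho * w * rhoB * 1e-6 / 60
  dV <- (dxmm * 1e-3)^3
  lam <- Wb * cB / (rho * ch) + Wb * cB * dV / (Vb_mL * 1e-6 * rhoB * cB)
  tau <- 1 / lam
  T0 <- 39; Tb0 <- 37
  st <- initialState(sys, T0, Tblood = Tb0)
  # equilibrium temperature from the conserved weighted mean
  Ct <- rho * ch * dV; Cb <- Vb_mL * 1e-6 * rhoB * cB
  Teq <- (Ct * T0 + Cb * Tb0) / (Ct + Cb)
  dt <- tau / 100
  for (tchk in c(0.5, 1, 2)) {
    nst <- round(tchk * tau / dt)
    stN <- thermalStep(st, sys, dt = dt, n = nst)
    expected <- Teq + (T0 - Teq) * exp(-lam * nst * dt)
    got <- as.numeric(temperatureGrid(stN)[1, 1, 1])
    expect_lt(abs(got - expected) / abs(expected), 0.001)
    expectedB <- Teq + (Tb0 - Teq) * exp(-lam * nst * dt)
    expect_lt(abs(bloodTemperature(stN) - expectedB) / abs(expectedB), 0.001)
  }
})

test_that("adiabatic energy balance holds with and without the blood pool", {
  tt <- adultTableZeroed(zeroPerfusion = TRUE, zeroMetabolism = TRUE)
  lab <- array(3L, c(8, 8, 8)); lab[3:6, 3:6, 3:6] <- 5L
  m <- voxelModel(lab, 4)
  cfg <- thermalConfig(h = 0, variableCore = FALSE, recordEvery = 300)
  sys <- buildThermalSystem(m, tt, cfg)
  st <- initialState(sys, 37)
  S <- 1.5
  sar <- array(S, dim(lab))
  out <- runExposure(st, sys, sar = sar, duration = 3600, h = 0)
  rho <- densityGrid(m)
  Pdep <- sum(rho * S) * voxelVolume(m)
  dE <- tail(out$series$energy_J, 1) - out$series$energy_J[1]
  expect_lt(abs(dE - Pdep * 3600) / (Pdep * 3600), 0.001)

  # blood pool active, no sources: total (tissue + pool) energy constant
  tt2 <- adultTableZeroed(zeroPerfusion = FALSE, zeroMetabolism = TRUE)
  cfg2 <- thermalConfig(h = 0, variableCore = TRUE, recordEvery = 300)
  sys2 <- buildThermalSystem(m, tt2, cfg2)
  st2 <- initialState(sys2, 39, Tblood = 36)
  out2 <- runExposure(st2, sys2, duration = 3600, h = 0)
  E <- out2$series$energy_J
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 0.001)
  # and the pool actually moved
  expect_gt(tail(out2$series$T_blood_C, 1), 36.01)
})

test_that("temperatures respect the maximum principle without sources", {
  tt <- adultTableZeroed()
  m <- sphereModel(20)
  cfg <- thermalConfig(h = 10, Tambient = 22, variableCore = FALSE,
                       recordEvery = 300)
  sys <- buildThermalSystem(m, tt, cfg)
  st <- initialState(sys, 37)
  out <- runExposure(st, sys, duration = 1800)
  Tv <- temperatureGrid(out$finalState)[sys$solid]
  expect_true(all(Tv <= 37 + 1e-9))
  expect_true(all(Tv >= 22 - 1e-9))
  expect_true(all(out$series$T_max_C <= 37 + 1e-9))
})

test_that("zero-duration equilibration returns the uniform state; full protocol cools the skin", {
  tt <- neonatalMetabolicScaling(tissueTable())
  m <- skinSphere(30)
  eq0 <- equilibrate(m, tt, duration = 0)
  expect_equal(unique(temperatureGrid(eq0$state)[eq0$system$solid]), 37)

  eq <- suppressMessages(equilibrate(m, tt, duration = 900))
  s <- tail(eq$series, 1)
  expect_lt(s$T_skin_mean_C, s$T_max_C)    # surface cools below the interior
  expect_lt(s$T_max_C, 37 + 1e-9)          # no heating without RF
})

test_that("perfusion ramp: unity at 37 C, maximum at 45 C, always 1 in neonate mode", {
  expect_equal(perfusionMultiplier(37, "skin", "adult"), 1)
  expect_equal(perfusionMultiplier(45, "skin", "adult"), 32)
  expect_equal(perfusionMultiplier(50, "skin", "adult"), 32)
  expect_equal(perfusionMultiplier(42, "brain", "adult"), 1 + (2 - 1) * 0.5)
  expect_equal(perfusionMultiplier(c(37, 42, 46), "muscle", "neonate"),
               c(1, 1, 1))
})

test_that("gross instability is detected and aborts with a diagnostic", {
  tt <- customTable(w = 0, qmet = 0)
  m <- uniformModel(n = 4)
  cfg <- thermalConfig(h = 0, variableCore = FALSE, recordEvery = 1)
  sys <- buildThermalSystem(m, tt, cfg)
  st <- initialState(sys, 37)
  st@Tgrid[2, 2, 2] <- 80                     # sharp spike
  bound <- dtBound(sys)
  expect_error(thermalStep(st, sys, dt = bound * 500, n = 50),
               "instability")
})
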