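# Pennes bioheat solver: system assembly, explicit time stepping,
# equilibration and exposure protocols.

#' Thermal solver configuration
#'
#' @param h surface heat-transfer coefficient (W m-2 K-1); default 11, the
#'   value giving an essentially stable insulated neonate.
#' @param Tambient ambient temperature (C); default 22, the scanner room.
#' @param dt time step in seconds, or NA for the automatic stability-bound
#'   choice.
#' @param duration simulated duration (s).
#' @param variableCore evolve the lumped blood-pool temperature.
#' @param tempDependentPerfusion enable the perfusion temperature ramp
#'   (adult mode; neonatal runs keep temperature-independent perfusion).
#' @param bloodVolume blood-pool volume (mL); 324 mL for a term neonate.
#' @param rhoBlood,cBlood blood density (kg/m3) and specific heat (J/kg/K).
#' @param recordEvery cadence of time-series records (s).
#' @return A \linkS4class{ThermalConfig}.
#' @export
thermalConfig <- function(h = 11, Tambient = 22, dt = NA_real_,
                          duration = 3600, variableCore = TRUE,
                          tempDependentPerfusion = FALSE, bloodVolume = 324,
                          rhoBlood = 1050, cBlood = 3617, recordEvery = 60) {
  new("ThermalConfig", h = h, Tambient = Tambient, dt = dt,
      duration = duration, variableCore = variableCore,
      tempDependentPerfusion = tempDependentPerfusion,
      bloodVolume = bloodVolume, rhoBlood = rhoBlood, cBlood = cBlood,
      recordEvery = recordEvery)
}

# Default maximum perfusion multipliers for the temperature ramp (adult
# mode).  The exact ramp parameters are configurable because published
# values vary; the ramp itself is 1 below 39 C, linear to the maximum at
# 45 C, constant above.
.defaultPerfusionMax <- c(skin = 32, muscle = 15, fat = 33, brain = 2)

#' Discretize the bioheat system on a voxel model
#'
#' Resolves per-voxel density, specific heat, thermal conductivity,
#' volumetric blood-perfusion coefficient W_b (kg blood m-3 s-1, from the
#' interface unit mL blood min-1 kg tissue-1 via
#' W_b = rho_tissue * w * rho_blood * 1e-6 / 60), metabolic rate and the
#' perfusion-ramp ceiling.  Every tissue label must have thermal properties;
#' the blanket layer carries wool conductivity with zero perfusion and
#' metabolism.
#'
#' @param model A \linkS4class{VoxelModel}.
#' @param table A \linkS4class{TissueTable}.
#' @param config A \linkS4class{ThermalConfig}.
#' @param perfusionMax named per-tissue maximum perfusion multipliers used
#'   when the temperature ramp is enabled.
#' @return A list of per-voxel arrays and scalars (class
#'   \code{"ThermalSystem"}).
#' @export
buildThermalSystem <- function(model, table, config,
                               perfusionMax = .defaultPerfusionMax) {
  lab <- model@labels
  d <- dim(lab)
  solid <- lab > 0L
  rho <- array(0, d); ch <- array(0, d); kc <- array(0, d)
  wb <- array(0, d); qmet <- array(0, d); mmax <- array(1, d)
  for (id in names(model@tissueNames)) {
    nm <- model@tissueNames[[id]]
    row <- table@props[table@props$tissue == nm, , drop = FALSE]
    if (!nrow(row))
      stop("missing thermal properties for tissue '", nm, "'")
    for (fld in c("rho_kg_m3", "k_W_m_K", "c_J_kg_K"))
      if (!is.finite(row[[fld]][1]) || row[[fld]][1] <= 0)
        stop("tissue '", nm, "' has invalid ", fld)
    sel <- lab == as.integer(id)
    rho[sel] <- row$rho_kg_m3[1]
    ch[sel] <- row$c_J_kg_K[1]
    kc[sel] <- row$k_W_m_K[1]
    # perfusion interface unit: mL blood / min / kg tissue
    wb[sel] <- row$rho_kg_m3[1] * row$perfusion_ml_min_kg[1] *
      config@rhoBlood * 1e-6 / 60
    qmet[sel] <- row$qmet_W_kg[1]
    if (config@tempDependentPerfusion && nm %in% names(perfusionMax))
      mmax[sel] <- perfusionMax[[nm]]
  }
  coreMask <- model@masks$core
  if (is.null(coreMask)) coreMask <- array(FALSE, d)
  skinMask <- model@masks$skin
  if (is.null(skinMask)) skinMask <- array(FALSE, d)
  structure(list(model = model, config = config, dims = d,
                 vox_m = model@voxelSize * 1e-3, solid = solid, rho = rho,
                 ch = ch, kc = kc, wb = wb, qmet = qmet, mmax = mmax,
                 coreMask = coreMask, skinMask = skinMask),
            class = "ThermalSystem")
}

#' Automatic stable time step
#'
#' Positivity bound: dt = 0.9 min over solid voxels of rho c divided by the
#' total per-volume conductance (faces plus perfusion exchange).
#'
#' @param system A ThermalSystem from \code{\link{buildThermalSystem}}.
#' @return dt in seconds.
#' @export
dtBound <- function(system) {
  cfg <- system$config
  cpp_dt_bound(as.integer(system$solid), system$rho, system$ch, system$kc,
               system$wb, system$mmax, as.integer(system$dims), system$vox_m,
               cfg@h, cfg@cBlood)
}

#' Create an initial thermal state
#'
#' @param system A ThermalSystem.
#' @param Tuniform uniform tissue temperature (C).
#' @param Tblood blood-pool temperature (C).
#' @return A \linkS4class{ThermalState}.
#' @export
initialState <- function(system, Tuniform = 37, Tblood = Tuniform) {
  Tg <- array(NA_real_, system$dims)
  Tg[system$solid] <- Tuniform
  new("ThermalState", Tgrid = Tg, Tblood = Tblood, time = 0)
}

# Shared driver around the compiled kernel.
.runKernel <- function(system, state, duration, sar = NULL, dt = NA,
                       h = NULL, variableCore = NULL, recordEvery = NULL) {
  cfg <- system$config
  if (is.null(h)) h <- cfg@h
  if (is.null(variableCore)) variableCore <- cfg@variableCore
  if (is.null(recordEvery)) recordEvery <- cfg@recordEvery
  if (is.na(dt)) dt <- if (is.na(cfg@dt)) NA else cfg@dt
  sys2 <- system
  sys2$config@h <- h
  if (is.na(dt)) dt <- dtBound(sys2)
  if (duration <= 0) {
    return(list(state = state,
                series = data.frame(t_s = state@time,
                                    T_core_C = NA_real_, T_max_C = NA_real_,
                                    T_blood_C = state@Tblood,
                                    T_skin_mean_C = NA_real_,
                                    energy_J = NA_real_)))
  }
  nsteps <- as.integer(ceiling(duration / dt))
  dt <- duration / nsteps
  recEvery <- max(1L, as.integer(round(recordEvery / dt)))
  if (is.null(sar)) sar <- array(0, system$dims)
  T0 <- state@Tgrid
  T0[is.na(T0)] <- 0
  res <- cpp_bioheat_run(as.integer(system$solid), system$rho, system$ch,
                         system$kc, system$wb, system$qmet, sar, system$mmax,
                         as.integer(cfg@tempDependentPerfusion),
                         as.integer(system$dims), system$vox_m, h,
                         cfg@Tambient, as.numeric(T0), state@Tblood,
                         as.integer(variableCore),
                         cfg@bloodVolume * 1e-6, cfg@rhoBlood, cfg@cBlood,
                         dt, nsteps, recEvery,
                         as.integer(system$coreMask),
                         as.integer(system$skinMask))
  Tg <- array(res$T, system$dims)
  series <- as.data.frame(res$series)
  names(series) <- c("t_s", "T_core_C", "T_max_C", "T_blood_C",
                     "T_skin_mean_C", "energy_J")
  series$t_s <- series$t_s + state@time
  list(state = new("ThermalState", Tgrid = Tg, Tblood = res$Tblood,
                   time = state@time + res$t),
       series = series, dt = dt)
}

#' Advance a thermal state by one or more explicit steps
#'
#' @param state A \linkS4class{ThermalState}.
#' @param system A ThermalSystem.
#' @param dt step size (s); must respect the stability bound.
#' @param n number of steps.
#' @param sar optional SAR source grid (W/kg).
#' @return A \linkS4class{ThermalState}.
#' @export
thermalStep <- function(state, system, dt, n = 1L, sar = NULL) {
  .runKernel(system, state, duration = dt * n, sar = sar, dt = dt,
             recordEvery = dt * n)$state
}

#' Equilibration protocol
#'
#' Establishes a physically realistic starting temperature distribution:
#' uniform 37 C in all tissues, ambient 22 C, h = 8 W m-2 K-1, fixed blood
#' temperature, no RF, run for 60 minutes.  Starting a variable-core run
#' from the unphysical uniform state gives unreliable results, so every
#' exposure simulation starts from this state.
#'
#' @param model A \linkS4class{VoxelModel}.
#' @param table A \linkS4class{TissueTable}.
#' @param config A \linkS4class{ThermalConfig} (its h/variableCore are
#'   overridden by the protocol values during equilibration).
#' @param duration equilibration time (s), default 3600.
#' @param hEquil protocol heat-transfer coefficient, default 8.
#' @param Tstart uniform starting temperature, default 37.
#' @return list(state, series, system): the equilibrated
#'   \linkS4class{ThermalState}, its time series and the reusable system.
#' @export
equilibrate <- function(model, table, config = thermalConfig(),
                        duration = 3600, hEquil = 8, Tstart = 37) {
  system <- buildThermalSystem(model, table, config)
  st0 <- initialState(system, Tuniform = Tstart, Tblood = Tstart)
  if (duration <= 0) return(list(state = st0, series = NULL, system = system))
  out <- .runKernel(system, st0, duration, sar = NULL, h = hEquil,
                    variableCore = FALSE)
  tail1 <- out$series[nrow(out$series), ]
  message(sprintf("equilibrated %d s: max T %.2f C, mean skin T %.2f C",
                  as.integer(duration), tail1$T_max_C, tail1$T_skin_mean_C))
  list(state = out$state, series = out$series, system = system)
}

#' RF exposure protocol
#'
#' Runs the bioheat solver from an equilibrated state with an RF SAR source
#' (optionally scaled by \code{driveScale}), h = 11 by default and, for
#' neonatal runs, a variable blood-pool core temperature.  Emits a time
#' series of core (mass-weighted mean over the core mask), maximum, blood
#' and mean-skin temperatures.
#'
#' @param state0 equilibrated \linkS4class{ThermalState}.
#' @param system ThermalSystem from \code{\link{equilibrate}} or
#'   \code{\link{buildThermalSystem}}.
#' @param sar SAR grid (W/kg) at the reference drive.
#' @param driveScale multiplier applied to the SAR grid (e.g. the allowed
#'   power from \code{\link{powerForLimit}} when \code{sar} is per watt).
#' @param duration exposure duration (s).
#' @param h heat-transfer coefficient; NULL uses the system config.
#' @return list(series, finalState).
#' @export
runExposure <- function(state0, system, sar = NULL, driveScale = 1,
                        duration = 3600, h = NULL) {
  if (!is.null(sar)) sar <- sar * driveScale
  out <- .runKernel(system, state0, duration, sar = sar, h = h)
  list(series = out$series, finalState = out$state, dt = out$dt)
}

#' Temperature-dependent perfusion multiplier
#'
#' Piecewise-linear ramp: 1 below 39 C, rising linearly to the per-tissue
#' maximum at 45 C, constant above.  In neonatal mode the multiplier is
#' always 1 (temperature-independent perfusion: neonatal thermoregulation
#' is underdeveloped, and suppressing the ramp is conservative).
#'
#' @param T_local local temperature(s), C.
#' @param tissue tissue name.
#' @param mode \code{"neonate"} or \code{"adult"}.
#' @param perfusionMax named per-tissue maxima.
#' @return Multiplier(s) in [1, max].
#' @export
perfusionMultiplier <- function(T_local, tissue, mode = c("neonate", "adult"),
                                perfusionMax = .defaultPerfusionMax) {
  mode <- match.arg(mode)
  if (mode == "neonate") return(rep(1, length(T_local)))
  m <- perfusionMax[[tissue]]
  if (is.null(m)) m <- 1
  pmin(pmax(1 + (m - 1) * (T_local - 39) / 6, 1), m)
}
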