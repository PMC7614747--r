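# Shared fixtures, built in code and cached for the duration of the run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Full-grid homogeneous block (no air): adiabatic domain for conservation
# and closed-form heating tests.
blockModel <- function(n = 6, voxel = 2, tissue = "muscle") {
  lab <- array(.labelFor(tissue), rep(n, 3))
  voxelModel(lab, voxel)
}

.labelFor <- function(tissue) {
  map <- c(skin = 1L, fat = 2L, muscle = 3L, bone = 4L, brain = 5L, csf = 6L,
           blood = 7L, heart = 8L, lung = 9L, liver = 10L, cartilage = 11L,
           connective = 12L, eye = 13L, blanket_wool = 99L)
  map[[tissue]]
}

# One-tissue table with controllable properties.
customTable <- function(tissue = "muscle", eps = 58.2, sigma = 0.77,
                        rho = 1000, k = 0.5, ch = 3500, w = 0, qmet = 0,
                        freq = 297) {
  new("TissueTable",
      props = data.frame(tissue = tissue, freq_MHz = freq, eps_r = eps,
                         sigma_S_per_m = sigma, rho_kg_m3 = rho, k_W_m_K = k,
                         c_J_kg_K = ch, perfusion_ml_min_kg = w,
                         qmet_W_kg = qmet, source = "test",
                         stringsAsFactors = FALSE))
}

# Packaged adult table with perfusion and/or metabolism switched off.
adultTableZeroed <- function(zeroPerfusion = TRUE, zeroMetabolism = TRUE) {
  tt <- tissueTable()
  if (zeroPerfusion) tt@props$perfusion_ml_min_kg <- 0
  if (zeroMetabolism) tt@props$qmet_W_kg <- 0
  tt
}

# A model with one uniform tissue whose density we control (via a custom
# tissue table used consistently by the caller).
uniformModel <- function(n = 6, voxel = 2, rho = 1000, tissue = "muscle") {
  lab <- array(.labelFor(tissue), rep(n, 3))
  voxelModel(lab, voxel,
             density = setNames(rho, as.character(.labelFor(tissue))))
}

# Small homogeneous-sphere phantom for SAR and solver tests.
sphereModel <- function(radius = 30, voxel = 2) {
  cached(sprintf("sphere_%g_%g", radius, voxel),
         generatePhantom(spherePhantomSpec(radius, voxel = voxel)))
}

# Sphere with a skin shell (needed wherever a blanket is added).
skinSphere <- function(radius = 30, voxel = 2) {
  cached(sprintf("skinsphere_%g_%g", radius, voxel),
         generatePhantom(spherePhantomSpec(radius, voxel = voxel,
                                           layers = c(skin = 2, muscle = Inf))))
}

# The full default neonate phantom (expensive: built once per run).
neonateModel <- function() {
  cached("neonate", generatePhantom(neonatePhantomSpec()))
}

neonateTables <- function() {
  cached("tables", {
    adult <- tissueTable()
    list(adult = adult, neonatal = applyAgeScaling(adult, scalingTable()))
  })
}

# Independent exhaustive psSAR10g oracle via 3-D summed-area tables: every
# centre, every fractional cube size, O(1) box sums.  Deliberately a
# different algorithm (and language) from the compiled growth kernel.
oracleSAR10g <- function(sar, massGrid, tissue, targetMass) {
  d <- dim(massGrid)
  cums <- function(a) {
    a <- apply(a, c(2, 3), cumsum)
    a <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3))
    aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))
  }
  CM <- array(0, d + 1L); CM[-1, -1, -1] <- cums(massGrid)
  CP <- array(0, d + 1L); CP[-1, -1, -1] <- cums(sar * massGrid)
  boxSum <- function(C, lo, hi) {
    C[hi[1] + 1, hi[2] + 1, hi[3] + 1] -
      C[lo[1], hi[2] + 1, hi[3] + 1] -
      C[hi[1] + 1, lo[2], hi[3] + 1] -
      C[hi[1] + 1, hi[2] + 1, lo[3]] +
      C[lo[1], lo[2], hi[3] + 1] +
      C[lo[1], hi[2] + 1, lo[3]] +
      C[hi[1] + 1, lo[2], lo[3]] -
      C[lo[1], lo[2], lo[3]]
  }
  best <- -Inf; bestIdx <- NA_integer_
  sar10g <- array(NA_real_, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!tissue[i, j, k]) next
    rmax <- min(i - 1, j - 1, k - 1, d[1] - i, d[2] - j, d[3] - k)
    mPrev <- 0; pPrev <- 0; val <- NA_real_
    for (r in 0:rmax) {
      lo <- c(i, j, k) - r; hi <- c(i, j, k) + r
      m <- boxSum(CM, lo, hi)
      p <- boxSum(CP, lo, hi)
      if (m >= targetMass) {
        f <- if (m > mPrev) (targetMass - mPrev) / (m - mPrev) else 1
        val <- (pPrev + f * (p - pPrev)) / targetMass
        break
      }
      mPrev <- m; pPrev <- p
    }
    if (!is.na(val)) {
      sar10g[i, j, k] <- val
      idx <- i + d[1] * ((j - 1) + d[2] * (k - 1))
      if (val > best) { best <- val; bestIdx <- idx }
    }
  }
  list(sar10g = sar10g, psSAR10g = best, peak_index = bestIdx)
}

# Random toy model + SAR grid for oracle comparisons.
randomSARCase <- function(seed, nmax = 16) {
  set.seed(seed)
  d <- sample(12:nmax, 3, replace = TRUE)
  tissueFrac <- runif(1, 0.5, 0.9)
  lab <- array(ifelse(runif(prod(d)) < tissueFrac,
                      sample(1:4, prod(d), replace = TRUE), 0L), d)
  storage.mode(lab) <- "integer"
  model <- voxelModel(lab, 3)
  sar <- array(runif(prod(d), 0, 10), d)
  sar[lab == 0L] <- 0
  list(model = model, sar = sar)
}
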