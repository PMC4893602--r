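# MSD estimation, model fitting, Bayesian classification, summaries,
# viscosity

test_that("MSD estimator matches hand computation and brute force", {
  tr <- data.frame(frame = 0:2, t_s = 0:2, x_um = c(0, 1, 2), y_um = 0)
  m <- computeMsd(tr, maxLagFraction = 1)
  expect_equal(m$msd_um2, c(1, 4))
  expect_equal(m$n_pairs, c(2, 1))
  # stationary track -> all zeros
  st <- data.frame(frame = 0:9, t_s = 0:9, x_um = 1, y_um = 2)
  expect_equal(computeMsd(st)$msd_um2, rep(0, 2))
  # vectorized estimator equals the naive double loop on random tracks
  for (s in 1:5) {
    set.seed(s)
    n <- sample(20:60, 1)
    tr <- data.frame(frame = 0:(n - 1), t_s = (0:(n - 1)) * 0.1,
                     x_um = cumsum(rnorm(n)), y_um = cumsum(rnorm(n)))
    m <- computeMsd(tr, maxLagFraction = 0.5)
    expect_equal(m$msd_um2,
                 msdBruteForce(tr$x_um, tr$y_um, 0.1, nrow(m)))
  }
  # non-uniform sampling is rejected
  bad <- data.frame(frame = c(0, 1, 3), t_s = c(0, 1, 3), x_um = 0, y_um = 0)
  expect_error(computeMsd(bad), "non-uniform")
})

test_that("model fits recover exact curves", {
  tau <- seq(0.1, 3, by = 0.1)
  npair <- rev(seq_along(tau)) + 5
  # exact line msd = 4*0.5*tau -> D = 0.5, residual ~ 0
  cD <- data.frame(tau_s = tau, msd_um2 = 4 * 0.5 * tau, n_pairs = npair)
  fD <- fitMotionModel(cD, "D")
  expect_equal(fD$params$D, 0.5, tolerance = 1e-10)
  expect_lt(fD$rss, 1e-20)
  # exact power law alpha = 0.6 recovered within 1e-6
  cA <- data.frame(tau_s = tau, msd_um2 = 4 * 0.02 * tau^0.6 + 0.001,
                   n_pairs = npair)
  fA <- fitMotionModel(cA, "DA")
  expect_lt(abs(fA$params$alpha - 0.6), 1e-6)
  expect_equal(fA$params$Dalpha, 0.02, tolerance = 1e-5)
  # constant curve: N fits exactly, D collapses to D ~ 0
  cN <- data.frame(tau_s = tau, msd_um2 = 0.012, n_pairs = npair)
  fN <- fitMotionModel(cN, "N")
  expect_equal(fN$params$c, 0.012)
  expect_lt(fN$rss, 1e-25)
  expect_lt(fitMotionModel(cN, "D")$params$D, 1e-10)
  # confined form round-trips
  cR <- data.frame(tau_s = tau,
                   msd_um2 = 0.09 * (1 - exp(-4 * 0.05 * tau / 0.09)) + 0.001,
                   n_pairs = npair)
  fR <- fitMotionModel(cR, "DR")
  expect_equal(fR$params$L^2, 0.09, tolerance = 1e-4)
  expect_equal(fR$params$D, 0.05, tolerance = 1e-4)
  expect_error(fitMotionModel(cD[1:3, ], "D"), "5 usable lags")
})

test_that("posteriors are a proper distribution and select the truth", {
  spec <- frameSpec(nFrames = 1980)
  pars <- list(N = motionParams("N", c = 0.001),
               D = motionParams("D", D = 0.1),
               DR = motionParams("DR", D = 0.1, L = 0.5),
               DA = motionParams("DA", Dalpha = 0.01, alpha = 0.5))
  for (m in names(pars)) {
    hits <- 0
    for (s in 1:5) {
      tr <- simulateTrajectory(pars[[m]], spec, seed = 500 + 10 * s)
      cl <- classifyTrajectory(computeMsd(tr))
      expect_equal(sum(cl$posteriors), 1, tolerance = 1e-12)
      expect_true(all(cl$posteriors >= 0 & cl$posteriors <= 1))
      hits <- hits + (cl$selected == m)
    }
    expect_gte(hits, 4)
  }
})

test_that("ties favour the simpler model and DA filtering subsets correctly", {
  # a noiseless constant curve is fit exactly by every model: N wins
  cN <- data.frame(tau_s = seq(0.1, 2, by = 0.1), msd_um2 = 0.01,
                   n_pairs = 20:1 + 5)
  expect_equal(classifyTrajectory(cN)$selected, "N")
  # filterDa: empty input, subset property, threshold respected
  empty <- data.frame(bead_id = integer(), p_N = numeric(), p_D = numeric(),
                      p_DR = numeric(), p_DA = numeric(),
                      selected = character())
  expect_equal(nrow(filterDa(empty)$retained), 0)
  post <- data.frame(bead_id = 1:4, p_N = c(0.9, 0, 0, 0.2),
                     p_D = c(0.1, 0.3, 0, 0.2), p_DR = c(0, 0.7, 0.1, 0.2),
                     p_DA = c(0, 0, 0.9, 0.4),
                     selected = c("N", "DR", "DA", "DA"))
  out <- filterDa(post, threshold = 0.5)
  expect_equal(out$retained$bead_id, 3)
  expect_true(all(out$retained$bead_id %in% post$bead_id))
  expect_equal(out$modelFrequency$n, c(1, 0, 1, 2))
  expect_error(filterDa(post, threshold = 1.2), "threshold")
})

test_that("tau-reference summaries report median MSD and RMS in nm", {
  curve <- data.frame(bead_id = 1, tau_s = c(0.5, 1, 1.5),
                      msd_um2 = c(0.001, 0.0025, 0.004), n_pairs = c(9, 8, 7))
  s <- summarizeAtTau(curve, tauRef = 1)
  expect_equal(s$median_msd_um2, 0.0025)
  expect_equal(s$median_rms_nm, 50)        # sqrt(2500 nm^2)
  # identical curves -> median equals that value
  many <- do.call(rbind, lapply(1:5, function(b)
    transform(curve, bead_id = b)))
  expect_equal(summarizeAtTau(many, 1)$median_msd_um2, 0.0025)
  expect_equal(summarizeAtTau(many, 1)$n_beads, 5)
  expect_error(summarizeAtTau(curve, tauRef = 9), "maximum lag")
  # MSD ratio 1.69 -> RMS ratio 1.30 between two populations
  a <- transform(curve, condition = "A")
  b <- transform(curve, msd_um2 = msd_um2 * 1.69, condition = "B",
                 bead_id = 2)
  s2 <- summarizeAtTau(rbind(a, b), 1, by = "condition")
  expect_equal(s2$median_rms_nm[s2$group == "B"] /
                 s2$median_rms_nm[s2$group == "A"], 1.30, tolerance = 0.005)
})

test_that("Stokes-Einstein viscosity arithmetic and proportionality", {
  # D = 2.33 um^2/s, r = 0.1 um, T = 296 K -> ~0.93 mPa s
  curve <- data.frame(bead_id = 1, tau_s = seq(0.1, 1, by = 0.1),
                      msd_um2 = 4 * 2.33 * seq(0.1, 1, by = 0.1),
                      n_pairs = 10:1 + 20)
  v <- viscosityFromEnsemble(curve, radius = 0.1, temperature = 296)
  expect_equal(v$D_um2_s, 2.33, tolerance = 1e-10)
  expect_equal(v$viscosity_mPas, 0.9306, tolerance = 1e-3)
  # doubling the viscosity halves the simulated diffusion coefficient
  spec <- frameSpec(nFrames = 500)
  D1 <- 2; D2 <- 1   # D ~ 1/eta
  est <- vapply(c(D1, D2), function(D) {
    tt <- simulateTrajectories(motionParams("D", D = D, locNoiseSd = 0),
                               spec, 100, seed = round(100 * D))
    viscosityFromEnsemble(computeMsdAll(tt, maxLagFraction = 0.05),
                          radius = 0.1)$viscosity_mPas
  }, 0)
  expect_equal(est[2] / est[1], 2, tolerance = 0.1)
  # a strongly non-linear ensemble MSD warns
  curved <- data.frame(bead_id = 1, tau_s = seq(0.1, 1, by = 0.1),
                       msd_um2 = seq(0.1, 1, by = 0.1)^0.3,
                       n_pairs = 10:1 + 20)
  expect_warning(viscosityFromEnsemble(curved, radius = 0.1), "linear")
})
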