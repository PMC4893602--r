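# generators: motion models, video rendering, focus stacks, force
# curves, plates

test_that("invalid motion parameters are rejected", {
  expect_error(motionParams("DA", Dalpha = 0.01, alpha = 1.3), "alpha")
  expect_error(motionParams("DA", Dalpha = -1, alpha = 0.5), "Dalpha")
  expect_error(motionParams("D", D = -0.1), "D must")
  expect_error(motionParams("DR", D = 0.1, L = 0), "L must")
  expect_error(motionParams("N", c = -1), "c must")
})

test_that("model N with zero noise is a fixed point", {
  tr <- simulateTrajectory(motionParams("N", c = 0, locNoiseSd = 0),
                           smallSpec(), seed = 1)
  expect_equal(length(unique(tr$x_um)), 1)
  expect_equal(length(unique(tr$y_um)), 1)
  expect_equal(nrow(tr), 50)
})

test_that("ensemble MSDs match their closed forms", {
  spec <- smallSpec(nFrames = 300)
  # N: constant 4*locNoiseSd^2 + c
  tn <- simulateTrajectories(motionParams("N", c = 0.002, locNoiseSd = 0.02),
                             spec, 200, seed = 11)
  mn <- computeMsdAll(tn)
  lvl <- mean(mn$msd_um2)
  expect_lt(abs(lvl - (0.002 + 4 * 0.02^2)) / (0.002 + 4 * 0.02^2), 0.05)
  # D: 4 D tau, slope within 5% at 200 trajectories
  td <- simulateTrajectories(motionParams("D", D = 2.33, locNoiseSd = 0),
                             spec, 200, seed = 12)
  md <- computeMsdAll(td)
  agg <- aggregate(msd_um2 ~ tau_s, md, mean)
  slope <- coef(lm(msd_um2 ~ tau_s + 0, agg))[[1]]
  expect_lt(abs(slope - 4 * 2.33) / (4 * 2.33), 0.05)
  # DA: log-log slope = alpha +/- 0.05
  ta <- simulateTrajectories(motionParams("DA", Dalpha = 0.01, alpha = 0.5,
                                          locNoiseSd = 0), spec, 200, seed = 13)
  ma <- computeMsdAll(ta)
  agg <- aggregate(msd_um2 ~ tau_s, ma, mean)
  llslope <- coef(lm(log(msd_um2) ~ log(tau_s), agg))[[2]]
  expect_lt(abs(llslope - 0.5), 0.05)
})

test_that("fBm increments reproduce the exact fGn covariance", {
  # independent oracle: the analytic autocovariance of fractional
  # Gaussian noise, gamma(k) = Dalpha*dt^a*(|k+1|^a - 2|k|^a + |k-1|^a)
  alpha <- 0.5; Dalpha <- 0.02; dt <- 0.2; nInc <- 6
  spec <- frameSpec(width = 8, height = 8, dt = dt, nFrames = nInc + 1)
  tt <- simulateTrajectories(motionParams("DA", Dalpha = Dalpha, alpha = alpha,
                                          locNoiseSd = 0), spec, 4000, seed = 3)
  incs <- do.call(rbind, lapply(split(tt$x_um, tt$bead_id), diff))
  gammaHat <- vapply(0:(nInc - 1), function(k)
    mean(incs[, seq_len(nInc - k)] * incs[, seq_len(nInc - k) + k]), 0)
  k <- 0:(nInc - 1)
  gammaTrue <- Dalpha * dt^alpha * (abs(k + 1)^alpha - 2 * abs(k)^alpha +
                                      abs(k - 1)^alpha)
  expect_equal(gammaHat, gammaTrue, tolerance = 0.05)
})

test_that("confined-motion MSD plateaus independently of D", {
  spec <- smallSpec(nFrames = 400)
  plateau <- vapply(c(0.2, 1), function(D) {
    tt <- simulateTrajectories(motionParams("DR", D = D, L = 0.5,
                                            locNoiseSd = 0),
                               spec, 150, seed = 100 + round(10 * D))
    m <- computeMsdAll(tt, maxLagFraction = 0.25)
    tail(aggregate(msd_um2 ~ tau_s, m, mean)$msd_um2, 1)
  }, 0)
  # square corral of side L: stationary MSD plateau = L^2/3
  expect_equal(plateau[1], 0.5^2 / 3, tolerance = 0.15)
  expect_equal(plateau[2], plateau[1], tolerance = 0.15)
})

test_that("seeded generation is bit-reproducible", {
  p <- motionParams("DA", Dalpha = 0.01, alpha = 0.5)
  expect_identical(simulateTrajectory(p, smallSpec(), seed = 7),
                   simulateTrajectory(p, smallSpec(), seed = 7))
  tr <- simulateTrajectory(motionParams("D", D = 0.05), smallSpec(), seed = 8)
  expect_identical(videoData(renderVideo(tr, smallSpec(), seed = 9)),
                   videoData(renderVideo(tr, smallSpec(), seed = 9)))
})

test_that("rendering: empty field, constant flux, sub-pixel accuracy", {
  spec <- smallSpec(nFrames = 4)
  # zero beads: frames are background + noise only
  v0 <- renderVideo(data.frame(bead_id = integer(), frame = integer(),
                               t_s = numeric(), x_um = numeric(),
                               y_um = numeric()), spec, seed = 2)
  expect_equal(mean(videoData(v0)), spec@backgroundLevel, tolerance = 0.05)
  expect_lt(max(videoData(v0)), spec@backgroundLevel + 6 * spec@readNoiseSd)
  # stationary bead at a sub-pixel position, zero noise
  specq <- smallSpec(nFrames = 4, readNoiseSd = 0)
  tr <- data.frame(bead_id = 1, frame = 0:3, t_s = (0:3) / 33,
                   x_um = 31.37 * specq@scale, y_um = 29.81 * specq@scale)
  vq <- renderVideo(tr, specq, seed = 1)
  sp <- detectSpots(vq[1], noiseSd = 1)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$x - 31.37), 0.05)
  expect_lt(abs(sp$y - 29.81), 0.05)
  # above-background flux constant across frames (no photobleaching)
  flux <- vapply(1:4, function(f) sum(vq[f] - specq@backgroundLevel), 0)
  expect_equal(max(flux) - min(flux), 0)
  # out-of-field bead warns
  trOut <- data.frame(bead_id = 1, frame = 0:3, t_s = (0:3) / 33,
                      x_um = -3, y_um = 5)
  expect_warning(renderVideo(trOut, specq), "outside")
})

test_that("focus stacks peak at the focal plane", {
  spec <- smallSpec(nFrames = 2, readNoiseSd = 0)
  zg <- seq(-7, 7, by = 1)
  st <- renderFocusStack(cbind(32, 32), zg, spec, zFocus = 0)
  peaks <- vapply(seq_along(zg), function(i) max(st[i]), 0)
  expect_equal(which.max(peaks), which(zg == 0))
  # symmetric grid about the focus gives a symmetric peak profile
  expect_equal(peaks, rev(peaks), tolerance = 0.02)
  # peak intensity decreases monotonically with |z - zFocus|
  expect_true(all(diff(peaks[zg >= 0]) <= 0))
  expect_true(all(diff(peaks[zg <= 0]) >= 0))
  expect_error(renderFocusStack(cbind(32, 32), numeric(0), spec), "zGrid")
})

test_that("force-curve generator follows the Hertz model", {
  # direct evaluation of the spherical Hertz formula
  expect_equal(hertzForce(1, 500, 2.5, 0.5), 1.4055, tolerance = 1e-4)
  expect_equal(hertzForce(0, 500, 2.5, 0.5), 0)
  fc <- simulateForceCurve(E = 500, contactZ = 1, noiseSd = 0, seed = 1)
  # pre-contact force is exactly baseline
  pre <- fc@deflection[fc@zPiezo < 1]
  expect_equal(max(abs(pre)), 0)
  # curve terminates at the first sample reaching the trigger
  expect_gte(fc@k * fc@deflection[length(fc@deflection)], fc@trigger)
  expect_lt(fc@k * fc@deflection[length(fc@deflection) - 1], fc@trigger)
  # implicit solution satisfies F = hertz(piezo - contact - deflection)
  i <- length(fc@zPiezo)
  deltaEnd <- (fc@zPiezo[i] - 1) - fc@deflection[i] / 1000
  expect_equal(fc@k * fc@deflection[i], hertzForce(deltaEnd, 500, 2.5, 0.5),
               tolerance = 1e-6)
  # noisy baseline averages to zero
  fcn <- simulateForceCurve(E = 500, contactZ = 1, noiseSd = 0.02, seed = 2)
  expect_lt(abs(mean(fcn@deflection[fcn@zPiezo < 1]) * fcn@k), 0.005)
  expect_error(simulateForceCurve(E = 500, contactZ = 1, zMax = 0.5,
                                  noiseSd = 0), "unreachable")
})

test_that("plate simulation tags provenance and draws Poisson bead counts", {
  lay <- balancedPlateLayout(c("A", "B"), nStrata = 4, fovsPerWell = 3)
  pars <- list(A = motionParams("D", D = 0.1),
               B = motionParams("DA", Dalpha = 0.01, alpha = 0.5))
  spec <- smallSpec(nFrames = 10)
  pd <- simulatePlate(lay, pars, spec, beadsPerFov = 3, seed = 5)
  expect_true(all(c("well", "fov", "condition", "stratum") %in% names(pd)))
  # every (condition, stratum) cell of a balanced layout is populated
  cells <- unique(pd[c("condition", "stratum")])
  expect_equal(nrow(cells), 8)
  # mean bead count ~ Poisson(3) per FOV over 24 FOV
  nb <- length(unique(pd$bead_id))
  nFov <- length(unique(paste(pd$well, pd$fov)))
  expect_lt(abs(nb - 3 * 8 * 3) / (3 * 8 * 3), 0.35)
  expect_error(simulatePlate(lay, pars["A"], spec), "no parameters")
})
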