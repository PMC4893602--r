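# AFM force-curve analysis

test_that("force and indentation arithmetic", {
  # k = 0.02 N/m, deflection 50 nm -> 1 nN; piezo 1.05 um - 0.05 um -> 1 um
  fc <- new("ForceCurve", zPiezo = c(0, 0.5, 1.05), deflection = c(0, 0, 50),
            k = 0.02, location = "on_nucleus", trigger = 1, meta = list())
  fi <- toForceIndentation(fc, contactIndex = 1, baseline = c(0, 0))
  expect_equal(fi$force_nN[3], 1)
  expect_equal(fi$indentation_um[3], 1.05 - 0.05)
  expect_equal(fi$force_nN[1], 0)
  sat <- new("ForceCurve", zPiezo = c(0, 1), deflection = c(0, 4e4),
             k = 0.02, location = "on_nucleus", trigger = 1, meta = list())
  expect_error(toForceIndentation(sat, 1), "saturated")
})

test_that("Hertz fit is exact on noiseless data and scale-consistent", {
  delta <- seq(0, 1, by = 0.01)
  f <- hertzForce(delta, 500, 2.5, 0.5)
  fit <- fitHertz(delta, f, R = 2.5, nu = 0.5)
  expect_lt(abs(fit$E - 500) / 500, 1e-6)
  expect_equal(fit$compliance, 2.0, tolerance = 1e-6)   # 500 Pa -> 2 kPa^-1
  fit250 <- fitHertz(delta, f / 2, R = 2.5, nu = 0.5)
  expect_equal(fit250$compliance, 4.0, tolerance = 1e-6) # 250 Pa -> 4 kPa^-1
  # doubling all forces doubles E exactly
  expect_equal(fitHertz(delta, 2 * f, R = 2.5, nu = 0.5)$E, 2 * fit$E)
  expect_error(fitHertz(rep(0, 30), rep(0, 30), R = 2.5), "degenerate")
})

test_that("contact point is found exactly on noiseless curves", {
  fc <- simulateForceCurve(E = 500, contactZ = 1, noiseSd = 0, seed = 1)
  truthIdx <- max(which(fc@zPiezo <= 1))
  hf <- findContactPoint(fc)
  expect_lte(abs(hf@contactIndex - truthIdx), 1)
  expect_equal(hf@E, 500, tolerance = 1e-6)
  expect_equal(hf@compliance, 2.0, tolerance = 1e-6)
})

test_that("contact search equals an exhaustive brute-force oracle", {
  fc <- simulateForceCurve(E = 400, contactZ = 0.4, noiseSd = 0.02, seed = 9,
                           zMax = 1.6, dz = 0.004)
  hf <- findContactPoint(fc, minSamples = 20)
  # naive independent scan over every candidate index
  z <- fc@zPiezo; d <- fc@deflection; n <- length(z)
  best <- NULL; bestRms <- Inf
  for (j in 21:(n - 19)) {
    pre <- lm(d[1:(j - 1)] ~ z[1:(j - 1)])
    base <- coef(pre)
    dc <- d - (base[1] + base[2] * z)
    force <- fc@k * dc[j:n]
    indent <- (z[j:n] - z[j]) - dc[j:n] / 1000
    keep <- indent >= 0
    x <- (4 / 3) * sqrt(2.5) * indent[keep]^1.5 * 1e-3 / (1 - 0.25)
    E <- sum(force[keep] * x) / sum(x^2)
    if (!is.finite(E) || E <= 0) next
    ss <- sum(pre$residuals^2) * fc@k^2 + sum((force[keep] - E * x)^2)
    rms <- sqrt(ss / n)
    if (rms < bestRms) { bestRms <- rms; best <- j }
  }
  expect_equal(hf@contactIndex, best)
  expect_equal(hf@rmsError, bestRms, tolerance = 1e-8)
})

test_that("degenerate curves raise no-contact errors", {
  set.seed(6)
  flat <- new("ForceCurve", zPiezo = seq(0, 2, by = 0.002),
              deflection = rnorm(1001, 0, 1), k = 0.02,
              location = "on_nucleus", trigger = 1, meta = list())
  expect_error(findContactPoint(flat), "no contact")
  short <- new("ForceCurve", zPiezo = seq(0, 0.03, by = 0.002),
               deflection = rnorm(16, 0, 1), k = 0.02,
               location = "on_nucleus", trigger = 1, meta = list())
  expect_error(findContactPoint(short), "too short")
})

test_that("contact recovery is accurate at realistic noise", {
  errs <- vapply(1:25, function(s) {
    fc <- simulateForceCurve(E = 500, contactZ = 1, noiseSd = 0.02,
                             seed = 300 + s)
    findContactPoint(fc)@contactZ - 1
  }, 0)
  expect_lt(median(abs(errs)) * 1000, 20)   # within 20 nm
})

test_that("batch medians reduce curves to cells to groups", {
  fits <- data.frame(compliance_kPa = c(2, 2, 2), cell = "c1", group = "G")
  b <- batchCompliance(fits)
  expect_equal(b$perCell$compliance_kPa, 2)
  expect_equal(b$perGroup$median_compliance_kPa, 2)
  # odd number of curves: median is the middle order statistic
  odd <- data.frame(compliance_kPa = c(1, 5, 100), cell = "c1", group = "G")
  expect_equal(batchCompliance(odd)$perCell$compliance_kPa, 5)
  # two groups, cells as the experimental unit
  two <- rbind(data.frame(compliance_kPa = rep(c(2, 2.4), 3),
                          cell = rep(c("a", "b", "c"), each = 2),
                          group = "soft"),
               data.frame(compliance_kPa = rep(c(4, 4.4), 3),
                          cell = rep(c("d", "e", "f"), each = 2),
                          group = "hard"))
  g <- batchCompliance(two)$perGroup
  expect_equal(g$median_compliance_kPa[g$group == "soft"], 2.2)
  expect_equal(g$median_compliance_kPa[g$group == "hard"], 4.2)
})
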