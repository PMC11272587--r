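# Allometry, survey, EQ and life-history diagnostics

test_that("allometry fit recovers planted log-linear relations exactly", {
  body <- c(2, 5, 10, 40, 80)
  brain <- 10^(0.5 * log10(body) - 1.2)
  fit <- allometryFit(body, brain)
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept, -1.2, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_warning(allometryFit(c(body, -1), c(brain, 1)), "excluded")
  expect_error(allometryFit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("random-genotype survey is seeded, classifies failures and fits
           the allometry over non-failed organisms", {
  sc <- scenarioPreset("sapiens", grid = ageGrid(1, 15))
  s1 <- randomGenotypeSurvey(sc, n = 150, sd = 4, seed = 9, adultAge = 14)
  s2 <- randomGenotypeSurvey(sc, n = 150, sd = 4, seed = 9, adultAge = 14)
  expect_identical(s1@table, s2@table)
  expect_true(s1@nonFailedFraction >= 0 && s1@nonFailedFraction <= 1)
  # failed organisms obey the two-clause rule
  f <- s1@table$failed
  expect_equal(f, s1@table$adultBody_kg < 0.2 &
                 (s1@table$adultBody_kg - s1@table$adultBrain_kg) <= 1e-6)
  # sd -> 0 collapses the survey onto the baseline genotype
  s0 <- randomGenotypeSurvey(sc, n = 5, sd = 1e-12, seed = 1, adultAge = 14)
  expect_lt(diff(range(s0@table$adultBody_kg)), 1e-6)
})

test_that("survey development matches develop() organism by organism", {
  sc <- scenarioPreset("sapiens", grid = ageGrid(1, 12))
  set.seed(21)
  s <- randomGenotypeSurvey(sc, n = 8, sd = 4, seed = 21, adultAge = 11)
  set.seed(21)
  nb <- 12
  Yb <- matrix(rnorm(nb * 8, 0, 4), nb, 8)
  Yr <- matrix(rnorm(nb * 8, 0, 4), nb, 8)
  Ys <- matrix(rnorm(nb * 8, 0, 4), nb, 8)
  for (i in 1:8) {
    ph <- develop(genotype(cbind(Yb[, i], Yr[, i], Ys[, i]), sc@grid), sc)
    expect_equal(s@table$adultBrain_kg[i], unname(ph@traits[12, 1]),
                 tolerance = 1e-12)
    expect_equal(s@table$adultBody_kg[i], sum(ph@traits[12, 1:3]),
                 tolerance = 1e-12)
  }
})

test_that("encephalization quotient follows its defining ratio", {
  ref <- eqReference()
  body <- 35
  expected <- ref[["coefficient"]] * body^ref[["exponent"]]
  expect_equal(encephalizationQuotient(expected, body), 1)
  # doubling the reference coefficient halves EQ
  ref2 <- ref; ref2[["coefficient"]] <- 2 * ref[["coefficient"]]
  expect_equal(encephalizationQuotient(0.5, body, ref2),
               encephalizationQuotient(0.5, body) / 2)
  # monotone in brain, antitone in body
  expect_gt(encephalizationQuotient(0.6, 30), encephalizationQuotient(0.5, 30))
  expect_gt(encephalizationQuotient(0.5, 30), encephalizationQuotient(0.5, 40))
  expect_error(encephalizationQuotient(-1, 30), "positive")
})

test_that("selection angle and evolvability are consistent", {
  expect_equal(selectionAngle(c(2, 0), c(1, 0)), 0)
  expect_equal(selectionAngle(c(0, 1), c(1, 0)), 90)
  expect_equal(selectionAngle(c(-1, 0), c(1, 0)), 180)
  expect_true(is.na(selectionAngle(c(0, 0), c(1, 0))))
  expect_equal(evolvability(c(0, 1), c(1, 0)), 0)
  expect_equal(evolvability(c(3, 0), c(1, 0)), 1)
  expect_error(evolvability(c(1, 0), c(0, 0)), "zero")
  # evolvability 0 iff angle 90 (within numerical tolerance)
  set.seed(2)
  for (i in 1:25) {
    dz <- rnorm(6); beta <- rnorm(6)
    ev <- evolvability(dz, beta)
    ang <- selectionAngle(dz, beta)
    expect_equal(abs(ev) < 1e-9, abs(ang - 90) < 1e-9 * 180 / pi)
    expect_equal(ev, cos(ang * pi / 180), tolerance = 1e-12)
  }
})

test_that("menarche age finds the first appreciably non-zero follicle age", {
  grid <- ageGrid(1, 30)
  mkPh <- function(xr) {
    tr <- cbind(x_b = 0.3, x_r = xr, x_s = 20, x_k = 1)
    new("Phenotype", traits = tr, energy = data.frame(), grid = grid)
  }
  step <- c(rep(0, 15), rep(1, 15))   # rises at 15 yr
  expect_equal(menarcheAge(mkPh(step)), 15)
  expect_equal(menarcheAge(mkPh(step), thresholdFraction = 0.5), 15)
  expect_true(is.na(menarcheAge(mkPh(rep(0, 30)))))
  expect_error(menarcheAge(mkPh(step), thresholdFraction = 2), "lie in")
})

test_that("weight velocity detects growth spurts", {
  grid <- ageGrid(0.5, 25)
  t <- grid@ages
  # single-logistic growth: exactly one interior velocity peak at the
  # inflection age
  L <- 50 / (1 + exp(-(t - 10.3) / 2))
  tr <- cbind(x_b = 0, x_r = 0, x_s = L, x_k = 0)
  ph <- new("Phenotype", traits = tr, energy = data.frame(), grid = grid)
  wv <- weightVelocity(ph)
  expect_equal(length(wv$spurtAges), 1L)
  expect_lt(abs(wv$spurtAges - 10.3), 0.6)
  # linear growth: constant velocity, no interior spurts
  tr2 <- cbind(x_b = 0, x_r = 0, x_s = 2 * t + 1, x_k = 0)
  ph2 <- new("Phenotype", traits = tr2, energy = data.frame(), grid = grid)
  expect_equal(length(weightVelocity(ph2)$spurtAges), 0L)
})

test_that("population-size proxy is a monotone transformation and vanishes
           with mu or eta0", {
  grid <- ageGrid(1, 10)
  mkPh <- function(xr) new("Phenotype",
    traits = cbind(0.3, xr, 20, 1), energy = data.frame(), grid = grid)
  lo <- populationSizeProxy(mkPh(rep(0.5, 10)), mu = 0.01, eta0 = 1e-4)
  hi <- populationSizeProxy(mkPh(rep(1.0, 10)), mu = 0.01, eta0 = 1e-4)
  expect_gt(hi, lo)
  expect_equal(populationSizeProxy(mkPh(rep(1, 10)), mu = 0), 0)
  expect_equal(populationSizeProxy(mkPh(rep(1, 10)), eta0 = 0), 0)
})

test_that("evolutionary time converts to years multiplicatively", {
  expect_equal(tauToYears(0), 0)
  expect_equal(tauToYears(300), 3.45e6)
  expect_equal(tauToYears(2, 250, 20), 1e4)
  expect_equal(tauToYears(6), 3 * tauToYears(2))
})
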