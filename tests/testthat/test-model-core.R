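# Developmental map: Kleiber's law, allocation, efficiency, develop

test_that("resting metabolic rate follows Kleiber's law", {
  cfg <- fixtureToy()$config
  expect_equal(restingMetabolicRate(0, cfg), 0)
  # 16^(3/4) = 8
  expect_equal(restingMetabolicRate(16, cfg), cfg@kleiberCoef * 8)
  # doubling mass multiplies the rate by 2^exponent; log-log slope check
  m <- c(1, 2, 4, 8, 16, 32)
  r <- restingMetabolicRate(m, cfg)
  expect_equal(r[-1] / r[-6], rep(2^cfg@kleiberExp, 5))
  expect_equal(diff(log(r)) / diff(log(m)), rep(cfg@kleiberExp, 5))
  expect_error(restingMetabolicRate(-1, cfg), "non-negative")
})

test_that("allocation fractions are a smooth simplex map with idle energy", {
  # symmetry: equal efforts give equal fractions
  q <- allocationFractions(c(0.7, 0.7, 0.7))
  expect_equal(unname(q[1]), unname(q[2]))
  expect_equal(unname(q[2]), unname(q[3]))
  # independent arithmetic transcription of the softmax-with-idle form
  y <- c(1, 0, -1)
  expect_equal(unname(allocationFractions(y)),
               exp(y) / (1 + exp(1) + exp(0) + exp(-1)))
  # fractions live in (0,1) and leave idle energy
  set.seed(3)
  Y <- matrix(rnorm(300, 0, 4), 100, 3)
  Q <- allocationFractions(Y)
  expect_true(all(Q > 0 & Q < 1))
  expect_true(all(rowSums(Q) < 1))
  # monotone saturation: a diverging effort takes the whole budget
  q <- allocationFractions(c(40, 0, 0))
  expect_equal(unname(q[1]), 1, tolerance = 1e-12)
  expect_lt(q[2] + q[3], 1e-12)
  expect_error(allocationFractions(c(Inf, 0, 0)), "finite")
})

test_that("energy-extraction efficiency is social only through non-ecological
           challenges and monotone in own skill", {
  cfg <- fixtureToy()$config
  eco <- cfg; eco@challengeMix <- c(1, 0, 0, 0)
  # ecological-only: independent of resident skill
  vals <- vapply(c(0, 1, 5, 20), function(rs)
    energyExtractionEfficiency(2, rs, eco), numeric(1))
  expect_equal(max(vals) - min(vals), 0)
  # skill-less newborn retains the baseline efficiency set by difficulty
  c0 <- eco@compBase
  expect_equal(energyExtractionEfficiency(0, 0, eco), c0 / (c0 + eco@alpha))
  # monotone non-decreasing in own skill, bounded in (0, 1)
  sk <- seq(0, 8, by = 0.25)
  e <- vapply(sk, function(s) energyExtractionEfficiency(s, 2, cfg),
              numeric(1))
  expect_true(all(diff(e) > 0))
  expect_true(all(e > 0 & e < 1))
  # per-type contributions sum to the total
  expect_equal(sum(energyExtractionEfficiency(2, 1.5, cfg, perType = TRUE)),
               energyExtractionEfficiency(2, 1.5, cfg))
  expect_error(energyExtractionEfficiency(-1, 0, cfg), "non-negative")
})

test_that("one developmental step reproduces explicit energy arithmetic", {
  fix <- fixtureToy(3)
  cfg <- fix$config
  x <- c(0.2, 0.01, 3, 0.5)
  y <- c(0.3, -0.5, 0.8)
  rk <- 0.5
  out <- developStep(x, y, rk, cfg)
  # independent hand transcription of the bookkeeping
  M <- 0.2 + 0.01 + 3
  Brest <- cfg@kleiberCoef * M^cfg@kleiberExp
  cc <- cfg@compBase * exp(cfg@gamma * 0.5)
  P <- cfg@challengeMix; al <- cfg@alpha
  Cco <- (sqrt(cc) + sqrt(cc))^2
  e <- P[1] * cc / (cc + al) + P[2] * Cco / (Cco + al) +
    P[4] * Cco / (Cco + al * Cco)
  maint <- cfg@Bb * 0.2 + cfg@Br * 0.01 + cfg@Bs * 3
  S <- e * Brest - maint
  q <- exp(y) / (1 + sum(exp(y)))
  dt <- cfg@grid@binWidth
  xb2 <- 0.2 + q[1] * S * dt / cfg@Eb
  xr2 <- 0.01 + q[2] * S * dt / cfg@Er
  xs2 <- 3 + q[3] * S * dt / cfg@Es
  xk2 <- 0.5 + dt * (cfg@sk * (cfg@Bb * 0.2 + cfg@Eb * (xb2 - 0.2) / dt) -
                     cfg@Bk * 0.5) / cfg@Ek
  expect_gt(S, 0)  # the fixture state is in the growth branch
  expect_equal(unname(out), unname(c(xb2, xr2, xs2, xk2)), tolerance = 1e-12)
})

test_that("zero surplus forces zero growth and deficits shrink tissues", {
  # fine-grained bins so the catabolic losses stay interior (no floors)
  cfg <- scenarioPreset("sapiens", grid = ageGrid(0.01, 0.1))
  # a follicle-heavy state: maintenance far above income
  x <- c(0.2, 0.5, 2, 0.5)
  out <- developStep(x, c(0, 0, 0), 0.5, cfg)
  expect_true(all(out[1:3] < x[1:3]))
  expect_true(all(out[1:3] > 0))
  # follicles decay fastest per kg, brain slowest (B_i/E_i ordering)
  relLoss <- (x[1:3] - out[1:3]) / x[1:3]
  expect_gt(relLoss[2], relLoss[3])
  expect_gt(relLoss[3], relLoss[1])
})

test_that("develop returns the fixed newborn and non-negative trajectories", {
  fix <- fixtureToy(10)
  cfg <- fix$config
  ph <- develop(fix$genotype, cfg)
  expect_equal(unname(ph@traits[1, ]), c(cfg@newborn, 0))
  set.seed(5)
  for (i in 1:10) {
    g <- genotype(matrix(rnorm(30, 0, 4), 10, 3), cfg@grid)
    ph <- develop(g, cfg)
    expect_equal(unname(ph@traits[1, ]), c(cfg@newborn, 0))
    expect_true(all(ph@traits >= 0))
  }
})

test_that("development is not social when facing only ecological challenges", {
  fix <- fixtureToy(10)
  cfg <- fix$config
  cfg@challengeMix <- c(1, 0, 0, 0)
  ph0 <- develop(fix$genotype, cfg, residentSkill = rep(0, 10))
  ph1 <- develop(fix$genotype, cfg, residentSkill = rep(50, 10))
  phS <- develop(fix$genotype, cfg)
  expect_identical(ph0@traits, ph1@traits)
  expect_identical(ph0@traits, phS@traits)
})

test_that("body mass sums tissue compartments and failure needs all-brain", {
  expect_equal(bodyMass(c(0.3, 0.1, 20, 2)), 20.4)
  expect_equal(bodyMass(c(0, 0, 0, 0)), 0)
  fix <- fixtureToy(10)
  ph <- develop(fix$genotype, fix$config)
  expect_equal(bodyMass(ph), rowSums(ph@traits[, 1:3]))
  # literal two-clause rule on synthetic phenotype slices
  mk <- function(xb, xr, xs) {
    tr <- ph@traits
    tr[10, ] <- c(xb, xr, xs, 0.1)
    new("Phenotype", traits = tr, energy = ph@energy, grid = ph@grid)
  }
  adult <- fix$config@grid@maxAge - fix$config@grid@binWidth
  expect_true(classifyFailed(mk(0.1, 0, 0), adultAge = adult))
  expect_false(classifyFailed(mk(0.1, 0, 0.05), adultAge = adult))
  expect_false(classifyFailed(mk(5, 1, 24), adultAge = adult))
  expect_error(classifyFailed(ph, adultAge = 1000), "age grid")
})

test_that("per-bin energy bookkeeping balances", {
  fix <- fixtureToy(10)
  ph <- develop(fix$genotype, fix$config)
  en <- ph@energy
  # income = eee * B_rest; surplus split into allocated growth + idle
  expect_equal(en$income, en$eee * en$B_rest, tolerance = 1e-12)
  grow <- en$income >= en$maint
  expect_equal(en$B_syn[grow], (en$income - en$maint)[grow],
               tolerance = 1e-9)
  expect_true(all(en$B_syn >= 0))
  expect_true(all(en$idle > 0 & en$idle < 1))
})
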