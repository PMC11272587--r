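# Developmental Jacobians, total/stabilized effects, covariance matrices,
# total selection gradients and parameter sensitivities, each validated
# against an independent oracle (finite differences or closed forms).

test_that("analytic Jacobians match central finite differences", {
  fix <- fixtureToy(10)
  cfg <- fix$config
  ph <- develop(fix$genotype, cfg)
  stack <- developmentalJacobians(ph, fix$genotype, cfg)
  prm <- evodevoBrain:::.asParamList(cfg)
  stepv <- function(x, y, rk) {
    st <- evodevoBrain:::.stepCore(x[1], x[2], x[3], x[4],
                                   y[1], y[2], y[3], rk, prm)
    unname(c(st$xb, st$xr, st$xs, st$xk))
  }
  for (a in c(1, 4, 8)) {
    x <- ph@traits[a, ]; y <- fix$genotype@efforts[a, ]; rk <- x[4]
    for (j in 1:4) {
      h <- max(1e-6, 1e-6 * abs(x[j]))
      xp <- x; xp[j] <- xp[j] + h
      xm <- x; xm[j] <- xm[j] - h
      fd <- (stepv(xp, y, rk) - stepv(xm, y, rk)) / (2 * h)
      expect_equal(stack@A[, j, a], fd, tolerance = 1e-5)
    }
    for (j in 1:3) {
      h <- 1e-6
      yp <- y; yp[j] <- yp[j] + h
      ym <- y; ym[j] <- ym[j] - h
      fd <- (stepv(x, yp, rk) - stepv(x, ym, rk)) / (2 * h)
      expect_equal(stack@B[, j, a], fd, tolerance = 1e-5)
    }
    h <- 1e-6
    fd <- (stepv(x, y, rk + h) - stepv(x, y, rk - h)) / (2 * h)
    expect_equal(stack@Ck[, a], fd, tolerance = 1e-5)
  }
})

test_that("resident-skill channel vanishes when development is not social", {
  fix <- fixtureToy(8)
  cfg <- fix$config
  cfg@challengeMix <- c(1, 0, 0, 0)
  ph <- develop(fix$genotype, cfg)
  stack <- developmentalJacobians(ph, fix$genotype, cfg)
  expect_true(all(stack@Ck == 0))
  expect_equal(stabilizedEffects(stack), totalEffects(stack))
})

test_that("total effects obey age causality and match the chain-rule on a
           scalar toy map", {
  # scalar map x_{a+1} = c x_a + d y_a: dx_3/dy_1 = c d, dx_3/dy_2 = d
  toy <- toyLinearMap(c = 0.8, d = 0.5, beta = 0, nBins = 4)
  TE <- toy$totalEffects()
  expect_equal(TE[3, 1], 0.8 * 0.5)
  expect_equal(TE[3, 2], 0.5)
  expect_equal(TE[3, 3], 0)

  # full model: block lower-triangular in age
  fix <- fixtureToy(10)
  ph <- develop(fix$genotype, fix$config)
  stack <- developmentalJacobians(ph, fix$genotype, fix$config)
  TE <- totalEffects(stack)
  n <- 10
  for (tr in 1:4) for (ty in 1:3) {
    blk <- TE[(tr - 1) * n + seq_len(n), (ty - 1) * n + seq_len(n)]
    expect_true(all(blk[upper.tri(blk, diag = TRUE)] == 0))
  }
})

test_that("total effects match finite differences of develop", {
  fix <- fixtureToy(10)
  ph <- develop(fix$genotype, fix$config)
  stack <- developmentalJacobians(ph, fix$genotype, fix$config)
  TE <- totalEffects(stack)
  n <- 10
  for (bin in c(2, 5)) for (trait in 1:3) {
    fd <- fdTotalEffect(fix$genotype, fix$config, bin, trait)
    for (tr in 1:4) {
      anl <- TE[(tr - 1) * n + seq_len(n), (trait - 1) * n + bin]
      expect_equal(anl, unname(fd[, tr]), tolerance = 1e-4)
    }
  }
})

test_that("stabilized effects solve the social feedback (closed form and
           reduction)", {
  # 1-D social map: the resident perturbation amplifies the recursion base
  # from c to c + beta (sequential fixed point over ages)
  toy <- toyLinearMap(c = 0.7, d = 0.4, beta = 0.2, nBins = 6)
  SE <- toy$stabilizedEffects()
  TE <- toy$totalEffects()
  expect_equal(SE[5, 2], 0.4 * (0.7 + 0.2)^2, tolerance = 1e-12)
  expect_equal(TE[5, 2], 0.4 * 0.7^2, tolerance = 1e-12)
  # beta = 0 collapses stabilized onto total
  toy0 <- toyLinearMap(c = 0.7, d = 0.4, beta = 0, nBins = 6)
  expect_identical(toy0$stabilizedEffects(), toy0$totalEffects())

  # full model: stabilized effects equal FD of self-resident development
  fix <- fixtureToy(10)
  cfg <- fix$config
  ph <- develop(fix$genotype, cfg)
  stack <- developmentalJacobians(ph, fix$genotype, cfg)
  SE <- stabilizedEffects(stack)
  n <- 10
  h <- 1e-5
  for (bin in c(2, 5)) {
    Yp <- fix$genotype@efforts; Yp[bin, 1] <- Yp[bin, 1] + h
    Ym <- fix$genotype@efforts; Ym[bin, 1] <- Ym[bin, 1] - h
    fd <- (develop(genotype(Yp, cfg@grid), cfg)@traits -
           develop(genotype(Ym, cfg@grid), cfg)@traits) / (2 * h)
    for (tr in 1:4)
      expect_equal(SE[(tr - 1) * n + seq_len(n), bin], unname(fd[, tr]),
                   tolerance = 1e-4)
  }
})

test_that("mutational covariance is diagonal and rejects covariation", {
  grid <- ageGrid(1, 5)
  H <- mutationalCovariance(grid)
  expect_equal(H, diag(15))
  expect_error(mutationalCovariance(grid, offDiagonal = 0.5),
               "diagonal")
  expect_error(mutationalCovariance(grid, variance = 0), "positive")
})

test_that("socio-genetic covariance has the Gram structure and dichotomy", {
  # 2x2 hand multiplication: A = [[1,0],[1,1]] gives A A^T = [[1,1],[1,2]]
  A <- rbind(c(1, 0), c(1, 1))
  L <- socioGeneticCovariance(A, A, 1)
  expect_equal(L$Lx, rbind(c(1, 1), c(1, 2)))
  # variance scaling is linear
  L2 <- socioGeneticCovariance(A, A, 2)
  expect_equal(L2$Lx, 2 * L$Lx)

  fix <- fixtureToy(8)
  cfg <- fix$config
  ph <- develop(fix$genotype, cfg)
  stack <- developmentalJacobians(ph, fix$genotype, cfg)
  te <- totalEffects(stack); se <- stabilizedEffects(stack)
  co <- socioGeneticCovariance(te, se)
  # social development makes L_z asymmetric; L_z is singular with rank
  # bounded by the genotypic dimension
  expect_gt(max(abs(co$Lz - t(co$Lz))), 1e-8)
  expect_lte(qr(co$Lz)$rank, 3 * 8)
  expect_equal(co$Hz, t(co$Hz))

  # ecological-only: L_z reduces to the symmetric H_z
  cfg2 <- cfg; cfg2@challengeMix <- c(1, 0, 0, 0)
  ph2 <- develop(fix$genotype, cfg2)
  st2 <- developmentalJacobians(ph2, fix$genotype, cfg2)
  co2 <- socioGeneticCovariance(totalEffects(st2), stabilizedEffects(st2))
  expect_equal(co2$Lz, co2$Hz, tolerance = 1e-12)
  expect_equal(co2$Lz, t(co2$Lz), tolerance = 1e-12)

  expect_error(socioGeneticCovariance(A, rbind(1, 1)), "equal shape")
})

test_that("total genotypic selection matches the finite-difference oracle", {
  fix <- fixtureToy(10)
  cfg <- fix$config
  ph <- develop(fix$genotype, cfg)
  stack <- developmentalJacobians(ph, fix$genotype, cfg)
  direct <- directSelectionGradient(ph, cfg@p)
  gr <- totalSelectionGradients(stack, direct)
  for (bin in c(1, 3, 6, 9)) for (trait in 1:3) {
    fd <- fdFitnessGradY(fix$genotype, cfg, bin, trait)
    expect_equal(unname(gr$dwdy[bin, trait]), fd, tolerance = 1e-4)
  }
  # the matrix route agrees with the adjoint route
  TE <- totalEffects(stack)
  dwdyMat <- crossprod(TE, as.vector(direct@dwdx))
  expect_equal(as.vector(gr$dwdy), as.vector(dwdyMat), tolerance = 1e-10)
  # zero direct selection gives zero total selection
  z <- direct; z@dwdx[] <- 0
  gz <- totalSelectionGradients(stack, z)
  expect_true(all(gz$dwdy == 0) && all(gz$dwdx == 0))
})

test_that("brain-row of L_z dynamics equals the follicle-covariance sum", {
  fix <- fixtureToy(8)
  cfg <- fix$config
  ph <- develop(fix$genotype, cfg)
  stack <- developmentalJacobians(ph, fix$genotype, cfg)
  te <- totalEffects(stack); se <- stabilizedEffects(stack)
  direct <- directSelectionGradient(ph, cfg@p)
  dwdxVec <- as.vector(direct@dwdx)
  full <- se %*% (1 * crossprod(te, dwdxVec))     # iota L_x dw/dx, all rows
  Lbr <- crossCovarianceBlock(se, te, 1, "b", "r")
  viaEq1 <- Lbr %*% direct@dwdx[, 2]
  expect_equal(full[seq_len(8)], as.vector(viaEq1), tolerance = 1e-12)
})

test_that("parameter sensitivities match finite differences and validate
           inputs", {
  fix <- fixtureToy(10)
  cfg <- fix$config
  ph <- develop(fix$genotype, cfg)
  for (id in c("Bb", "Bs", "Bk", "Ek", "kleiberCoef")) {
    ps <- parameterSensitivity(ph, fix$genotype, cfg, id)
    fd <- fdFitnessGradParam(fix$genotype, cfg, id)
    expect_equal(ps$total, fd, tolerance = 1e-4,
                 label = paste("dw/d", id))
  }
  expect_error(parameterSensitivity(ph, fix$genotype, cfg, "bogus"),
               "unknown parameterId")
})
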