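# Constraint side of the theory: per-age developmental Jacobians, total and
# stabilized effects of the genotype on the phenotype, mutational and
# socio-genetic covariance matrices, total selection gradients and total
# fitness effects of parameters. All derivatives are analytic chain-rule
# propagations evaluated at the resident trajectory; finite differences are
# used only as an independent oracle in the tests.

# Analytic derivatives of one developmental step, mirroring .stepCore.
# Returns A = dg/dx (4x4), B = dg/dy (4x3), C = dg/dxbar_k (4x1).
# Rows of outputs that were floored at zero are zeroed (the map is locally
# constant there).
.stepJacobian <- function(x, y, rk, prm) {
  xb <- x[1]; xr <- x[2]; xs <- x[3]; xk <- x[4]
  M <- xb + xr + xs
  Brest <- prm$K * M^prm$theta
  c1 <- .competence(xk, prm)
  cb <- .competence(rk, prm)
  ee <- .eeeCore(c1, cb, prm)
  maint <- prm$Bb * xb + prm$Br * xr + prm$Bs * xs
  income <- ee$e * Brest
  S <- income - maint
  m <- max(0, y); ex <- exp(y - m); q <- ex / (exp(-m) + sum(ex))
  E <- c(prm$Eb, prm$Er, prm$Es)
  Bm <- c(prm$Bb, prm$Br, prm$Bs)
  dt <- prm$dt
  kterm <- if (M > 0) ee$e * prm$K * prm$theta * M^(prm$theta - 1) else 0
  dSdx <- c(kterm - Bm,
            Brest * ee$dedc * .competencePrime(xk, prm))
  dSdrk <- Brest * ee$dedcb * .competencePrime(rk, prm)

  A <- diag(4); B <- matrix(0, 4, 3); C <- matrix(0, 4, 1)
  if (S >= 0) {
    delta <- q * S * dt / E
    for (i in 1:3) {
      A[i, ] <- A[i, ] + q[i] * dt / E[i] * dSdx
      B[i, ] <- dt * S / E[i] * q[i] * ((1:3 == i) - q)
      C[i, 1] <- q[i] * dt / E[i] * dSdrk
    }
  } else {
    R <- if (maint > 0) Bm * c(xb, xr, xs) / maint else rep(0, 3)
    delta <- S * dt * R / E
    for (i in 1:3) {
      dRdx <- if (maint > 0) ((1:3 == i) * Bm[i] - R[i] * Bm) / maint else rep(0, 3)
      A[i, 1:3] <- A[i, 1:3] + dt / E[i] * (R[i] * dSdx[1:3] + S * dRdx)
      A[i, 4] <- dt / E[i] * R[i] * dSdx[4]
      C[i, 1] <- dt / E[i] * R[i] * dSdrk
    }
  }
  # apply floors on tissue rows; record the effective brain increment slope
  nx <- pmax(c(xb, xr, xs) + delta, 0)
  floored <- (c(xb, xr, xs) + delta) < 0
  dDelB <- A[1, ] - c(1, 0, 0, 0)   # d(delta_b)/dx
  dDelB_y <- B[1, ]
  dDelB_rk <- C[1, 1]
  for (i in 1:3) if (floored[i]) {
    A[i, ] <- 0; B[i, ] <- 0; C[i, 1] <- 0
  }
  if (floored[1]) { # brain clamped: delta_b = -x_b exactly
    dDelB <- c(-1, 0, 0, 0); dDelB_y <- rep(0, 3); dDelB_rk <- 0
  }
  # skill row: delta_k = dt*(sk*(Bb*xb + Eb*delta_b/dt) - Bk*xk)/Ek
  sE <- prm$sk * prm$Eb / prm$Ek
  A[4, ] <- sE * dDelB
  A[4, 1] <- A[4, 1] + dt * prm$sk * prm$Bb / prm$Ek
  A[4, 4] <- A[4, 4] + 1 - dt * prm$Bk / prm$Ek
  B[4, ] <- sE * dDelB_y
  C[4, 1] <- sE * dDelB_rk
  deltaB <- if (floored[1]) -xb else delta[1]
  deltaK <- dt * (prm$sk * (prm$Bb * xb + prm$Eb * deltaB / dt) -
                  prm$Bk * xk) / prm$Ek
  if (xk + deltaK < 0) { A[4, ] <- 0; B[4, ] <- 0; C[4, 1] <- 0 }
  list(A = A, B = B, C = C)
}

#' Per-age Jacobians of the developmental map
#'
#' Computes the analytic derivatives of g_a with respect to the phenotype,
#' the growth efforts and the resident skill at every age bin, evaluated at
#' the resident trajectory. When ecological challenges are the only ones
#' faced (P_1 = 1) development is not social and the resident-skill column
#' is identically zero.
#'
#' @param phenotype the resident [Phenotype-class] developed from
#'   \code{genotype} under \code{config}.
#' @param genotype the resident [Genotype-class].
#' @param config the [ScenarioConfig-class].
#' @return a [SensitivityStack-class].
#' @export
developmentalJacobians <- function(phenotype, genotype, config) {
  grid <- config@grid
  n <- grid@nBins
  if (nrow(phenotype@traits) != n || nrow(genotype@efforts) != n)
    stop("phenotype/genotype/config age grids do not match")
  prm <- .asParamList(config)
  X <- phenotype@traits; Y <- genotype@efforts
  # spot-check that the trajectory satisfies the developmental map
  st <- .stepCore(X[1, 1], X[1, 2], X[1, 3], X[1, 4],
                  Y[1, 1], Y[1, 2], Y[1, 3], X[1, 4], prm)
  if (max(abs(c(st$xb, st$xr, st$xs, st$xk) - X[2, ])) >
      1e-6 * max(1, max(abs(X[2, ]))))
    stop("phenotype is not the resident trajectory of this genotype/config")
  A <- array(0, c(4, 4, n - 1)); B <- array(0, c(4, 3, n - 1))
  C <- matrix(0, 4, n - 1)
  for (a in seq_len(n - 1)) {
    jac <- .stepJacobian(X[a, ], Y[a, ], X[a, 4], prm)
    A[, , a] <- jac$A; B[, , a] <- jac$B; C[, a] <- jac$C
  }
  new("SensitivityStack", A = A, B = B, Ck = C, grid = grid)
}

# column index of (trait j, age t) in trait-major layout
.tmIndex <- function(trait, age, n) (trait - 1L) * n + age

.effectsMatrix <- function(stack, social) {
  n <- stack@grid@nBins
  Phi <- matrix(0, 4, 3 * n)
  TE <- matrix(0, 4 * n, 3 * n)
  for (a in seq_len(n - 1)) {
    A <- stack@A[, , a]
    if (social) A[, 4] <- A[, 4] + stack@Ck[, a]
    Phi <- A %*% Phi
    cols <- .tmIndex(1:3, a, n)
    Phi[, cols] <- Phi[, cols] + stack@B[, , a]
    TE[.tmIndex(1:4, a + 1, n), ] <- Phi
  }
  TE
}

#' Total effects of the genotype on the phenotype
#'
#' Forward chain-rule accumulation of \code{dx^T/dy} through the
#' developmental recurrence: \code{dx_(a+1)/dy = (dg_a/dx_a) dx_a/dy} plus
#' the direct block \code{dg_a/dy_a} at age a, starting from
#' \code{dx_1/dy = 0} (the newborn is fixed). The result is block
#' lower-triangular in age: genotypic entries cannot affect earlier
#' phenotypes.
#'
#' @param stack a [SensitivityStack-class] from [developmentalJacobians()].
#' @return a \code{(4 nBins) x (3 nBins)} matrix in trait-major, age-minor
#'   layout (phenotype rows x_b, x_r, x_s, x_k; genotype columns y_b, y_r,
#'   y_s; ages run within each trait block).
#' @export
totalEffects <- function(stack) .effectsMatrix(stack, social = FALSE)

#' Stabilized (social) effects of the genotype on the phenotype
#'
#' Total effects after social development has stabilized in the population:
#' the perturbation of the resident peers' skill equals the population's own
#' skill perturbation at the same age. Because the developmental map depends
#' only on same-age resident skill, the social feedback resolves
#' sequentially along the forward recursion with the skill column augmented
#' by the resident-skill channel. Reduces exactly to [totalEffects()] when
#' development is not social.
#'
#' @inheritParams totalEffects
#' @return matrix of the same shape as [totalEffects()].
#' @export
stabilizedEffects <- function(stack) .effectsMatrix(stack, social = TRUE)

#' Mutational covariance matrix H_y
#'
#' There is no mutational covariation in the model: H_y is diagonal with a
#' common mutational variance (default 1) on every genotypic entry.
#'
#' @param config a [ScenarioConfig-class] (or an [AgeGrid-class]).
#' @param variance positive mutational variance.
#' @param offDiagonal must be absent; requesting mutational covariation is
#'   rejected as it contradicts the model assumption.
#' @return diagonal matrix of size \code{3 nBins}.
#' @export
mutationalCovariance <- function(config, variance = 1, offDiagonal = NULL) {
  if (!is.null(offDiagonal))
    stop("mutational covariation is not part of the model: H_y is diagonal")
  if (variance <= 0) stop("mutational variance must be positive")
  grid <- if (is(config, "AgeGrid")) config else config@grid
  diag(variance, 3 * grid@nBins)
}

.diagOf <- function(Hy, m) {
  if (is.matrix(Hy)) {
    if (any(Hy[row(Hy) != col(Hy)] != 0))
      stop("H_y must be diagonal (no mutational covariation)")
    d <- diag(Hy)
  } else if (length(Hy) == 1) d <- rep(Hy, m) else d <- Hy
  if (length(d) != m) stop("H_y size does not match the effect matrices")
  if (any(d <= 0)) stop("mutational variances must be positive")
  d
}

#' Mechanistic socio-genetic covariance matrices
#'
#' Assembles \code{L_x = (sx/sy^T) H_y (dx^T/dy)^T} from the stabilized and
#' total effect matrices, plus the geno-phenotype matrices \code{L_z} and
#' its non-social analogue \code{H_z} over \code{z = (x; y)}. \code{L_z} is
#' singular by construction (rank at most the number of genotypic entries)
#' and asymmetric whenever social development makes stabilized and total
#' effects differ; with P_1 = 1 it reduces to the symmetric \code{H_z}.
#'
#' @param total,stabilized effect matrices from [totalEffects()] and
#'   [stabilizedEffects()].
#' @param Hy mutational covariance: scalar variance, diagonal vector or
#'   diagonal matrix.
#' @return list with \code{Lx}, \code{Lz}, \code{Hz}.
#' @export
socioGeneticCovariance <- function(total, stabilized = total, Hy = 1) {
  if (!all(dim(total) == dim(stabilized)))
    stop("total and stabilized effect matrices must have equal shape")
  m <- ncol(total)
  h <- .diagOf(Hy, m)
  SH <- sweep(stabilized, 2, h, `*`)     # (sx/sy^T) H_y
  TH <- sweep(total, 2, h, `*`)
  Lx <- SH %*% t(total)
  Hx <- TH %*% t(total)
  Lz <- rbind(cbind(Lx, SH), cbind(t(TH), diag(h, m)))
  Hz <- rbind(cbind(Hx, TH), cbind(t(TH), diag(h, m)))
  list(Lx = Lx, Lz = Lz, Hz = Hz)
}

#' One trait-pair block of the socio-genetic covariance of the phenotype
#'
#' Computes \code{L_x[rowTrait, colTrait]} (an nBins x nBins age-by-age
#' block, e.g. brain x follicles) without assembling the full matrix.
#'
#' @param stabilized,total effect matrices.
#' @param Hy mutational covariance (scalar, vector or diagonal matrix).
#' @param rowTrait,colTrait one of "b", "r", "s", "k".
#' @return nBins x nBins matrix.
#' @export
crossCovarianceBlock <- function(stabilized, total, Hy = 1,
                                 rowTrait = "b", colTrait = "r") {
  n <- nrow(total) / 4
  h <- .diagOf(Hy, ncol(total))
  ti <- function(tr) .tmIndex(match(tr, c("b", "r", "s", "k")), seq_len(n), n)
  sweep(stabilized[ti(rowTrait), , drop = FALSE], 2, h, `*`) %*%
    t(total[ti(colTrait), , drop = FALSE])
}

#' Total selection gradients
#'
#' Propagates the direct selection gradient through the developmental
#' constraint by the backward (adjoint) recursion, yielding the total
#' phenotypic selection gradient \code{dw/dx} and the total genotypic
#' selection gradient \code{dw/dy = (dx^T/dy) (dw/dx-direct)}. Since direct
#' selection is supported only on follicle entries, \code{dw/dy} depends
#' only on the follicle rows of the total effects.
#'
#' @param stack a [SensitivityStack-class].
#' @param direct a [DirectSelection-class] for the same resident.
#' @return list with \code{dwdx} (nBins x 4) and \code{dwdy} (nBins x 3).
#' @export
totalSelectionGradients <- function(stack, direct) {
  n <- stack@grid@nBins
  if (nrow(direct@dwdx) != n) stop("direct gradient grid does not match")
  dwdx <- matrix(0, n, 4, dimnames = dimnames(direct@dwdx))
  dwdy <- matrix(0, n, 3, dimnames = list(NULL, c("y_b", "y_r", "y_s")))
  lambda <- direct@dwdx[n, ]
  dwdx[n, ] <- lambda
  for (a in seq(n - 1, 1)) {
    dwdy[a, ] <- crossprod(stack@B[, , a], lambda)
    lambda <- direct@dwdx[a, ] + as.numeric(crossprod(stack@A[, , a], lambda))
    dwdx[a, ] <- lambda
  }
  list(dwdx = dwdx, dwdy = dwdy)
}

# derivative of the energy-extraction efficiency wrt alpha
.eeeDalpha <- function(c1, cbar, prm) {
  a <- prm$alpha; P <- prm$P
  d <- 0
  if (P[1] > 0) d <- d - P[1] * c1 / (c1 + a)^2
  if (P[2] > 0) { C <- .coopPair(c1, cbar, prm)$C; d <- d - P[2] * C / (C + a)^2 }
  if (P[3] > 0) d <- d - P[3] * c1 * cbar / (c1 + a * cbar)^2
  if (P[4] > 0) {
    C <- .coopPair(c1, cbar, prm)$C; Cb <- .coopPair(cbar, cbar, prm)$C
    d <- d - P[4] * C * Cb / (C + a * Cb)^2
  }
  d
}

# d g_a / d theta for one step (4-vector), mirroring .stepCore branches
.stepParamDeriv <- function(x, y, rk, prm, parameterId) {
  xb <- x[1]; xr <- x[2]; xs <- x[3]; xk <- x[4]
  M <- xb + xr + xs
  Brest <- prm$K * M^prm$theta
  c1 <- .competence(xk, prm); cb <- .competence(rk, prm)
  ee <- .eeeCore(c1, cb, prm)
  maint <- prm$Bb * xb + prm$Br * xr + prm$Bs * xs
  income <- ee$e * Brest
  S <- income - maint
  m <- max(0, y); ex <- exp(y - m); q <- ex / (exp(-m) + sum(ex))
  E <- c(prm$Eb, prm$Er, prm$Es); Bm <- c(prm$Bb, prm$Br, prm$Bs)
  dt <- prm$dt
  dS <- switch(parameterId,              # d(surplus)/d theta
    Bb = -xb, Br = -xr, Bs = -xs,
    kleiberCoef = income / prm$K,
    alpha = Brest * .eeeDalpha(c1, cb, prm),
    0)
  dDelta <- numeric(3)           # d(tissue increments)/d theta
  if (S >= 0) {
    delta <- q * S * dt / E
    dDelta <- q * dS * dt / E
  } else {
    R <- if (maint > 0) Bm * c(xb, xr, xs) / maint else rep(0, 3)
    delta <- S * dt * R / E
    dDelta <- dt / E * R * dS
    if (maint > 0 && parameterId %in% c("Bb", "Br", "Bs")) {
      i0 <- match(parameterId, c("Bb", "Br", "Bs"))
      xi <- c(xb, xr, xs)[i0]
      dR <- ((1:3 == i0) * xi - R * xi) / maint
      dDelta <- dDelta + dt / E * S * dR
    }
  }
  if (parameterId == "Eb") dDelta[1] <- dDelta[1] - delta[1] / prm$Eb
  if (parameterId == "Er") dDelta[2] <- dDelta[2] - delta[2] / prm$Er
  if (parameterId == "Es") dDelta[3] <- dDelta[3] - delta[3] / prm$Es
  # floors
  floored <- (c(xb, xr, xs) + delta) < 0
  dDelta[floored] <- 0
  dB <- if (floored[1]) 0 else dDelta[1]
  deltaB <- if (floored[1]) -xb else delta[1]
  # skill increment
  brainEnergy <- prm$Bb * xb + prm$Eb * deltaB / dt
  deltaK <- dt * (prm$sk * brainEnergy - prm$Bk * xk) / prm$Ek
  dK <- prm$sk * prm$Eb / prm$Ek * dB
  if (parameterId == "Bb") dK <- dK + dt * prm$sk * xb / prm$Ek
  if (parameterId == "Bk") dK <- dK - dt * xk / prm$Ek
  if (parameterId == "Ek") dK <- dK - deltaK / prm$Ek
  if (parameterId == "sk") dK <- dK + dt * brainEnergy / prm$Ek
  if (parameterId == "Eb" && !floored[1])
    dK <- dK + prm$sk * deltaB / prm$Ek  # explicit E_b factor in the skill budget
  if (xk + deltaK < 0) dK <- 0
  c(dDelta, dK)
}

#' Total fitness effect of a model parameter
#'
#' Total derivative of the resident's relative fitness with respect to a
#' developmental-map parameter, obtained by propagating the per-age
#' parameter sensitivity of the map through the same backward recursion as
#' the total selection gradients and contracting with direct selection. A
#' negative value is a total fitness cost, a positive value a total fitness
#' benefit; parameters have no direct fitness effect because fitness depends
#' on them only through development.
#'
#' @param phenotype resident [Phenotype-class].
#' @param genotype resident [Genotype-class].
#' @param config the [ScenarioConfig-class].
#' @param parameterId one of "Bb", "Br", "Bs", "Bk", "Ek", "Eb", "Er", "Es",
#'   "sk", "kleiberCoef", "alpha".
#' @return list with \code{total} (scalar dw/d theta) and \code{perAge}
#'   (contribution of each age bin).
#' @export
parameterSensitivity <- function(phenotype, genotype, config, parameterId) {
  valid <- c("Bb", "Br", "Bs", "Bk", "Ek", "Eb", "Er", "Es", "sk",
             "kleiberCoef", "alpha")
  if (!parameterId %in% valid)
    stop("unknown parameterId '", parameterId, "'; valid: ",
         paste(valid, collapse = ", "))
  stack <- developmentalJacobians(phenotype, genotype, config)
  direct <- directSelectionGradient(phenotype, config@p)
  tot <- totalSelectionGradients(stack, direct)
  prm <- .asParamList(config)
  n <- config@grid@nBins
  X <- phenotype@traits; Y <- genotype@efforts
  perAge <- numeric(n)
  for (a in seq_len(n - 1)) {
    dg <- .stepParamDeriv(X[a, ], Y[a, ], X[a, 4], prm, parameterId)
    perAge[a] <- sum(dg * tot$dwdx[a + 1, ])
  }
  list(total = sum(perAge), perAge = perAge)
}
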