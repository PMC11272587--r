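# Canonical-equation evolutionary loop: mutation-limited gradient dynamics
# of the genotypic growth efforts, with scenario schedules and per-step
# diagnostics. The loop itself is deterministic; seeds matter only for
# survey utilities.

#' Construct an evolution run configuration
#'
#' @param schedule list of \code{list(time =, scenario =)} entries
#'   (a [ScenarioConfig-class] each), first entry at time 0, switch times
#'   strictly increasing; or a single [ScenarioConfig-class].
#' @param Tend final evolutionary time (default 500).
#' @param iota non-negative mutational input scalar. The default (2e4)
#'   calibrates the evolutionary time unit so that the two-stage hominin
#'   protocol approaches its equilibrium within 500 time units; iota is
#'   proportional to the mutation rate times carrying capacity and is
#'   absorbed into the unit of evolutionary time.
#' @param deltaTau evolutionary step (default 1).
#' @param sigmaMut mutational variance, the common diagonal of H_y.
#' @param mu,eta0 diagnostic parameters of the population-size proxy.
#' @param seed integer seed recorded for provenance.
#' @param storeL evolutionary times at which socio-genetic covariance
#'   snapshots are stored (default c(1, 10, 100, 500); use numeric(0) for
#'   none).
#' @return an [EvolutionConfig-class].
#' @export
evolutionConfig <- function(schedule, Tend = 500, iota = 2e4, deltaTau = 1,
                            sigmaMut = 1, mu = 0.01, eta0 = NULL,
                            seed = 1L, storeL = c(1, 10, 100, 500)) {
  if (is(schedule, "ScenarioConfig"))
    schedule <- list(list(time = 0, scenario = schedule))
  n <- schedule[[1]]$scenario@grid@nBins
  if (is.null(eta0)) eta0 <- 1 / (10 * 3 * n)
  new("EvolutionConfig", iota = iota, deltaTau = deltaTau, Tend = Tend,
      schedule = schedule, sigmaMut = sigmaMut, mu = mu, eta0 = eta0,
      seed = as.integer(seed), storeL = as.numeric(storeL))
}

.scenarioAt <- function(schedule, tau) {
  sc <- schedule[[1]]$scenario
  for (s in schedule) if (s$time <= tau) sc <- s$scenario else break
  sc
}

.adultBin <- function(grid, adultAge = 40) {
  a <- round(adultAge / grid@binWidth) + 1
  as.integer(min(max(a, 1), grid@nBins))
}

#' One step of the canonical equation
#'
#' Updates the resident genotype by
#' \code{y' = y + iota * H_y * (dw/dy) * deltaTau}, with the total genotypic
#' selection gradient computed at the resident developed under the given
#' scenario.
#'
#' @param genotype resident [Genotype-class].
#' @param scenario the active [ScenarioConfig-class].
#' @param evoConfig an [EvolutionConfig-class] (iota, sigmaMut, deltaTau).
#' @return list with the updated \code{genotype}, the gradient \code{dwdy}
#'   (nBins x 3), and the resident \code{phenotype}.
#' @export
evolutionaryStep <- function(genotype, scenario, evoConfig) {
  phen <- develop(genotype, scenario)
  stack <- developmentalJacobians(phen, genotype, scenario)
  direct <- directSelectionGradient(phen, scenario@p)
  grads <- totalSelectionGradients(stack, direct)
  if (any(!is.finite(grads$dwdy)))
    stop("non-finite total genotypic selection gradient; resident adult ",
         "phenotype: ", paste(signif(phen@traits[nrow(phen@traits), ], 4),
                              collapse = ", "))
  newY <- genotype@efforts +
    evoConfig@iota * evoConfig@sigmaMut * grads$dwdy * evoConfig@deltaTau
  list(genotype = genotype(newY, genotype@grid), dwdy = grads$dwdy,
       phenotype = phen)
}

#' Run the evo-devo dynamics
#'
#' Iterates development and the canonical equation over evolutionary time.
#' At a scenario switch the genotype carries over unchanged while the
#' phenotype re-develops under the new parameters (the immediate plastic
#' change). Per-step records hold the resident genotype, phenotype, total
#' genotypic selection gradient and summary diagnostics; socio-genetic
#' covariance snapshots are stored at the scheduled times.
#'
#' @param ancestor ancestral [Genotype-class].
#' @param evoConfig an [EvolutionConfig-class] whose schedule covers
#'   \code{[0, Tend]}.
#' @param verbose print progress every 100 steps.
#' @return an [EvoTrajectory-class].
#' @export
runEvoDevo <- function(ancestor, evoConfig, verbose = FALSE) {
  grid <- ancestor@grid
  n <- grid@nBins
  nStep <- as.integer(round(evoConfig@Tend / evoConfig@deltaTau))
  taus <- seq(0, by = evoConfig@deltaTau, length.out = nStep + 1)
  G <- array(NA_real_, c(nStep + 1, n, 3))
  X <- array(NA_real_, c(nStep + 1, n, 4))
  D <- array(NA_real_, c(nStep + 1, n, 3))
  scen <- character(nStep + 1)
  Lsnap <- list()
  diag_rows <- vector("list", nStep + 1)
  Y <- ancestor
  aAd <- .adultBin(grid)
  eqr <- eqReference()
  prevZ <- NULL
  for (i in seq_len(nStep + 1)) {
    tau <- taus[i]
    sc <- .scenarioAt(evoConfig@schedule, tau)
    phen <- develop(Y, sc)
    stack <- developmentalJacobians(phen, Y, sc)
    direct <- directSelectionGradient(phen, sc@p)
    grads <- totalSelectionGradients(stack, direct)
    if (any(!is.finite(grads$dwdy)))
      stop("non-finite gradient at evolutionary time ", tau)
    G[i, , ] <- Y@efforts
    X[i, , ] <- phen@traits
    D[i, , ] <- grads$dwdy
    scen[i] <- sc@name
    ad <- phen@traits[aAd, ]
    body <- sum(ad[1:3])
    z <- c(as.vector(phen@traits), as.vector(Y@efforts))
    beta <- c(as.vector(direct@dwdx), as.vector(direct@dwdy))
    ang <- ev <- NA_real_
    if (!is.null(prevZ)) {
      dz <- z - prevZ$z
      if (sqrt(sum(dz^2)) > 0) {
        ang <- selectionAngle(dz, prevZ$beta)
        ev <- evolvability(dz, prevZ$beta)
      }
    }
    diag_rows[[i]] <- data.frame(
      tau = tau, scenario = sc@name,
      adultBrain_kg = ad[1], adultFollicles_kg = ad[2],
      adultBody_kg = body, adultSkill_TB = ad[4],
      EQ = if (body > 0 && ad[1] > 0)
        encephalizationQuotient(ad[1], body, eqr) else NA_real_,
      menarche_yr = menarcheAge(phen),
      gradNorm = sqrt(sum(grads$dwdy^2)),
      maxDirectFollicle = max(direct@dwdx[, 2]),
      angle_deg = ang, evolvability = ev,
      popsizeProxy = populationSizeProxy(phen, evoConfig@mu, evoConfig@eta0))
    if (tau %in% evoConfig@storeL) {
      te <- totalEffects(stack); se <- stabilizedEffects(stack)
      Lsnap[[as.character(tau)]] <- list(
        brainFollicle = crossCovarianceBlock(se, te, evoConfig@sigmaMut,
                                             "b", "r"),
        follicleFollicle = crossCovarianceBlock(se, te, evoConfig@sigmaMut,
                                                "r", "r"))
    }
    prevZ <- list(z = z, beta = beta)
    if (i <= nStep)
      Y <- genotype(Y@efforts + evoConfig@iota * evoConfig@sigmaMut *
                      grads$dwdy * evoConfig@deltaTau, grid)
    if (verbose && (i - 1) %% 100 == 0)
      message("tau = ", tau, ": adult brain ", signif(ad[1], 3),
              " kg, body ", signif(body, 3), " kg")
  }
  new("EvoTrajectory", tau = taus, genotypes = G, phenotypes = X,
      gradients = D, diagnostics = do.call(rbind, diag_rows),
      Lsnapshots = Lsnap, scenarioNames = scen, evoConfig = evoConfig)
}

#' First-order consistency of the phenotype dynamics
#'
#' Checks that the realized per-step phenotype change matches the prediction
#' of the geno-phenotype gradient dynamics,
#' \code{d zbar / d tau = iota L_z (dw/dz)}, and that the realized
#' brain-size change matches the brain-row reconstruction
#' \code{iota sum_j L_(x_ba, x_rj) dw_j/dx_rj} (the covariance-with-follicles
#' sum). Both residuals are first-order in the step size on smooth segments;
#' across a scenario switch the comparison is not meaningful and is refused.
#'
#' @param trajectory an [EvoTrajectory-class].
#' @param tau the evolutionary time of the record to check (its successor
#'   must exist and be in the same scenario).
#' @param zeroBrainFollicleBlock if TRUE the brain-follicle covariance block
#'   is artificially set to zero before predicting, demonstrating that
#'   without brain-follicle covariation no brain-size evolution is
#'   predicted.
#' @return list with per-entry residuals and the predicted and realized
#'   changes.
#' @export
phenotypeRateCheck <- function(trajectory, tau, zeroBrainFollicleBlock = FALSE) {
  i <- match(tau, trajectory@tau)
  if (is.na(i) || i >= length(trajectory@tau))
    stop("tau must name a record with a successor")
  if (trajectory@scenarioNames[i] != trajectory@scenarioNames[i + 1])
    stop("records straddle a scenario switch; the first-order prediction ",
         "does not apply to the plastic change")
  ec <- trajectory@evoConfig
  sc <- .scenarioAt(ec@schedule, trajectory@tau[i])
  grid <- sc@grid; n <- grid@nBins
  Y <- genotype(trajectory@genotypes[i, , ], grid)
  phen <- develop(Y, sc)
  stack <- developmentalJacobians(phen, Y, sc)
  direct <- directSelectionGradient(phen, sc@p)
  te <- totalEffects(stack); se <- stabilizedEffects(stack)
  dwdxVec <- as.vector(direct@dwdx)          # trait-major
  dwdy <- as.vector(crossprod(te, dwdxVec))  # (dx^T/dy) dw/dx
  predDx <- ec@iota * ec@sigmaMut * (se %*% dwdy) * ec@deltaTau
  realizedDx <- as.vector(trajectory@phenotypes[i + 1, , ] -
                          trajectory@phenotypes[i, , ])
  Lbr <- crossCovarianceBlock(se, te, ec@sigmaMut, "b", "r")
  if (zeroBrainFollicleBlock) Lbr[] <- 0
  predBrain <- ec@iota * as.vector(Lbr %*% direct@dwdx[, 2]) * ec@deltaTau
  realizedBrain <- trajectory@phenotypes[i + 1, , 1] -
    trajectory@phenotypes[i, , 1]
  list(phenotypeResidual = realizedDx - as.vector(predDx),
       brainResidual = realizedBrain - predBrain,
       predictedPhenotype = as.vector(predDx), realizedPhenotype = realizedDx,
       predictedBrain = predBrain, realizedBrain = realizedBrain)
}
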