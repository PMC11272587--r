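# Post-processing: allometry regressions, random-genotype surveys and
# life-history diagnostics.

#' Log-log brain-body allometry fit
#'
#' Ordinary least squares of log10 adult brain mass on log10 adult body
#' mass. Slope and R-squared are base-invariant; the intercept is reported
#' in base 10. Non-positive masses are excluded with a warning.
#'
#' @param body,brain adult masses in kg, equal lengths.
#' @return list with \code{slope}, \code{intercept}, \code{r2}, \code{n}.
#' @export
allometryFit <- function(body, brain) {
  if (length(body) != length(brain)) stop("body and brain lengths differ")
  ok <- body > 0 & brain > 0 & is.finite(body) & is.finite(brain)
  if (any(!ok)) warning(sum(!ok), " non-positive mass pairs excluded")
  if (sum(ok) < 3) stop("need at least 3 positive-mass pairs")
  lx <- log10(body[ok]); ly <- log10(brain[ok])
  fit <- stats::lm(ly ~ lx)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = stats::cor(lx, ly)^2, n = sum(ok))
}

#' Random-genotype developmental survey
#'
#' Draws \code{n} genotypes with every growth-effort entry i.i.d.
#' Normal(0, sd), develops each as its own resident under the scenario,
#' classifies failed organisms (small adult bodies entirely composed of
#' brain) and fits the brain-body allometry over the non-failed ones.
#'
#' @param scenario a [ScenarioConfig-class].
#' @param n number of genotypes (>= 1).
#' @param sd standard deviation of the growth efforts (default 4).
#' @param seed integer seed.
#' @param adultAge adult age in years (default 40), clamped to the grid.
#' @param batch number of genotypes developed per vectorized pass.
#' @return a [SurveyResult-class].
#' @export
randomGenotypeSurvey <- function(scenario, n, sd = 4, seed = 1L,
                                 adultAge = 40, batch = 2000L) {
  if (n < 1) stop("n must be >= 1")
  if (sd < 0) stop("sd must be non-negative")
  grid <- scenario@grid
  nb <- grid@nBins
  aAd <- .adultBin(grid, adultAge)
  set.seed(seed)
  brain <- body <- numeric(n)
  nonBrain <- numeric(n)
  done <- 0L
  while (done < n) {
    m <- min(batch, n - done)
    Yb <- matrix(stats::rnorm(nb * m, 0, sd), nb, m)
    Yr <- matrix(stats::rnorm(nb * m, 0, sd), nb, m)
    Ys <- matrix(stats::rnorm(nb * m, 0, sd), nb, m)
    ad <- .developMany(Yb, Yr, Ys, scenario, keepBins = aAd)[[1]]
    idx <- done + seq_len(m)
    brain[idx] <- ad[1, ]
    body[idx] <- ad[1, ] + ad[2, ] + ad[3, ]
    nonBrain[idx] <- ad[2, ] + ad[3, ]
    done <- done + m
  }
  failed <- body < 0.2 & nonBrain <= 1e-6
  tab <- data.frame(adultBody_kg = body, adultBrain_kg = brain,
                    failed = failed)
  keep <- !failed & body > 0 & brain > 0
  fit <- if (sum(keep) >= 3)
    allometryFit(body[keep], brain[keep])
  else list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_)
  new("SurveyResult", table = tab, nonFailedFraction = mean(!failed),
      slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
      seed = as.integer(seed), n = as.integer(n))
}

#' Reference curve for the encephalization quotient
#'
#' Mammalian expected brain mass for a given body mass,
#' \code{expected = coefficient * body^exponent} with both masses in kg
#' (0.0585 g g^-0.76 converted to kg units).
#'
#' @return named vector with \code{coefficient} and \code{exponent}.
#' @export
eqReference <- function() {
  c(coefficient = 0.0585 * 1000^(0.76 - 1), exponent = 0.76)
}

#' Encephalization quotient
#'
#' Brain mass relative to the expected brain mass of a mammal of the same
#' body mass: \code{EQ = brain / (coefficient * body^exponent)}.
#'
#' @param brain,body masses in kg, positive.
#' @param reference named vector with \code{coefficient} and
#'   \code{exponent}; defaults to [eqReference()].
#' @return dimensionless EQ (vectorized).
#' @export
encephalizationQuotient <- function(brain, body, reference = eqReference()) {
  if (any(brain <= 0) || any(body <= 0)) stop("masses must be positive")
  brain / (reference[["coefficient"]] * body^reference[["exponent"]])
}

#' Angle between evolutionary change and direct selection
#'
#' @param deltaZ realized geno-phenotype change vector.
#' @param beta direct selection gradient of the geno-phenotype.
#' @return angle in degrees in [0, 180]; NA if either vector is zero.
#' @export
selectionAngle <- function(deltaZ, beta) {
  nd <- sqrt(sum(deltaZ^2)); nb <- sqrt(sum(beta^2))
  if (nd == 0 || nb == 0) return(NA_real_)
  acos(max(-1, min(1, sum(deltaZ * beta) / (nd * nb)))) * 180 / pi
}

#' Evolvability along direct selection
#'
#' The extent to which evolution proceeds in the direction of direct
#' selection: the normalized projection of the realized geno-phenotype
#' change onto the direct selection gradient (the cosine of their angle).
#' Zero exactly when change is orthogonal to selection ("no evolution
#' despite selection"), maximal (1) when parallel.
#'
#' @param deltaZ realized geno-phenotype change vector.
#' @param beta direct selection gradient; must be non-zero.
#' @return dimensionless measure in [-1, 1], non-negative under gradient
#'   dynamics.
#' @export
evolvability <- function(deltaZ, beta) {
  nb <- sqrt(sum(beta^2))
  if (nb == 0) stop("direct selection gradient is zero")
  nd <- sqrt(sum(deltaZ^2))
  if (nd == 0) return(NA_real_)
  sum(deltaZ * beta) / (nd * nb)
}

#' Age at menarche
#'
#' The developmental onset of reproduction: the first age at which follicle
#' count exceeds a fraction of its lifetime maximum ("appreciably
#' non-zero").
#'
#' @param phenotype a [Phenotype-class].
#' @param thresholdFraction fraction of the maximum follicle count
#'   (default 0.01).
#' @return age in years, or NA if follicle count is identically zero.
#' @export
menarcheAge <- function(phenotype, thresholdFraction = 0.01) {
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must lie in (0, 1)")
  xr <- phenotype@traits[, 2]
  mx <- max(xr)
  if (mx <= 0) return(NA_real_)
  phenotype@grid@ages[which(xr > thresholdFraction * mx)[1]]
}

#' Weight velocity and growth spurts
#'
#' First differences of body mass over age divided by the bin width; growth
#' spurts are strict local maxima of the velocity above a noise floor.
#'
#' @param phenotype a [Phenotype-class].
#' @param floorFraction spurts below this fraction of the peak velocity are
#'   ignored.
#' @return list with \code{age} (midpoints, years), \code{velocity}
#'   (kg yr^-1) and \code{spurtAges}.
#' @export
weightVelocity <- function(phenotype, floorFraction = 0.05) {
  bm <- bodyMass(phenotype)
  grid <- phenotype@grid
  v <- diff(bm) / grid@binWidth
  age <- grid@ages[-1] - grid@binWidth / 2
  nf <- floorFraction * max(v, 0)
  k <- length(v)
  isMax <- rep(FALSE, k)
  if (k >= 3)
    # left-strict maxima: a flat two-bin peak counts once, a constant
    # velocity counts never
    isMax[2:(k - 1)] <- v[2:(k - 1)] > v[1:(k - 2)] &
      v[2:(k - 1)] >= v[3:k] & v[2:(k - 1)] > nf
  list(age = age, velocity = v, spurtAges = age[isMax])
}

#' Population-size proxy
#'
#' Returns \code{(1/2) mu nstar eta0}, a monotone transformation of the
#' resident's demographic size. The carrying-capacity quantity nstar is
#' represented here by the resident's net lifetime reproduction
#' \code{sum_a p^(a-1) xbar_ra} (survivorship-weighted fertility), a
#' monotone stand-in for the demographic closure.
#'
#' @param resident a [Phenotype-class].
#' @param mu mutation rate, 0 < mu << 1.
#' @param eta0 small positive parameter, << 1/(N_g N_a).
#' @param p per-bin survival used in the weighting (default 0.9985).
#' @return dimensionless proxy.
#' @export
populationSizeProxy <- function(resident, mu = 0.01, eta0 = NULL,
                                p = 0.9985) {
  n <- resident@grid@nBins
  if (is.null(eta0)) eta0 <- 1 / (10 * 3 * n)
  xr <- resident@traits[, 2]
  nstar <- sum(p^(seq_len(n) - 1) * xr)
  0.5 * mu * nstar * eta0
}

#' Convert evolutionary time to years
#'
#' One evolutionary time unit is the time from mutation to fixation.
#'
#' @param tau evolutionary time.
#' @param generationsPerFixation generations per gene fixation (default 500).
#' @param yearsPerGeneration female generation time in years (default 23).
#' @return years, the product of the three factors.
#' @export
tauToYears <- function(tau, generationsPerFixation = 500,
                       yearsPerGeneration = 23) {
  tau * generationsPerFixation * yearsPerGeneration
}
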