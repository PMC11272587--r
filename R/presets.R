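# Scenario presets (shipped as JSON data files), ancestral genotype presets
# and reduced fixtures for derivative oracles.

.scenarioNames <- c("afarensis", "habilis", "ergaster", "erectus",
                    "heidelbergensis", "neanderthalensis", "sapiens",
                    "ecological")

.ancestorNames <- c("naive", "somewhatNaive", "ecoSols", "highlySpecified",
                    "afarensisFromHighlySpecified",
                    "afarensisFromSomewhatNaive", "somewhatNaive2",
                    "afarensisFromNaive2", "afarensisFromEcoSols")

.pkgCache <- new.env(parent = emptyenv())

#' Hominin scenario preset
#'
#' Loads one of the shipped scenario configurations: the seven hominin
#' scenarios (afarensis, habilis, ergaster, erectus, heidelbergensis,
#' neanderthalensis, sapiens) plus the ecological scenario (P_1 = 1). All
#' share the core metabolic parameters; they differ in the challenge mix,
#' the competence regime (power = strongly diminishing returns of learning,
#' exponential = weakly diminishing) and the cooperation form.
#'
#' @param name scenario name.
#' @param grid optional [AgeGrid-class] (default: the file's 0.1-yr, 47-yr
#'   grid).
#' @return a [ScenarioConfig-class].
#' @export
scenarioPreset <- function(name, grid = NULL) {
  if (!name %in% .scenarioNames)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(.scenarioNames, collapse = ", "))
  path <- system.file("extdata", "scenarios", paste0(name, ".json"),
                      package = "evodevoBrain", mustWork = TRUE)
  loadConfig(path, grid = grid)
}

.effortProfile <- function(name, t) {
  switch(name,
    naive = cbind(y_b = 0 * t, y_r = 0 * t, y_s = 0 * t),
    somewhatNaive = cbind(y_b = 0 * t,
                          y_r = -1 + 0.1 * t,
                          y_s = 0.5 - 0.05 * t),
    somewhatNaive2 = cbind(y_b = 0.5 - 0.08 * t,
                           y_r = -4.5 + 0.25 * t - 0.006 * t^2,
                           y_s = 2.5 - 0.05 * t),
    ecoSols = cbind(y_b = 1.5 - 0.1 * t,
                    y_r = -5 + 0.35 * t - 0.007 * t^2,
                    y_s = 1 - 0.1 * t),
    highlySpecified = cbind(y_b = 2 * exp(-t / 8) - 1,
                            y_r = -4 + 3.5 / (1 + exp(-(t - 12) / 2)),
                            y_s = 2 * exp(-t / 12) - 1),
    stop("no closed-form profile for '", name, "'"))
}

#' Ancestral genotype preset
#'
#' Returns one of the nine documented ancestral genotypes on the requested
#' grid. The naive-family presets are smooth parametric age profiles of the
#' growth efforts; the afarensisFrom* presets are the evolved endpoints of a
#' 500-step run under the afarensis scenario seeded with the corresponding
#' base preset, regenerated by [runEvoDevo()] on first use and cached for
#' the session.
#'
#' @param name one of naive, somewhatNaive, somewhatNaive2, ecoSols,
#'   highlySpecified, afarensisFromNaive2, afarensisFromSomewhatNaive,
#'   afarensisFromHighlySpecified, afarensisFromEcoSols.
#' @param grid an [AgeGrid-class] (default 0.1-yr bins to 47 yr).
#' @return a [Genotype-class].
#' @export
ancestralGenotype <- function(name, grid = ageGrid()) {
  if (!name %in% .ancestorNames)
    stop("unknown ancestral genotype '", name, "'; valid names: ",
         paste(.ancestorNames, collapse = ", "))
  if (startsWith(name, "afarensisFrom")) {
    base <- switch(name,
      afarensisFromNaive2 = "somewhatNaive2",
      afarensisFromSomewhatNaive = "somewhatNaive",
      afarensisFromHighlySpecified = "highlySpecified",
      afarensisFromEcoSols = "ecoSols")
    key <- paste(name, grid@nBins, grid@binWidth, sep = "|")
    if (!is.null(.pkgCache[[key]])) return(.pkgCache[[key]])
    sc <- scenarioPreset("afarensis", grid = grid)
    traj <- runEvoDevo(ancestralGenotype(base, grid),
                       evolutionConfig(sc, Tend = 500, storeL = numeric(0)))
    out <- genotype(traj@genotypes[length(traj@tau), , ], grid)
    .pkgCache[[key]] <- out
    return(out)
  }
  genotype(.effortProfile(name, grid@ages), grid)
}

#' Reduced-grid fixture configuration
#'
#' A fully valid scenario configuration with the real developmental map on
#' a small grid (1-yr bins), together with a smooth genotype kept in the
#' surplus-energy region, sized for finite-difference derivative oracles.
#'
#' @param nBins number of age bins, between 2 and 20.
#' @param scenario preset name providing the parameter core.
#' @return list with \code{config} and \code{genotype}.
#' @export
toyConfig <- function(nBins = 10, scenario = "sapiens") {
  if (nBins < 2 || nBins > 20) stop("nBins must lie in [2, 20]")
  grid <- ageGrid(binWidth = 1, maxAge = nBins)
  config <- scenarioPreset(scenario, grid = grid)
  t <- grid@ages
  # follicle efforts stay strongly negative: their high maintenance cost
  # would otherwise flip alternate bins into the deficit branch, putting
  # finite-difference probes onto kinks
  gen <- genotype(cbind(y_b = 0.5 - 0.05 * t,
                        y_r = -6 + 0.15 * t,
                        y_s = 0.5 - 0.04 * t), grid)
  list(config = config, genotype = gen)
}

#' Analytically solvable linear developmental map
#'
#' A scalar recurrence \code{x_(a+1) = c x_a + d y_a + beta xbar_a} in which
#' the single phenotypic trait is itself the social trait. Ships the map,
#' its iterate, and closed forms for the trajectory, the total effects
#' (\code{d c^(a-1-j)}), the stabilized effects (\code{d (c+beta)^(a-1-j)},
#' the social feedback resolving into a shifted geometric factor) and the
#' resulting covariance matrices, used as an independent oracle.
#'
#' @param c,d,beta map coefficients (default 0.8, 0.5, 0.3).
#' @param nBins number of age bins.
#' @param x1 developmentally initial state.
#' @return list of functions and coefficients; see Details.
#' @export
toyLinearMap <- function(c = 0.8, d = 0.5, beta = 0.3, nBins = 6, x1 = 0) {
  iterate <- function(y, social = TRUE) {
    x <- numeric(nBins)
    x[1] <- x1
    for (a in seq_len(nBins - 1))
      x[a + 1] <- c * x[a] + d * y[a] + (if (social) beta * x[a] else 0)
    x
  }
  closedTrajectory <- function(y0) {
    # constant effort y0, resident self-consistent
    r <- c + beta
    a <- seq_len(nBins)
    x1 * r^(a - 1) + d * y0 * ifelse(a == 1, 0,
      ifelse(abs(r - 1) < 1e-12, a - 1, (r^(a - 1) - 1) / (r - 1)))
  }
  effects <- function(r) {
    M <- matrix(0, nBins, nBins)
    for (a in seq_len(nBins)) for (j in seq_len(nBins))
      if (j < a) M[a, j] <- d * r^(a - 1 - j)
    M
  }
  list(c = c, d = d, beta = beta, nBins = nBins, x1 = x1,
       iterate = iterate, closedTrajectory = closedTrajectory,
       totalEffects = function() effects(c),
       stabilizedEffects = function() effects(c + beta),
       Lx = function(sigma2 = 1)
         sigma2 * effects(c + beta) %*% t(effects(c)))
}
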