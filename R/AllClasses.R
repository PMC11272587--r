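#' @import methods
NULL

#' Discrete age grid
#'
#' Ages are modelled as \code{nBins} bins of width \code{binWidth} years
#' spanning birth (age 0) to \code{maxAge}. Bin \code{a} holds the phenotype
#' at age \code{(a - 1) * binWidth}, so bin 1 is the newborn.
#'
#' @slot binWidth bin width in years.
#' @slot maxAge final age in years; must be an exact multiple of the bin width.
#' @slot nBins number of bins, \code{maxAge / binWidth}.
#' @slot ages age (years) at the start of each bin, strictly increasing.
#' @export
setClass("AgeGrid",
  representation(binWidth = "numeric", maxAge = "numeric",
                 nBins = "integer", ages = "numeric"))

setValidity("AgeGrid", function(object) {
  msg <- character()
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  n <- object@maxAge / object@binWidth
  if (abs(n - round(n)) > 1e-8)
    msg <- c(msg, "maxAge must be an exact multiple of binWidth")
  if (object@nBins != round(n))
    msg <- c(msg, "nBins must equal maxAge / binWidth")
  if (length(object@ages) != object@nBins || any(diff(object@ages) <= 0))
    msg <- c(msg, "ages must be strictly increasing with one entry per bin")
  if (length(msg)) msg else TRUE
})

#' Construct an age grid
#'
#' @param binWidth bin width in years (default 0.1).
#' @param maxAge final age in years (default 47).
#' @return an [AgeGrid-class] object.
#' @examples
#' ageGrid()           # the default 470-bin grid
#' ageGrid(0.05, 47)   # halved bin size used for regression checks
#' @export
ageGrid <- function(binWidth = 0.1, maxAge = 47) {
  n <- as.integer(round(maxAge / binWidth))
  new("AgeGrid", binWidth = binWidth, maxAge = maxAge, nBins = n,
      ages = (seq_len(n) - 1) * binWidth)
}

#' Scenario configuration
#'
#' Holds every parameter of one hominin scenario: tissue-specific metabolic
#' costs (MJ kg^-1 yr^-1 for maintenance, MJ kg^-1 for synthesis), skill
#' bookkeeping costs, Kleiber's law constants, the challenge mix
#' \code{P_1..P_4} (ecological, cooperative, between-individual competitive,
#' between-group competitive), the competence regime, the cooperation form,
#' the constant per-bin survival probability and the fixed newborn phenotype.
#'
#' @slot name scenario label.
#' @slot Bb,Br,Bs maintenance costs of brain, follicle and somatic tissue,
#'   MJ kg^-1 yr^-1.
#' @slot Bk memory (skill maintenance) cost, MJ TB^-1 yr^-1.
#' @slot Ek learning (skill synthesis) cost, MJ TB^-1.
#' @slot Eb,Er,Es tissue synthesis costs, MJ kg^-1.
#' @slot sk fraction of brain energy allocated to skill, dimensionless.
#' @slot kleiberCoef,kleiberExp resting metabolic rate constants:
#'   B_rest = coef * mass^exp, MJ yr^-1 with mass in kg.
#' @slot alpha environmental difficulty, dimensionless.
#' @slot gamma skill effectiveness, TB^-1.
#' @slot compBase baseline competence of an unskilled individual,
#'   dimensionless.
#' @slot nu exponent of the power competence regime, dimensionless.
#' @slot competenceForm "exponential" (weakly diminishing returns of
#'   learning, Regime 1) or "power" (strongly diminishing, Regime 2).
#' @slot cooperationForm "additive" or "submultiplicative" pairing of
#'   cooperating partners' competences.
#' @slot challengeMix probabilities P_1..P_4, non-negative, summing to 1.
#' @slot p per-bin survival probability, in (0, 1).
#' @slot newborn newborn tissue masses (x_b1, x_r1, x_s1) in kg; newborn
#'   skill is fixed at 0 TB.
#' @slot grid the [AgeGrid-class].
#' @export
setClass("ScenarioConfig",
  representation(name = "character",
                 Bb = "numeric", Br = "numeric", Bs = "numeric",
                 Bk = "numeric", Ek = "numeric",
                 Eb = "numeric", Er = "numeric", Es = "numeric",
                 sk = "numeric",
                 kleiberCoef = "numeric", kleiberExp = "numeric",
                 alpha = "numeric", gamma = "numeric", nu = "numeric",
                 compBase = "numeric",
                 competenceForm = "character",
                 cooperationForm = "character",
                 challengeMix = "numeric",
                 p = "numeric", newborn = "numeric",
                 grid = "AgeGrid"))

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  costs <- c(Bb = object@Bb, Br = object@Br, Bs = object@Bs, Bk = object@Bk,
             Ek = object@Ek, Eb = object@Eb, Er = object@Er, Es = object@Es,
             kleiberCoef = object@kleiberCoef)
  if (any(costs <= 0))
    msg <- c(msg, paste("costs must be > 0:",
                        paste(names(costs)[costs <= 0], collapse = ", ")))
  if (object@kleiberExp <= 0 || object@kleiberExp >= 1)
    msg <- c(msg, "kleiberExp must lie in (0, 1)")
  P <- object@challengeMix
  if (length(P) != 4 || any(P < 0) || abs(sum(P) - 1) > 1e-9)
    msg <- c(msg, "challengeMix must be 4 non-negative proportions summing to 1")
  if (object@p <= 0 || object@p >= 1)
    msg <- c(msg, "p must lie in (0, 1)")
  if (length(object@newborn) != 3 || any(object@newborn < 0))
    msg <- c(msg, "newborn must hold 3 non-negative masses (kg)")
  if (!object@competenceForm %in% c("exponential", "power"))
    msg <- c(msg, "competenceForm must be 'exponential' or 'power'")
  if (!object@cooperationForm %in% c("additive", "submultiplicative"))
    msg <- c(msg, "cooperationForm must be 'additive' or 'submultiplicative'")
  if (object@sk < 0 || object@sk > 1)
    msg <- c(msg, "sk must lie in [0, 1]")
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
  if (object@compBase <= 0) msg <- c(msg, "compBase must be > 0")
  if (length(msg)) msg else TRUE
})

#' Genotype: age-specific growth efforts
#'
#' The evolving object. One unconstrained real effort per age bin and per
#' produced tissue (brain, follicles, soma), measured as a difference from a
#' baseline effort, so entries may be negative.
#'
#' @slot efforts numeric matrix, \code{nBins x 3}, columns
#'   \code{y_b, y_r, y_s}.
#' @slot grid the [AgeGrid-class] the efforts live on.
#' @export
setClass("Genotype",
  representation(efforts = "matrix", grid = "AgeGrid"))

setValidity("Genotype", function(object) {
  msg <- character()
  if (ncol(object@efforts) != 3)
    msg <- c(msg, "efforts must have 3 columns (y_b, y_r, y_s)")
  if (nrow(object@efforts) != object@grid@nBins)
    msg <- c(msg, "efforts must have one row per age bin")
  if (any(!is.finite(object@efforts)))
    msg <- c(msg, "efforts must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a genotype from an effort matrix
#' @param efforts nBins x 3 matrix (columns y_b, y_r, y_s).
#' @param grid an [AgeGrid-class].
#' @export
genotype <- function(efforts, grid) {
  efforts <- as.matrix(efforts)
  colnames(efforts) <- c("y_b", "y_r", "y_s")
  new("Genotype", efforts = efforts, grid = grid)
}

#' Phenotype: developed trajectories
#'
#' The product of iterating the developmental map from the newborn state:
#' brain mass, follicle count (mass units), somatic mass (kg) and skill (TB)
#' per age bin, together with the per-age energy bookkeeping.
#'
#' @slot traits numeric matrix, \code{nBins x 4}, columns
#'   \code{x_b, x_r, x_s, x_k}.
#' @slot energy data.frame with per-age energy state: resting metabolic rate
#'   \code{B_rest}, energy-extraction efficiency \code{eee}, realized income,
#'   maintenance, growth metabolic rate \code{B_syn}, allocation fractions
#'   \code{q_b, q_r, q_s} and idle fraction (all rates MJ yr^-1).
#' @slot grid the [AgeGrid-class].
#' @export
setClass("Phenotype",
  representation(traits = "matrix", energy = "data.frame", grid = "AgeGrid"))

setValidity("Phenotype", function(object) {
  msg <- character()
  if (ncol(object@traits) != 4)
    msg <- c(msg, "traits must have 4 columns (x_b, x_r, x_s, x_k)")
  if (nrow(object@traits) != object@grid@nBins)
    msg <- c(msg, "traits must have one row per age bin")
  if (any(object@traits < 0))
    msg <- c(msg, "phenotypic entries must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Direct selection gradient over the geno-phenotype
#'
#' Entries of the gradient of relative fitness with respect to every
#' phenotypic and genotypic entry, holding development fixed. Fitness depends
#' directly only on the mutant follicle count, so only the \code{x_r} column
#' is non-zero.
#'
#' @slot dwdx nBins x 4 matrix (columns x_b, x_r, x_s, x_k).
#' @slot dwdy nBins x 3 matrix (columns y_b, y_r, y_s); identically zero.
#' @export
setClass("DirectSelection",
  representation(dwdx = "matrix", dwdy = "matrix"))

#' Per-age developmental Jacobians
#'
#' Derivatives of the developmental map g_a with respect to own phenotype,
#' own genotype and resident skill, evaluated at the resident trajectory.
#' Slice \code{a} maps age bin \code{a} to bin \code{a + 1}, so there are
#' \code{nBins - 1} slices.
#'
#' @slot A 4 x 4 x (nBins-1) array, d g_a / d x_a.
#' @slot B 4 x 3 x (nBins-1) array, d g_a / d y_a.
#' @slot Ck 4 x (nBins-1) matrix, d g_a / d xbar_k,a (resident-skill channel).
#' @slot grid the [AgeGrid-class].
#' @export
setClass("SensitivityStack",
  representation(A = "array", B = "array", Ck = "matrix", grid = "AgeGrid"))

#' Evolutionary trajectory record
#'
#' Per-evolutionary-time snapshots produced by [runEvoDevo()]: the resident
#' genotype and phenotype, the total genotypic selection gradient, and
#' summary diagnostics (adult sizes, EQ, menarche, selection angle,
#' evolvability, population-size proxy).
#'
#' @slot tau evolutionary times of the records (0 = ancestor).
#' @slot genotypes nTau x nBins x 3 array of growth efforts.
#' @slot phenotypes nTau x nBins x 4 array of developed traits.
#' @slot gradients nTau x nBins x 3 array of dw/dy entries.
#' @slot diagnostics data.frame, one row per record.
#' @slot Lsnapshots named list of socio-genetic covariance blocks stored at
#'   scheduled times.
#' @slot scenarioNames scenario active at each record.
#' @slot evoConfig the [EvolutionConfig-class] used.
#' @export
setClass("EvoTrajectory",
  representation(tau = "numeric", genotypes = "array", phenotypes = "array",
                 gradients = "array", diagnostics = "data.frame",
                 Lsnapshots = "list", scenarioNames = "character",
                 evoConfig = "ANY"))

#' Evolution run configuration
#'
#' @slot iota non-negative mutational-input scalar of the canonical equation.
#' @slot deltaTau evolutionary step size (default 1).
#' @slot Tend final evolutionary time (default 500).
#' @slot schedule list of \code{list(time=, scenario=)} entries with strictly
#'   increasing switch times; the scenario at time 0 must be present.
#' @slot sigmaMut mutational variance (H_y = sigmaMut * I).
#' @slot mu mutation rate (diagnostic only).
#' @slot eta0 diagnostic parameter, 0 < eta0 << 1/(N_g N_a).
#' @slot seed integer seed recorded for provenance.
#' @slot storeL evolutionary times at which covariance snapshots are kept.
#' @export
setClass("EvolutionConfig",
  representation(iota = "numeric", deltaTau = "numeric", Tend = "numeric",
                 schedule = "list", sigmaMut = "numeric", mu = "numeric",
                 eta0 = "numeric", seed = "integer", storeL = "numeric"))

setValidity("EvolutionConfig", function(object) {
  msg <- character()
  if (object@iota < 0) msg <- c(msg, "iota must be >= 0")
  times <- vapply(object@schedule, function(s) s$time, numeric(1))
  if (length(times) == 0 || times[1] != 0)
    msg <- c(msg, "schedule must start with a scenario at time 0")
  if (any(diff(times) <= 0))
    msg <- c(msg, "schedule switch times must be strictly increasing")
  if (object@sigmaMut <= 0) msg <- c(msg, "sigmaMut must be > 0")
  if (length(msg)) msg else TRUE
})

#' Random-genotype survey result
#'
#' @slot table data.frame with per-genotype adult body mass, brain mass and
#'   failed flag.
#' @slot nonFailedFraction fraction of genotypes developing non-failed
#'   organisms.
#' @slot slope,intercept,r2 log10-log10 OLS fit of adult brain on adult body
#'   over non-failed organisms.
#' @slot seed,n survey provenance.
#' @export
setClass("SurveyResult",
  representation(table = "data.frame", nonFailedFraction = "numeric",
                 slope = "numeric", intercept = "numeric", r2 = "numeric",
                 seed = "integer", n = "integer"))
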