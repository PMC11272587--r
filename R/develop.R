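# Core developmental map: energy-conservation construction of brain,
# follicles, soma and skill across age bins.
#
# Per age bin of width dt (years), with tissue masses x_b, x_r, x_s (kg) and
# skill x_k (TB):
#   M       = x_b + x_r + x_s                       body mass
#   B_rest  = K * M^theta                           Kleiber's law, MJ yr^-1
#   maint   = B_b x_b + B_r x_r + B_s x_s           maintenance demand
#   e       = sum_j P_j e_j(c(x_k), c(xbar_k))      energy-extraction efficiency
#   income  = e * B_rest                            realized energy rate
#   B_syn   = income - maint         when positive  growth metabolic rate
# The individual realizes the fraction e of her Kleiber budget by
# overcoming energy-extraction challenges; maintenance is paid from that
# income and the surplus B_syn is split by the allocation fractions
# q_i(y_a): tissue i grows by q_i * B_syn * dt / E_i. When maintenance
# exceeds income the shortfall is covered by catabolism: tissue i shrinks
# by its maintenance share R_i = B_i x_i / maint of the deficit, at energy
# yield E_i per kg.
# The brain's energy consumption B_b x_b + E_b dx_b/dt funds skill: a
# fraction s_k of it pays the memory cost B_k x_k and the learning cost E_k
# per TB gained. All tissue and skill states are floored at zero.

.asParamList <- function(config) {
  list(Bb = config@Bb, Br = config@Br, Bs = config@Bs, Bk = config@Bk,
       Ek = config@Ek, Eb = config@Eb, Er = config@Er, Es = config@Es,
       sk = config@sk, K = config@kleiberCoef, theta = config@kleiberExp,
       alpha = config@alpha, gamma = config@gamma, nu = config@nu,
       c0 = config@compBase,
       comp = config@competenceForm, coop = config@cooperationForm,
       P = config@challengeMix, p = config@p, newborn = config@newborn,
       dt = config@grid@binWidth, nBins = config@grid@nBins)
}

#' Resting metabolic rate from Kleiber's law
#'
#' @param bodyMass body mass in kg (vectorized), must be non-negative.
#' @param config a [ScenarioConfig-class].
#' @return energy rate in MJ yr^-1, \code{coef * mass^exp}.
#' @export
restingMetabolicRate <- function(bodyMass, config) {
  if (any(bodyMass < 0)) stop("bodyMass must be non-negative")
  config@kleiberCoef * bodyMass^config@kleiberExp
}

#' Allocation fractions of the growth metabolic rate
#'
#' Maps the three unconstrained growth efforts at one age to the fractions
#' of the growth metabolic rate allocated to brain, follicle and somatic
#' tissue synthesis. The map is a softmax with an idle class,
#' \code{q_i = exp(y_i) / (1 + sum_j exp(y_j))}, so each fraction lies in
#' (0, 1), the fractions sum to less than 1 (idle energy is allowed), the
#' map is smooth and symmetric across tissues, and a diverging effort
#' saturates its fraction at 1 while the others vanish.
#'
#' @param efforts numeric vector of 3 efforts (y_b, y_r, y_s) or an n x 3
#'   matrix of efforts.
#' @return a vector (q_b, q_r, q_s) or an n x 3 matrix of fractions.
#' @export
allocationFractions <- function(efforts) {
  if (is.matrix(efforts)) {
    if (ncol(efforts) != 3) stop("efforts matrix must have 3 columns")
    if (any(!is.finite(efforts))) stop("efforts must be finite")
    m <- pmax(0, efforts[, 1], efforts[, 2], efforts[, 3])
    ex <- exp(efforts - m)
    q <- ex / (exp(-m) + rowSums(ex))
    colnames(q) <- c("q_b", "q_r", "q_s")
    return(q)
  }
  if (length(efforts) != 3) stop("efforts must hold 3 values")
  if (any(!is.finite(efforts))) stop("efforts must be finite")
  m <- max(0, efforts)
  ex <- exp(efforts - m)
  stats::setNames(ex / (exp(-m) + sum(ex)), c("q_b", "q_r", "q_s"))
}

# competence c(x_k) and its derivative; c(0) = c0 in both regimes so a
# skill-less newborn retains a baseline ability to extract energy.
.competence <- function(xk, prm) {
  if (prm$comp == "exponential") prm$c0 * exp(prm$gamma * xk)
  else prm$c0 * (1 + prm$gamma * xk)^prm$nu
}
.competencePrime <- function(xk, prm) {
  if (prm$comp == "exponential") prm$c0 * prm$gamma * exp(prm$gamma * xk)
  else prm$c0 * prm$gamma * prm$nu * (1 + prm$gamma * xk)^(prm$nu - 1)
}

# pair competence of two cooperating partners and partial derivatives
.coopPair <- function(c1, c2, prm) {
  if (prm$coop == "additive") {
    list(C = c1 + c2, d1 = rep(1, length(c1)), d2 = rep(1, length(c2)))
  } else {
    s <- sqrt(c1 * c2)
    list(C = c1 + c2 + 2 * s, d1 = 1 + sqrt(c2 / c1), d2 = 1 + sqrt(c1 / c2))
  }
}

# efficiency of each challenge type and derivatives wrt own and resident
# competence. Own side competence is pitted against the environmental
# difficulty alpha times the opposing side's competence (1 for non-social
# nature in ecological and cooperative challenges).
.eeeCore <- function(c1, cbar, prm) {
  a <- prm$alpha
  P <- prm$P
  e <- dedc <- dedcb <- 0
  if (P[1] > 0) {
    den <- c1 + a
    e <- e + P[1] * c1 / den
    dedc <- dedc + P[1] * a / den^2
  }
  if (P[2] > 0) {
    cp <- .coopPair(c1, cbar, prm)
    den <- cp$C + a
    e <- e + P[2] * cp$C / den
    dedc <- dedc + P[2] * a * cp$d1 / den^2
    dedcb <- dedcb + P[2] * a * cp$d2 / den^2
  }
  if (P[3] > 0) {
    den <- c1 + a * cbar
    e <- e + P[3] * c1 / den
    dedc <- dedc + P[3] * a * cbar / den^2
    dedcb <- dedcb - P[3] * a * c1 / den^2
  }
  if (P[4] > 0) {
    cp <- .coopPair(c1, cbar, prm)
    cbb <- .coopPair(cbar, cbar, prm)
    Cbp <- if (prm$coop == "additive") 2 else 4  # d C(cbar,cbar) / d cbar
    den <- cp$C + a * cbb$C
    e <- e + P[4] * cp$C / den
    dedc <- dedc + P[4] * a * cbb$C * cp$d1 / den^2
    dedcb <- dedcb + P[4] * a * (cbb$C * cp$d2 - cp$C * Cbp) / den^2
  }
  list(e = e, dedc = dedc, dedcb = dedcb)
}

#' Energy-extraction efficiency
#'
#' The probability-weighted efficiency of converting the four challenge
#' types (ecological, cooperative, between-individual competitive,
#' between-group competitive) into energy, as a function of own and resident
#' (peer) skill. Own competence \code{c(x_k)} is exponential in skill under
#' Regime 1 (weakly diminishing returns of learning) or a power law under
#' Regime 2 (strongly diminishing returns); cooperating pairs combine
#' competences additively or submultiplicatively. Only the social challenge
#' types depend on resident skill.
#'
#' @param ownSkill,residentSkill skill levels in TB, non-negative.
#' @param config a [ScenarioConfig-class].
#' @param perType if TRUE return the per-challenge-type efficiencies
#'   weighted by their probabilities instead of their sum.
#' @return dimensionless efficiency in (0, 1).
#' @export
energyExtractionEfficiency <- function(ownSkill, residentSkill, config,
                                       perType = FALSE) {
  if (any(ownSkill < 0) || any(residentSkill < 0))
    stop("skill levels must be non-negative")
  prm <- .asParamList(config)
  c1 <- .competence(ownSkill, prm)
  cb <- .competence(residentSkill, prm)
  if (!perType) return(.eeeCore(c1, cb, prm)$e)
  a <- prm$alpha
  out <- numeric(4)
  out[1] <- prm$P[1] * c1 / (c1 + a)
  cp <- .coopPair(c1, cb, prm)
  out[2] <- prm$P[2] * cp$C / (cp$C + a)
  out[3] <- prm$P[3] * c1 / (c1 + a * cb)
  cbb <- .coopPair(cb, cb, prm)
  out[4] <- prm$P[4] * cp$C / (cp$C + a * cbb$C)
  stats::setNames(out, c("ecological", "cooperative",
                         "betweenIndividual", "betweenGroup"))
}

# One developmental step on plain state vectors. Returns the next state and
# the energy decomposition of the bin. Vectorized over organisms: x* and rk
# may be equal-length vectors, yb/yr/ys scalars or equal-length vectors.
.stepCore <- function(xb, xr, xs, xk, yb, yr, ys, rk, prm) {
  M <- xb + xr + xs
  Brest <- prm$K * M^prm$theta
  c1 <- .competence(xk, prm)
  cb <- .competence(rk, prm)
  eee <- .eeeCore(c1, cb, prm)$e
  maint <- prm$Bb * xb + prm$Br * xr + prm$Bs * xs
  income <- eee * Brest              # realized energy-extraction rate
  S <- income - maint                # surplus (may be negative)
  Bsyn <- pmax(S, 0)                 # growth metabolic rate
  m <- pmax(0, yb, yr, ys)                   # overflow-safe softmax
  eb <- exp(yb - m); er <- exp(yr - m); es <- exp(ys - m)
  den <- exp(-m) + eb + er + es
  qb <- eb / den; qr <- er / den; qs <- es / den
  grow <- S >= 0
  negS <- pmin(S, 0)
  safeM <- ifelse(maint > 0, maint, 1)
  dxb <- ifelse(grow, qb * Bsyn / prm$Eb,
                negS * (prm$Bb * xb / safeM) / prm$Eb) * prm$dt
  dxr <- ifelse(grow, qr * Bsyn / prm$Er,
                negS * (prm$Br * xr / safeM) / prm$Er) * prm$dt
  dxs <- ifelse(grow, qs * Bsyn / prm$Es,
                negS * (prm$Bs * xs / safeM) / prm$Es) * prm$dt
  nxb <- pmax(xb + dxb, 0)
  nxr <- pmax(xr + dxr, 0)
  nxs <- pmax(xs + dxs, 0)
  # skill: funded by a fraction s_k of realized brain energy consumption
  brainEnergy <- prm$Bb * xb + prm$Eb * (nxb - xb) / prm$dt
  dxk <- (prm$sk * brainEnergy - prm$Bk * xk) / prm$Ek * prm$dt
  nxk <- pmax(xk + dxk, 0)
  list(xb = nxb, xr = nxr, xs = nxs, xk = nxk,
       Brest = Brest, eee = eee, income = income, maint = maint,
       Bsyn = Bsyn, qb = qb, qr = qr, qs = qs)
}

#' One step of the developmental map
#'
#' Applies the developmental constraint g_a once: from the phenotype slice at
#' one age bin, the growth efforts at that bin and the resident (peer) skill,
#' returns the phenotype at the next bin. Checks the internal energy balance
#' of the bin: income splits exactly into maintenance, synthesis and idle
#' energy (or, under deficit, maintenance equals income plus catabolic
#' yield).
#'
#' @param x numeric vector (x_b, x_r, x_s, x_k): kg, kg, kg, TB.
#' @param y numeric vector (y_b, y_r, y_s) of growth efforts.
#' @param residentSkill resident skill at the same age, TB.
#' @param config a [ScenarioConfig-class].
#' @param tol relative tolerance of the internal energy-balance check.
#' @return named numeric vector, the phenotype slice at the next age bin.
#' @export
developStep <- function(x, y, residentSkill, config, tol = 1e-9) {
  if (any(x < 0)) stop("phenotype entries must be non-negative")
  prm <- .asParamList(config)
  st <- .stepCore(x[1], x[2], x[3], x[4], y[1], y[2], y[3], residentSkill, prm)
  # energy-balance audit: income = maintenance + allocated growth + idle,
  # or under deficit income = maintenance - catabolic yield.
  if (st$income > 0) {
    surplus <- st$income - st$maint
    spent <- if (surplus >= 0) {
      alloc <- st$Bsyn * (st$qb + st$qr + st$qs)
      idle <- surplus - alloc
      st$maint + alloc + idle
    } else st$maint + surplus
    if (abs(spent - st$income) > tol * max(1, st$income))
      stop("internal energy-balance residual beyond tolerance")
  }
  c(x_b = st$xb, x_r = st$xr, x_s = st$xs, x_k = st$xk)
}

#' Develop a phenotype from a genotype
#'
#' Iterates the developmental map from the fixed newborn phenotype across all
#' age bins. When \code{residentSkill} is omitted the individual is treated
#' as the resident: the peer skill at each age is its own skill at that age,
#' which is already available when the next bin is computed, so no
#' fixed-point iteration is needed.
#'
#' @param genotype a [Genotype-class].
#' @param config a [ScenarioConfig-class] on the same age grid.
#' @param residentSkill optional numeric vector of peer skill (TB) per bin.
#' @return a [Phenotype-class] with per-age energy bookkeeping.
#' @export
develop <- function(genotype, config, residentSkill = NULL) {
  grid <- config@grid
  n <- grid@nBins
  if (nrow(genotype@efforts) != n)
    stop("genotype and config age grids differ in length")
  if (!is.null(residentSkill) && length(residentSkill) != n)
    stop("residentSkill must have one entry per age bin")
  prm <- .asParamList(config)
  Y <- genotype@efforts
  X <- matrix(0, n, 4, dimnames = list(NULL, c("x_b", "x_r", "x_s", "x_k")))
  en <- matrix(0, n, 9, dimnames = list(NULL,
    c("B_rest", "eee", "income", "maint", "B_syn", "q_b", "q_r", "q_s", "idle")))
  X[1, ] <- c(prm$newborn, 0)
  for (a in seq_len(n - 1)) {
    rk <- if (is.null(residentSkill)) X[a, 4] else residentSkill[a]
    st <- .stepCore(X[a, 1], X[a, 2], X[a, 3], X[a, 4],
                    Y[a, 1], Y[a, 2], Y[a, 3], rk, prm)
    X[a + 1, ] <- c(st$xb, st$xr, st$xs, st$xk)
    en[a, ] <- c(st$Brest, st$eee, st$income, st$maint, st$Bsyn,
                 st$qb, st$qr, st$qs, 1 - st$qb - st$qr - st$qs)
  }
  # bookkeeping of the final bin (no successor state)
  rk <- if (is.null(residentSkill)) X[n, 4] else residentSkill[n]
  st <- .stepCore(X[n, 1], X[n, 2], X[n, 3], X[n, 4],
                  Y[n, 1], Y[n, 2], Y[n, 3], rk, prm)
  en[n, ] <- c(st$Brest, st$eee, st$income, st$maint, st$Bsyn,
               st$qb, st$qr, st$qs, 1 - st$qb - st$qr - st$qs)
  new("Phenotype", traits = X, energy = as.data.frame(en), grid = grid)
}

# Vectorized self-resident development of many genotypes at once; used by
# the random-genotype survey. Yb, Yr, Ys are nBins x n matrices. Returns the
# 4 x n phenotype slices at the requested bins.
.developMany <- function(Yb, Yr, Ys, config, keepBins) {
  prm <- .asParamList(config)
  n <- ncol(Yb)
  nb <- prm$nBins
  xb <- rep(prm$newborn[1], n); xr <- rep(prm$newborn[2], n)
  xs <- rep(prm$newborn[3], n); xk <- rep(0, n)
  keep <- vector("list", length(keepBins))
  names(keep) <- as.character(keepBins)
  if (1 %in% keepBins)
    keep[["1"]] <- rbind(x_b = xb, x_r = xr, x_s = xs, x_k = xk)
  for (a in seq_len(nb - 1)) {
    st <- .stepCore(xb, xr, xs, xk, Yb[a, ], Yr[a, ], Ys[a, ], xk, prm)
    xb <- st$xb; xr <- st$xr; xs <- st$xs; xk <- st$xk
    if ((a + 1) %in% keepBins)
      keep[[as.character(a + 1)]] <- rbind(x_b = xb, x_r = xr,
                                           x_s = xs, x_k = xk)
  }
  keep
}

#' Body mass of a phenotype
#'
#' Brain, follicle and somatic tissue contribute to body mass; skill carries
#' no mass.
#'
#' @param x a [Phenotype-class] (returns the per-age body mass) or a numeric
#'   phenotype slice (x_b, x_r, x_s, x_k).
#' @return body mass in kg.
#' @export
setGeneric("bodyMass", function(x) standardGeneric("bodyMass"))

#' @rdname bodyMass
#' @export
setMethod("bodyMass", "numeric", function(x) unname(x[1] + x[2] + x[3]))

#' @rdname bodyMass
#' @export
setMethod("bodyMass", "Phenotype", function(x)
  unname(x@traits[, 1] + x@traits[, 2] + x@traits[, 3]))

#' Classify a developed organism as failed
#'
#' Failed organisms have a small body (under \code{massThreshold} kg,
#' default 200 g) at the adult age that is entirely composed of brain
#' tissue, the signature of decay-dominated development.
#'
#' @param phenotype a [Phenotype-class].
#' @param adultAge adult age in years (default 40); must lie on the grid.
#' @param massThreshold body-mass threshold in kg.
#' @param tol absolute tolerance (kg) for "entirely brain".
#' @return logical flag.
#' @export
classifyFailed <- function(phenotype, adultAge = 40, massThreshold = 0.2,
                           tol = 1e-6) {
  a <- .ageToBin(adultAge, phenotype@grid)
  x <- phenotype@traits[a, ]
  body <- x[1] + x[2] + x[3]
  unname(body < massThreshold && (x[2] + x[3]) <= tol)
}

.ageToBin <- function(age, grid) {
  a <- round(age / grid@binWidth) + 1
  if (a < 1 || a > grid@nBins ||
      abs((a - 1) * grid@binWidth - age) > 1e-8)
    stop("age ", age, " yr does not lie on the age grid")
  as.integer(a)
}
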