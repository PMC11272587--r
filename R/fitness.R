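# Age-structured relative fitness and direct selection.
#
# Fertility is proportional to follicle count (preovulatory follicles do no
# offspring maintenance) and survival is a constant p per age bin. Under
# these assumptions a mutant's relative fitness reduces to
#
#   w = [ sum_j ( p^(j-1) x_rj + sum_{k>j} p^(k-1) xbar_rk ) ]
#       / [ sum_a a p^(a-1) xbar_ra ]
#
# which is affine in the mutant follicle schedule and equals 1 exactly when
# mutant = resident. The fertility proportionality constant cancels.

.fitnessDenominator <- function(residentFollicles, p) {
  n <- length(residentFollicles)
  a <- seq_len(n)
  den <- sum(a * p^(a - 1) * residentFollicles)
  if (den <= 0)
    stop("resident follicle schedule is identically zero: relative fitness ",
         "is undefined (division by zero)")
  den
}

#' Relative fitness of a mutant follicle schedule
#'
#' @param mutantFollicles,residentFollicles follicle count (kg) per age bin,
#'   equal lengths.
#' @param p constant per-bin survival probability in (0, 1).
#' @return dimensionless relative fitness; 1 when mutant equals resident.
#' @export
relativeFitness <- function(mutantFollicles, residentFollicles, p) {
  n <- length(mutantFollicles)
  if (length(residentFollicles) != n)
    stop("mutant and resident schedules must have equal length")
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  den <- .fitnessDenominator(residentFollicles, p)
  disc <- p^(seq_len(n) - 1)
  # sum_j sum_{k>j} p^(k-1) xbar_rk = sum_k (k-1) p^(k-1) xbar_rk
  resTail <- sum((seq_len(n) - 1) * disc * residentFollicles)
  (sum(disc * mutantFollicles) + resTail) / den
}

#' Direct selection gradient over the geno-phenotype
#'
#' Differentiates relative fitness with respect to every mutant phenotypic
#' and genotypic entry while holding development fixed. Fitness contains the
#' mutant only through its follicle schedule, so
#' \code{dw/dx_rj = p^(j-1) / sum_a a p^(a-1) xbar_ra} while every brain,
#' soma, skill and genotypic entry is exactly zero. Direct selection for
#' follicle count is positive at all ages and decays geometrically with age
#' at ratio p (the declining force of selection).
#'
#' @param resident a [Phenotype-class] (or numeric follicle schedule).
#' @param p constant per-bin survival probability.
#' @return a [DirectSelection-class].
#' @export
directSelectionGradient <- function(resident, p) {
  xr <- if (is(resident, "Phenotype")) resident@traits[, 2] else resident
  n <- length(xr)
  den <- .fitnessDenominator(xr, p)
  dwdx <- matrix(0, n, 4, dimnames = list(NULL, c("x_b", "x_r", "x_s", "x_k")))
  dwdx[, 2] <- p^(seq_len(n) - 1) / den
  dwdy <- matrix(0, n, 3, dimnames = list(NULL, c("y_b", "y_r", "y_s")))
  new("DirectSelection", dwdx = dwdx, dwdy = dwdy)
}

#' Forces of selection on fertility and survival
#'
#' Decomposes relative fitness into the classic age-structured form
#' \code{w = (1/T) sum_a (phi_a f_a + pi_a p_a)} with mutant fertility
#' \code{f_a = x_ra} and constant survival \code{p_a = p}. The force of
#' selection on fertility is the survivorship \code{phi_a = p^(a-1)}; the
#' force on survival at age a discounts all later resident reproduction,
#' \code{pi_a = sum_{k>a} p^(k-2) xbar_rk}; the generation-time
#' normalization is \code{T = sum_a a p^(a-1) xbar_ra} (ages in bins). Both
#' forces decline with age. The decomposition reproduces the reduced fitness
#' exactly for any mutant.
#'
#' @param resident a [Phenotype-class] or numeric resident follicle schedule.
#' @param p constant per-bin survival probability.
#' @return list with \code{phi}, \code{pi} (per-age forces) and \code{T}.
#' @export
forcesOfSelection <- function(resident, p) {
  xr <- if (is(resident, "Phenotype")) resident@traits[, 2] else resident
  n <- length(xr)
  Tgen <- .fitnessDenominator(xr, p)
  phi <- p^(seq_len(n) - 1)
  # pi_a = sum_{k > a} p^(k-2) xbar_rk
  disc <- p^(seq_len(n) - 2) * xr
  piv <- rev(cumsum(rev(disc)))            # sum_{k >= a}
  piv <- c(piv[-1], 0)                     # shift to k > a
  list(phi = phi, pi = piv, T = Tgen)
}

#' Reconstruct relative fitness from the forces of selection
#'
#' Evaluates \code{(1/T) sum_a (phi_a f_a + pi_a p_a)} for a mutant follicle
#' schedule; the contract is exact agreement with [relativeFitness()].
#'
#' @param forces output of [forcesOfSelection()].
#' @param mutantFollicles mutant follicle schedule (kg per bin).
#' @param p constant per-bin survival probability.
#' @return dimensionless relative fitness.
#' @export
fitnessFromForces <- function(forces, mutantFollicles, p) {
  (sum(forces$phi * mutantFollicles) + sum(forces$pi * p)) / forces$T
}
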