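# Shared fixtures. Reduced-grid instances keep the finite-difference
# oracles fast; the session-level cache avoids re-developing them per test.

.fix <- new.env()

fixtureToy <- function(nBins = 10, scenario = "sapiens") {
  key <- paste("toy", nBins, scenario)
  if (is.null(.fix[[key]])) .fix[[key]] <- toyConfig(nBins, scenario)
  .fix[[key]]
}

# central finite difference of develop() with respect to one genotypic
# entry, holding the resident (peer) skill fixed at the baseline resident:
# this probes the total effects; self-resident redevelopment would probe
# the stabilized effects instead
fdTotalEffect <- function(gen, config, bin, trait, h = 1e-5) {
  rk <- develop(gen, config)@traits[, 4]
  Yp <- gen@efforts; Ym <- gen@efforts
  Yp[bin, trait] <- Yp[bin, trait] + h
  Ym[bin, trait] <- Ym[bin, trait] - h
  grid <- gen@grid
  xp <- develop(genotype(Yp, grid), config, rk)@traits
  xm <- develop(genotype(Ym, grid), config, rk)@traits
  (xp - xm) / (2 * h)
}

# finite difference of resident fitness w(develop(y)) wrt one genotypic entry,
# holding the resident (denominator and social partners) fixed
fdFitnessGradY <- function(gen, config, bin, trait, h = 1e-5) {
  res <- develop(gen, config)
  rk <- res@traits[, 4]
  Yp <- gen@efforts; Ym <- gen@efforts
  Yp[bin, trait] <- Yp[bin, trait] + h
  Ym[bin, trait] <- Ym[bin, trait] - h
  grid <- gen@grid
  wp <- relativeFitness(develop(genotype(Yp, grid), config, rk)@traits[, 2],
                        res@traits[, 2], config@p)
  wm <- relativeFitness(develop(genotype(Ym, grid), config, rk)@traits[, 2],
                        res@traits[, 2], config@p)
  (wp - wm) / (2 * h)
}

# finite difference of resident fitness wrt a scenario parameter
fdFitnessGradParam <- function(gen, config, parameterId, h = NULL) {
  res <- develop(gen, config)
  rk <- res@traits[, 4]
  val <- slot(config, parameterId)
  if (is.null(h)) h <- max(1e-6, 1e-6 * abs(val))
  cp <- config; slot(cp, parameterId) <- val + h
  cm <- config; slot(cm, parameterId) <- val - h
  wp <- relativeFitness(develop(gen, cp, rk)@traits[, 2],
                        res@traits[, 2], config@p)
  wm <- relativeFitness(develop(gen, cm, rk)@traits[, 2],
                        res@traits[, 2], config@p)
  (wp - wm) / (2 * h)
}
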