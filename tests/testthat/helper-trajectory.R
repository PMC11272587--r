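# Session-cached full-scale runs shared by the acceptance tests. The
# two-stage protocol (afarensis 500 steps from somewhatNaive2, then sapiens
# 500 steps from the evolved genotype) takes a few minutes at the 470-bin
# grid, so it is computed once and reused.

twoStageRun <- function() {
  if (!is.null(.fix$twoStage)) return(.fix$twoStage)
  grid <- ageGrid()
  afar <- scenarioPreset("afarensis")
  sap <- scenarioPreset("sapiens")
  anc <- ancestralGenotype("somewhatNaive2", grid)
  tr1 <- runEvoDevo(anc, evolutionConfig(afar, Tend = 500,
                                         storeL = numeric(0)))
  g2 <- genotype(tr1@genotypes[length(tr1@tau), , ], grid)
  tr2 <- runEvoDevo(g2, evolutionConfig(sap, Tend = 500,
                                        storeL = numeric(0)))
  .fix$twoStage <- list(afar = tr1, sapiens = tr2, grid = grid,
                        afarConfig = afar, sapConfig = sap)
  .fix$twoStage
}
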