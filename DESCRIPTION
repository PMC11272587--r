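Package: evodevoBrain
Title: Evo-Devo Dynamics of Hominin Brain Life History
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mechanistic simulator of hominin life-history development
    (brain, ovarian-follicle, somatic tissue and skill over age) built on
    metabolic energy conservation, coupled to mutation-limited evolutionary
    dynamics of genotypic growth efforts via the canonical equation of
    adaptive dynamics. Exposes the selection-versus-constraint decomposition:
    direct and total selection gradients, developmental sensitivities, and
    the mechanistic socio-genetic covariance matrices that divert selection
    on follicle count into brain expansion. Includes hominin scenario
    presets, ancestral genotype presets, random-genotype allometry surveys
    and life-history diagnostics (encephalization quotient, menarche,
    growth spurts, evolvability, selection angle).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
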