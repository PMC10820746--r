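Package: pppmfa
Title: Bayesian 13C Metabolic Flux Analysis of Glycolysis and the Pentose
    Phosphate Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for 13C metabolic flux analysis (MFA) of upper glucose
    metabolism (glycolysis and the oxidative and non-oxidative pentose
    phosphate pathway) from parallel glucose tracer experiments and GC-EI-MS
    fragment labeling data.  Provides a constrained flux model built from
    stoichiometric dependency analysis, an elementary metabolite unit (EMU)
    simulator of carbon mass distributions with a full-isotopomer reference
    solver, natural-isotope correction of mass isotopomer distributions,
    positional enrichment arithmetic, a Dirichlet measurement likelihood with
    adaptive Markov chain Monte Carlo posterior sampling of fluxes, synthetic
    data generation, precision-score comparison of measurement designs, and
    principal component analysis of flux tables with varimax rotation and
    jackknife validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
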