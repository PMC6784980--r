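Package: sediagen
Title: Transient Early-Diagenesis Modelling of Lake Sediment Oxygen Demand
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-dimensional, multi-component early-diagenesis
    reaction-transport model for lake sediments, built for simulating
    sediment oxygen uptake (SOU), the efflux of reduced substances (F_red)
    and total sediment oxygen demand (SOD) under transient boundary
    conditions.  Twelve solutes and ten solid species are transported by
    molecular diffusion, bioturbation and burial on a stretched grid and
    coupled through a kinetic reaction network: a six-pathway organic-matter
    mineralization cascade with Monod limitation and inhibition, secondary
    redox reactions, and mineral precipitation/dissolution (FeS, pyrite,
    vivianite, MnCO3).  Includes piecewise-linear boundary timelines for a
    eutrophication and re-oligotrophication history, four lake-management
    scenarios, optional seasonal cosine forcing, and diagnostics: interface
    fluxes, Fick's-law flux estimation, O2 penetration depth, production
    attribution by sediment age, element mass balances, parameter
    sensitivity, and a synthetic porewater/TOC observation generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: deSolve, yaml, Rcpp, stats, utils, graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
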