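Package: epirheo
Title: Viscoelastic and Viscoplastic Rheology of an Elongating Epithelium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constitutive models and inference tools for the creep-and-recovery
    rheology of an embryonic epithelium under constant traction. Implements
    closed-form and numerically integrated solutions for Kelvin-Voigt,
    mixed Maxwell/Kelvin-Voigt and ratchet-polymerization (viscoplastic)
    materials under piecewise-constant traction; exponential fitting of
    post-ablation recoil curves with tension/viscosity/stiffness proxies;
    a recoil-ratio-versus-length regression that discriminates the three
    material classes; per-embryo elongation-speed and five-parameter-logistic
    closure-speed estimators; and a seeded synthetic-data generator with
    named genotype presets emulating control and DPP-signaling-mutant
    embryos.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    readr,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
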