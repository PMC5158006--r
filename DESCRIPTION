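Package: lvelast
Title: Myocardial Elasticity from Echocardiography via a Thick-Walled
    Ellipsoidal Left-Ventricle Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the left ventricle as a thick-walled ellipsoidal
    pressure vessel of linear-elastic, isotropic myocardium and recovers
    Young's modulus and Poisson's ratio per subject from routine
    echocardiographic measurements (chamber dimensions, wall thickness,
    e/e' filling-pressure surrogate, and speckle-tracking global strains)
    by minimizing a nonlinear least-squares consistency cost with analytic
    gradients and multi-start search. Includes the classical thick-walled
    cylinder (plane-strain Lame) comparison model with its exact
    two-equation solution, readers and writers for delimited echo cohort
    tables, a seeded synthetic-cohort generator with latent age and
    hypertension effects for parameter-recovery studies, group-comparison
    and age-trend reporting, a forward pressure-thickness exploration, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
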