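Package: headfem
Title: Explicit Finite-Element Simulation of Head Impact Biomechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale finite-element model of the human head for blunt
    impact simulation. Generates a parametric layered skull-CSF-brain
    tetrahedral mesh with quality auditing and smoothing, carries a
    constitutive registry of elastic and one-term Prony viscoelastic brain
    and skeletal tissues, couples the cerebrospinal fluid as a surface-based
    hydrostatic fluid cavity, integrates the equations of motion with an
    explicit central-difference scheme (lumped mass, CFL control, energy
    audit, penalty contact with rigid impactors), and evaluates standard
    head-injury measures: coup/contrecoup intracranial pressure against the
    Ward tolerance thresholds, the Head Injury Criterion (HIC), peak brain
    von Mises stress, peak skull principal stress, and skull-brain relative
    motion at neutral-density-target marker columns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
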