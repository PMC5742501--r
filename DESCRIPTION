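Package: mwablate
Title: Axisymmetric Finite-Element Modelling of Double-Slot Coaxial
    Microwave Ablation Applicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples a time-harmonic axisymmetric electromagnetic solve of a
    double-slot microcoaxial antenna (TM H-phi formulation with a
    power-normalised coaxial port) one-way into a transient Pennes bioheat
    solve on the same triangular mesh. Computes SAR fields, reflection
    coefficient and standing-wave-ratio spectra, temperature histories, and
    55-degree-isotherm lesion metrics for breast-tumour microwave ablation
    scenarios, together with synthetic tissue-dispersion and fibre-optic
    temperature-probe emulators for validation-style testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
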