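Package: tatdose
Title: Dosimetry and Efficacy Analysis for Preclinical Targeted Alpha Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for preclinical targeted alpha-particle therapy
    studies with lead-212 labelled antibodies. Fits rise-and-decay time-activity
    curves to organ biodistribution data, integrates them to cumulated activity
    and converts to absorbed dose with a configurable decay-chain energy model;
    calibrates phosphor-plate autoradiographs against activity standards and
    quantifies region uptake with a significance threshold against healthy
    tissue; computes diffusion-tensor metrics (FA, MD, AD, RD) and fits the
    non-Gaussian diffusion-kurtosis signal model; derives clonogenic survival
    curves with SF2, D50 and surviving-fraction effect ratios; and summarizes
    treatment efficacy (tumor volumetry, baseline normalization, Kaplan-Meier
    survival). Seeded synthetic-data generators reproduce the statistical
    structure of each data stage so the whole pipeline is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
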