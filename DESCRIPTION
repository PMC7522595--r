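Package: corohemo
Title: Coronary and Left-Ventricular Hemodynamics Under Microaxial Pump
    Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing invasive coronary and left-ventricular
    hemodynamics in experiments that contrast no support with maximal
    support from a transaortic microaxial pump in the setting of coronary
    artery dissection. Implements waveform conditioning (anti-aliased
    down-sampling, Savitzky-Golay smoothing, cardiac-cycle detection from
    pressure minima, ensemble averaging of consecutive beats),
    conductance-catheter volume calibration against thermodilution cardiac
    output and echocardiographic end-diastolic volume, pressure-volume
    loop metrics including stroke work as loop area, an angiographic
    contrast-filling delay-time statistic, paired-condition summary
    statistics, and a lumped-parameter time-varying elastance plus
    Windkessel simulator with a pressure-dependent dissection-flap
    resistance that generates paired support-off/support-max recordings
    with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
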