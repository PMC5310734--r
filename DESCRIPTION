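Package: txdrive
Title: Exact Poisson-Mixture Solutions for Gene Transcription with
    Upstream Drives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Solves the chemical master equation for mRNA
    transcription-degradation in single cells whose transcription and
    degradation rates are time-varying, possibly stochastic, upstream
    drives. The full solution is assembled as a Poisson mixture over the
    effective drive, the solution of a linear random differential
    equation. Includes closed-form and numerical mixing densities for
    entrained sinusoidal drives, Kuramoto-coupled promoter populations,
    random telegraph, refractory and modulated promoters; a conservative
    finite-volume solver for the multistate Fokker-Planck-Kolmogorov
    system; ensemble and temporal Fano factor analytics with the
    sinusoidal phase-lag inversion; and exact stochastic simulation
    (thinning) plus truncated-CME oracles and an efficient drive-path
    sampling scheme for population snapshots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
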