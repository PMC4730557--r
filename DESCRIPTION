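Package: rsfa
Title: Resting-State Fluctuation Amplitude, Vascular Scaling of Task fMRI,
    and Mediation Path Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the vascular and neural contributions to the
    BOLD signal in ageing cohorts. Computes the resting-state fluctuation
    amplitude (RSFA) -- the voxelwise standard deviation of nuisance-cleaned,
    band-passed (0.01-0.08 Hz) resting fMRI -- and uses it to scale task
    activation maps so that vascular gain is discounted. Extracts heartbeats
    from physiological waveforms, cleans interbeat intervals with an iterated
    outlier-rejection procedure, computes mean heart rate and LF/HF
    heart-rate-variability spectral power, and reduces them to a principal-
    component vascular index. Computes band-limited variability of
    multichannel sensor recordings, decomposes participant-by-feature
    matrices by MDL-ordered ICA, and fits three-variable mediation path
    models with bias-corrected bootstrap confidence intervals, proportion-
    mediated effect sizes, and mediation-versus-suppression classification.
    A synthetic-cohort generator with known ground truth (latent vascular and
    neural factors, BOLD runs, pulse waveforms, sensor arrays) makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    RNifti,
    ica,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
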