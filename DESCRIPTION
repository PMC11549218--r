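Package: skpatch
Title: Patch-Clamp, Patch-Seq and Behavioral Analysis of SK-Channel
    Dysfunction in Midbrain Dopamine Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Feature extraction and statistics for slice electrophysiology of
    pacemaking midbrain dopamine neurons and the assays that surround it:
    spike and action-current detection, interspike-interval voltage trajectory
    averaging (mAHP, minimum ISI voltage, apparent threshold, spike width),
    voltage-clamp protocol metrics (SK tail-current amplitude and charge,
    frequency-current gain, A-type current bi-exponential inactivation,
    rebound delay, rule-based cell classification), liquid-junction-potential
    calculation by the Henderson equation and a stationary Nernst-Planck
    solver, Patch-seq quality control, normalization, differential expression
    and physiology correlation, per-cell immunofluorescence intensity
    distribution comparison, and operant and locomotor behavioral metrics.  A
    conductance-based pacemaker simulator with a calcium-activated SK
    conductance and a calmodulin-phosphorylation knob, plus generators for
    protocol sweeps, negative-binomial Patch-seq counts and behavioral event
    logs, provide synthetic inputs with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    signal,
    minpack.lm,
    pracma,
    stats,
    utils,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
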