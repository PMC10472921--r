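Package: gastroSync
Title: Stomach-Brain Phase Synchronization from Concurrent EGG and fMRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying phase synchronization between the gastric
    slow wave, recorded with cutaneous electrogastrography (EGG), and the
    fMRI BOLD signal. Implements EGG spectral peak detection and quality
    grading, nuisance regression of BOLD confounds, narrow-band filtering
    and Hilbert phase extraction, the phase-locking value with a
    circular-shift surrogate null, group-level cluster-mass sign-flip
    permutation inference, hemisphere-symmetric spin tests of spatial
    overlap, EGG-confound synchrony analyses, a test-retest reliability
    battery including functional-connectivity fingerprinting, and seeded
    synthetic-cohort generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'bold-prep.R'
    'confound-sync.R'
    'egg.R'
    'filters.R'
    'gastroSync-package.R'
    'group-stats.R'
    'io.R'
    'pipeline.R'
    'reliability.R'
    'sync.R'
    'synthetic.R'
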