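Package: neurostates
Title: Temporally Reoccurring Neural States at Rest and Their Psychological Correlates
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers temporally reoccurring brain states from parcel-level
    resting-state fMRI time series with a group-level Gaussian-observation
    hidden Markov model, hard-classifies state occupancy by Viterbi decoding,
    and summarises each subject's dynamics as mean dwell-times, fractional
    occupancies and switching rates. Dwell-times are related to
    varimax-rotated principal components of retrospective experience reports
    and well-being questionnaires through multivariate analysis of covariance
    (Wilks' Lambda), and state mean-activity maps are projected into a
    three-gradient cortical hierarchy space where a permutation null
    calibrates a weighted distance-sum statistic. A synthetic-data module
    generates Markov-switching Gaussian time series, coupled experience
    reports, motion traces and orthogonal gradient bases so the whole
    pipeline is testable without access to restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'neurostates-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'behaviour.R'
    'association.R'
    'gradients.R'
    'hmm-fit.R'
    'hmm-decode.R'
    'ingest.R'
    'io.R'
    'synth.R'
    'pipeline.R'
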