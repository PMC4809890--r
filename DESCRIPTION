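Package: mantis
Title: Morphologically Adaptive Neonatal Tissue Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tissue classification of brain-extracted T2-weighted neonatal MR
    volumes into eight classes (cortical gray matter, white matter, deep
    nuclear gray matter, CSF, brainstem, cerebellum, hippocampus, amygdala).
    Combines an atlas-prior Gaussian-mixture EM classifier with smooth bias
    correction, marker-controlled watershed adaptation of the CSF prior for
    enlarged ventricles, grayscale reconstruction by dilation to remove
    isolated bright white-matter regions, and topological restoration of
    isolated CSF pockets. Includes NIfTI-1 input/output, overlap and
    surface-distance evaluation metrics, and a deterministic synthetic
    neonatal phantom generator so every stage is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'tissue-table.R'
    'nifti.R'
    'volumes-io.R'
    'morphology.R'
    'classifier.R'
    'metrics.R'
    'phantom.R'
    'pipeline.R'
    'cli.R'
    'mantis-package.R'
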