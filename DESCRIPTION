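Package: cccpheno
Title: Two-Stage Classification and Phenotyping of Circulating Blood-Cell
    Clusters from Multi-Channel Imaging Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing per-event image triplets from multi-channel
    imaging flow cytometry of circulating blood-cell clusters (CCCs): a
    brightfield channel showing cluster morphology plus CD61 (platelet,
    green) and CD45 (leukocyte, yellow) fluorescence channels.  The package
    decides cluster versus non-cluster, delineates the cluster mask on the
    brightfield image with a pluggable segmentation backend (a classical
    Otsu/morphology reference segmenter is included), extracts binary stain
    masks by HSV-range thresholding with a tunable brightness lower bound,
    and assigns a phenotype (RBC, platelet, WBC, or WBC+platelet cluster,
    or excluded staining artifact) from mask-overlap rules.  Includes
    preprocessing and stratified cross-validation fold construction,
    classification and instance-segmentation evaluation metrics (accuracy,
    precision, recall, F1, IoU, AP/mAP over IoU thresholds), a synthetic
    multi-channel record generator with exact ground truth, and a
    command-line driver with a brightness-by-overlap threshold-sweep
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
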