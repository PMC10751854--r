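Package: lafat
Title: Left Atrial Wall Thickness and Intramyocardial Fat Mapping from Cardiac CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies left atrial (LA) intramyocardial fat infiltration from
    contrast-enhanced cardiac CT. Given a Hounsfield-unit calibrated volume and
    endocardial/epicardial LA surface meshes, the package computes wall thickness
    maps, builds the inter-shell wall voxel compartment (excluding the appendage
    and distal pulmonary veins), classifies infiltrated adipose tissue by HU
    thresholds into dense fat and fat-myocardium admixture, parcellates the
    atrium into 19 anatomical segments, and summarises regional fat distribution.
    A synthetic CT phantom generator with known two-shell geometry and planted
    fat deposits provides ground truth for validation, and a cohort statistics
    layer performs the group comparisons (ANOVA/Kruskal-Wallis, Bonferroni
    post-hoc, BMI-adjusted ANCOVA) used in atrial fibrillation imaging studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    igraph,
    car,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
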