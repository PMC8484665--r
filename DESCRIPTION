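Package: pyrenpop
Title: Fine-Scale Population Structure, Genetic Barriers and Demographic
    Inference for Small Valley Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and modelling micro-geographic population
    structure from whole-genome variation in small rural populations, built
    around five valley populations sampled along a ~140 km west-east axis of
    the Spanish Eastern Pyrenees. Provides a coalescent synthetic-data
    generator under a five-population split demography with migration;
    identity-by-state distances, classical multidimensional scaling and a
    Procrustes test against geography; Li-Stephens haplotype painting into a
    coancestry matrix with agglomerative coancestry clustering; a spatial
    model that explains coancestry by per-group anisotropy plus additive
    inter-group genetic barriers, with exhaustive partition search and a
    permutation test; linkage-disequilibrium decay via the HR statistic with
    minor-allele-frequency matching, runs-of-homozygosity detection,
    heterozygosity ratios with resampling normalisation; and approximate
    Bayesian computation with a learned summary regressor for the demographic
    parameters, reporting mean, median, half-range mode, 95% credible
    interval and 89% highest-density interval.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR,
    vegan,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
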