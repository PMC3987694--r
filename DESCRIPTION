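Package: bymscan
Title: Hierarchical Spatial Disease Mapping and Bernoulli Scan Statistics for
    Complex Survey Prevalence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the spatial analysis of binary outcomes measured in
    complex (two-stage stratified cluster) sample surveys. Provides
    design-weighted prevalence estimation with Taylor-linearized variances and
    Rao-Scott corrected tests of association, a principal-components media
    exposure index, Bayesian hierarchical spatial logistic regression
    (Besag-York-Mollie type models with intrinsic CAR structured and iid
    unstructured area effects) fitted by Metropolis-within-Gibbs MCMC with
    DIC-based model comparison and posterior prevalence mapping, and a
    from-scratch Kulldorff-style Bernoulli spatial scan statistic with Monte
    Carlo inference for high- and low-rate cluster detection. A synthetic
    survey generator emulating Demographic and Health Survey designs supplies
    ground-truth data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
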