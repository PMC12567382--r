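Package: nicheweave
Title: Climate-Gradient Analysis of Tick-Host Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how climate gradients shape tick-host
    associations. Monthly climate series are summarised by harmonic
    regression into seasonal predictors; per-taxon climate suitability is
    estimated with an ensemble of distribution models over presences and
    pseudo-absences; realized niches are summarised as convex hulls in
    principal-component space and compared by Jaccard overlap per
    ecosystem; overlap-weighted bipartite tick-host networks are scored
    for nestedness (NODF, weighted NODF) and Barber modularity against
    proportional null models; host phylogenetic diversity (Faith's PD,
    Pagel's lambda) and non-metric multidimensional scaling of overlap
    profiles complete the analysis. A synthetic-data generator with known
    Gaussian niches, harmonic climate fields and Yule phylogenies
    supports parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    e1071,
    glmnet,
    jsonlite,
    MASS,
    mgcv,
    stats,
    utils,
    vegan
Suggests:
    phytools,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
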