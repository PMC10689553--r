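Package: metaboscan
Title: Metabolome-Wide Association Scans with Most Likely Transformation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans a metabolome (a sample-by-metabolite abundance table) for
    associations with one continuous variable of interest, such as age.  Each
    metabolite is modelled by a monotone transformation regression model in
    which the baseline transformation is parameterized by Bernstein
    polynomials and estimated by maximum likelihood (the most likely
    transformation), so that differently scaled, skewed, left-censored
    (limit-of-quantification) and tied measurements are handled in one
    coherent likelihood.  Every metabolite is fitted under two exposure
    metameters (arithmetic and logarithmic), and the resulting 2p marginal
    models are combined by stacked-score multiple-marginal-models covariance
    estimation with single-step max-t adjustment, yielding simultaneous
    confidence intervals and familywise-error-controlled adjusted p-values,
    plus an ordered forest plot of all intervals.  Includes a synthetic-data
    generator with known ground truth, tabular readers (CSV/TSV/XLSX and
    MetaboLights metabolite-assignment tables) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rlang,
    methods,
    stats,
    utils,
    grDevices,
    survival,
    mvtnorm,
    ggplot2,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    readxl,
    yaml,
    jsonlite,
    S4Vectors,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
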