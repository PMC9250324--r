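Package: swimstrat
Title: Search Strategy Classification for Morris Water Maze Swim Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Morris water maze swim trajectories. Encodes
    the pool coordinate system (octants, quadrants, and five analysis zones),
    reads and preprocesses tracking-system exports, computes the traditional
    per-trial measures (platform latency, path distance, swim speed, correct
    quadrant time, platform-zone crossings), and classifies each trial into
    ten ordinal search-strategy categories (A-J) from three parameters:
    effectiveness, initial directionality, and precision. Trajectory changes
    (curves over 90 degrees, zigzag and spiral movements, peripheral seeking
    across octants) are detected from the heading series. Includes a synthetic
    trajectory generator with construction-defined ground truth for validating
    the classifier, and the statistical layer used to compare cohorts:
    strategy pooling with chi-square tests, Cohen's kappa inter-rater
    agreement, Mann-Whitney U, Friedman with Bonferroni correction, and
    Kolmogorov-Smirnov normality checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    nortest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
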