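Package: griffing
Title: Griffing Diallel Analysis for Multi-Environment Half-Diallel Trials
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combining-ability analysis of balanced half-diallel trials laid
    out as randomized complete block designs in one or more environments.
    Implements Griffing Method 2 / Model 1 closed-form estimation of general
    (GCA) and specific (SCA) combining-ability effects, the GCA/SCA partition
    of the genotype sum of squares, per-environment and combined analyses of
    variance with GCA-by-environment and SCA-by-environment terms,
    additive-dominance variance components, Baker's GCA/SCA ratio, broad- and
    narrow-sense heritabilities, mid-parent heterosis and heterobeltiosis with
    their least-significant-difference tests, Fisher LSD mean comparisons with
    compact letter displays, and a fully parameterized synthetic-trial
    generator with known truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
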