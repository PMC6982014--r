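Package: tmtphos
Title: TMT Reporter-Ion Proteome and Phosphoproteome Differential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for isobaric (TMT) labelled proteome and
    phosphoproteome experiments under a multi-condition design: reporter-ion
    quantification of peptide-spectrum matches, unique-peptide ratio
    normalization, median rollup to proteins with one-sample t-tests,
    phosphosite localization filtering and protein-abundance normalization,
    fold-change/p-value differential calling, hypergeometric category
    enrichment with z-score heatmap clustering, physiological summary
    statistics (percent changes and Tukey HSD compact letter displays from
    summary data), and a synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
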