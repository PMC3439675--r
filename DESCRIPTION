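Package: bonb
Title: Bagged Naive Bayes Classification and Biomarker Selection from Genome-Wide SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case/control classification and genetic biomarker selection from
    genome-wide SNP genotype data using an ensemble of categorical Naive Bayes
    classifiers trained on bootstrap replicates (bagging). Each classifier
    selects its attributes with a closed-form univariate Naive Bayes score
    followed by a linkage-disequilibrium-aware multivariate selection step
    driven by out-of-bag Matthews Correlation Coefficient. Significant
    biomarkers are identified by permuting genotype columns in the out-of-bag
    samples and testing the resulting marginal utilities with a one-tailed
    Wilcoxon signed-rank test. Includes readers and writers for PLINK-style
    transposed text genotype files and a TSV matrix dialect, an evaluation
    harness (repeated random sub-sampling cross-validation, precision-recall
    and ROC curves, a chi-squared-filtered standard Naive Bayes baseline,
    parameter sweeps), and a seeded synthetic GWAS generator with LD blocks
    and planted causal SNPs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
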