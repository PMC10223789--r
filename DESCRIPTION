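Package: depnet
Title: Network-Derived Features for Predicting Cancer Gene Dependencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary cancer gene dependencies from network-biology
    features. Builds per-lineage mutual-information coexpression networks
    from expression profiles (with data-processing-inequality pruning and a
    configurable edge-weight cutoff), engineers four classes of per-gene
    network features (classical topology, cancer-hallmark neighbour counts,
    hop-count and smallest-weight paths to Cancer Gene Census genes),
    binarizes CRISPR gene-effect scores at a dependency cutoff, and
    evaluates a ten-model classifier zoo with stratified 5-fold
    cross-validated F1, feature-class and single-feature ablations,
    permutation importance, and hyperparameter sweeps. Includes a synthetic
    data generator with planted feature-to-dependency signal for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    randomForest,
    e1071,
    kernlab,
    rpart,
    class,
    fgsea,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'ablation.R'
    'depnet-package.R'
    'evaluate.R'
    'features.R'
    'io.R'
    'labeling.R'
    'models.R'
    'network-inference.R'
    'pipeline.R'
    'sweeps.R'
    'synthetic.R'
    'utils.R'
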