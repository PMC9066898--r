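#!/usr/bin/env Rscript
# Validate the four-node m6A-related module as a biomarker: restrict the
# 63-sample labelled cohort to the module features, make a stratified 2:1
# train/test split (42/21), fit the linear SVM on training-standardised
# expression, and report both accuracies.

library(m6acerna)

bundle <- "results/synthetic_bundle"
module <- jsonlite::read_json("results/m6a_module.json", simplifyVector = TRUE)
feats <- c(module$lncrna, module$regulator, module$mirna, module$mrna)

params <- simulation_params(seed = 1L)
cohort <- simulate_cohort(params, feats)$profile
ids <- colnames(cohort$values)
sp <- split_cohort(ids, unname(cohort$groups), train_fraction = 2 / 3,
                   seed = 1L)
clf <- train_module_classifier(cohort, feats, sp$train, seed = 1L)
res_train <- evaluate(clf, cohort, sp$train, split = "train")
res_test <- evaluate(clf, cohort, sp$test, split = "test")
print(res_train)
print(res_test)

jsonlite::write_json(
  list(module_features = feats,
       train = res_train[c("split", "n", "correct", "accuracy")],
       test = res_test[c("split", "n", "correct", "accuracy")],
       predictions = rbind(res_train$predictions, res_test$predictions)),
  "results/classifier_results.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
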