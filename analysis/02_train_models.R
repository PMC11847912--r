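#!/usr/bin/env Rscript
# Stage 2: grouped stratified 4:1 split, then train the PROMs MLP, its
# logistic comparator, and the wound-image CNN; fuse per response and
# benchmark discrimination on the held-out partition.

suppressMessages(library(ssitriage))

cohort <- read_cohort("results/cohort")
r <- cohort$responses

split <- grouped_stratified_split(r, seed = 7)
print(split)
train <- split$assignment$partition == "train"

feats <- encode_proms(r[train, ])
mlp <- fit_tabular(feats, r$ssi48[train], kind = "mlp", seed = 11)
logit <- fit_tabular(feats, r$ssi48[train], kind = "logistic")
p_proms <- setNames(predict(mlp, r), r$response_id)

img <- cohort$images
img_resp <- match(img$response_id, r$response_id)
img_y <- r$ssi48[img_resp]
img_train <- which(train[img_resp])
sel <- img_train[ssitriage:::select_training_images(img_y[img_train],
                                                    240, 13)]
cat(sprintf("training CNN on %d images (%d SSI-positive)\n",
            length(sel), sum(img_y[sel])))
train_batch <- ssitriage:::render_image_batch(cohort, img$image_id[sel],
                                              labels = img_y[sel])
cnn <- fit_cnn(train_batch, seed = 11)
print(cnn)

img_pred <- predict_cohort_images(cohort, cnn)
# the stack sees cross-fitted PROMs probabilities (stacked generalisation)
p_proms_oof <- crossfit_proms(r[train, ], r$ssi48[train], seed = 11)
head_fit <- fit_fusion_head(
  p_proms_oof[img_pred$response_id[train[img_resp]]],
  img_pred$p_image[train[img_resp]],
  img_y[train[img_resp]], kind = "logistic_stack", seed = 11)
predictions <- fuse_predictions(p_proms, img_pred, head_fit)

dir.create("results/models", showWarnings = FALSE, recursive = TRUE)
save_model(mlp, "results/models/mlp.json")
save_model(logit, "results/models/logistic.json")
save_model(cnn, "results/models/cnn.json")
save_model(head_fit, "results/models/fusion_head.json")
write_predictions(predictions, "results/predictions.csv")
write.csv(split$assignment, "results/split.csv", row.names = FALSE)

# held-out discrimination, reported in the conventional bands
test_ids <- split$assignment$response_id[!train]
y_test <- r$ssi48[match(test_ids, r$response_id)]
bench <- do.call(rbind, lapply(
  list(mlp_proms = p_proms[test_ids],
       logistic_proms = setNames(predict(logit, r), r$response_id)[test_ids],
       fused = setNames(predictions$p_fused,
                        predictions$response_id)[test_ids]),
  function(s) {
    a <- roc_auc(s, y_test)
    data.frame(auc = a$auc, ci_low = a$ci[1], ci_high = a$ci[2],
               band = discrimination_band(a$auc))
  }))
bench$model <- rownames(bench)
img_test <- !train[img_resp]
if (length(unique(img_y[img_test])) == 2) {
  a <- roc_auc(img_pred$p_image[img_test], img_y[img_test])
  bench <- rbind(bench, data.frame(auc = a$auc, ci_low = a$ci[1],
                                   ci_high = a$ci[2],
                                   band = discrimination_band(a$auc),
                                   model = "cnn_image"))
}
print(bench[, c("model", "auc", "ci_low", "ci_high", "band")], digits = 3)
write.csv(bench, "results/auc_benchmarks.csv", row.names = FALSE)
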