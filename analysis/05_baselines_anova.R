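#!/usr/bin/env Rscript

# Stage 5 — statistical comparisons.
#
# (a) Permutation two-way ANOVA (GROUP x TASK) on each of the 16 gait
#     features, with restricted permutations: group labels shuffled across
#     subjects, task labels within subjects.
# (b) Rank-based comparison of the eleven models' AUC distributions
#     against the NormalW reference, Bonferroni-corrected.
# (c) SVM and shrinkage-LDA baselines on the best model, sharing stratified
#     10-fold assignments (50 repetitions here; the protocol's 500 only
#     lengthens the runtime).

suppressPackageStartupMessages(library(gaitssc))
root_seed <- 1L
features <- read_feature_table("results/features.csv")
rownames(features) <- features$id
groups <- read.csv("results/groups.csv", stringsAsFactors = FALSE)
ssc <- read.csv("results/ssc_models.csv", stringsAsFactors = FALSE)
auc_samples <- lapply(jsonlite::read_json("results/auc_samples.json"),
                      function(v) unlist(v))

grp <- groups$group[match(features$id, groups$id)]

anova_rows <- lapply(stgf_names(), function(f) {
  V <- as.matrix(features[, paste(task_names(), f, sep = "::")])
  a <- permutation_anova2(V, grp, n_perm = 999,
                          seed = derive_seed(root_seed, paste("anova", f)))
  data.frame(feature = f, p_group = a$p[["group"]], p_task = a$p[["task"]],
             p_interaction = a$p[["interaction"]])
})
anova_tab <- do.call(rbind, anova_rows)
write.csv(anova_tab, "results/anova.csv", row.names = FALSE)
cat(sprintf("GROUP effect p <= 0.001 for %d/16 features; TASK for %d/16; %d interaction(s) at p < 0.02\n",
            sum(anova_tab$p_group <= 0.001), sum(anova_tab$p_task <= 0.001),
            sum(anova_tab$p_interaction < 0.02)))

cmp <- compare_model_aucs(auc_samples, reference = "NormalW")
write.csv(cmp, "results/model_comparison.csv", row.names = FALSE)
cat(sprintf("%d of %d models differ significantly from NormalW after Bonferroni\n",
            sum(cmp$significant, na.rm = TRUE), nrow(cmp) - 1))

best <- ssc$model[which.max(ssc$median_auc)]
keep <- groups$id[groups$group %in% c("HE", "MCI-E")]
y <- groups$group[match(keep, groups$id)]
Xb <- select_model_columns(features[match(keep, features$id), ], best)
Xb <- as.matrix(Xb[, setdiff(names(Xb), c("id", "group", "label"))])
bl <- baseline_classifiers(Xb, y, folds = 10, reps = 50,
                           seed = derive_seed(root_seed, "baselines"))
cat(sprintf("Best model %s: SSC median AUC %.3f vs SVM %.3f +/- %.3f, LDA %.3f +/- %.3f\n",
            best, max(ssc$median_auc), bl$svm$mean, bl$svm$sd,
            bl$lda$mean, bl$lda$sd))
write.csv(data.frame(model = best, classifier = c("SVM", "rLDA"),
                     auc_mean = c(bl$svm$mean, bl$lda$mean),
                     auc_sd = c(bl$svm$sd, bl$lda$sd)),
          "results/baselines.csv", row.names = FALSE)
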