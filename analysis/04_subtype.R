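#!/usr/bin/env Rscript
# Identify tumor ecosystem subtypes: keep the gene sets whose NES is
# associated with overall survival (univariate Cox, Wald p < 0.05),
# cluster patients by K-means selecting k in 2..10 by mean silhouette
# width, orient labels so TES 1 is the better-prognosis cluster, and test
# the survival separation with a log-rank test.

suppressMessages(library(tesnet))

nes <- as.matrix(read.delim("results/nes.tsv", row.names = 1,
                            check.names = FALSE))
surv <- read.delim("results/cohort/survival.tsv",
                   stringsAsFactors = FALSE)
surv <- surv[match(rownames(nes), surv$sample_id), ]

filt <- filter_prognostic_genesets(nes, surv, p_threshold = 0.05)
cat("Prognostic filter kept", length(filt$kept), "of", ncol(nes),
    "gene sets (", sum(filt$results$direction[filt$results$kept] == "risk"),
    "risk /", sum(filt$results$direction[filt$results$kept] == "protective"),
    "protective )\n")

fit <- fit_subtypes(nes[, filt$kept, drop = FALSE], k_range = 2:10,
                    n_init = 25, seed = 1, surv = surv)
cat("Selected k =", fit$selected_k, "by mean silhouette:\n")
print(round(fit$silhouette_by_k, 4))
print(table(TES = fit$labels))

lr <- logrank_test(surv, fit$labels)
cat("Log-rank between TESs: chi-square =", round(lr$statistic, 2),
    ", p =", format(lr$p_value, digits = 3), "\n")

truth <- read.delim("results/cohort/true_labels.tsv")
ari <- mclust::adjustedRandIndex(fit$labels,
                                 truth$subtype[match(names(fit$labels),
                                                     truth$sample_id)])
cat("Adjusted Rand index vs planted subtypes:", round(ari, 3), "\n")

write.table(data.frame(sample_id = names(fit$labels),
                       tes_label = unname(fit$labels)),
            "results/tes_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(k = as.integer(names(fit$silhouette_by_k)),
                       mean_silhouette = unname(fit$silhouette_by_k)),
            "results/silhouette_trace.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(filt$results, "results/cox_filter.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
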