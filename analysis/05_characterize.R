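#!/usr/bin/env Rscript
# Contrast the two subtypes: Wilcoxon rank-sum comparison of every gene
# set's NES between TES 1 and TES 2, and differential propagated genes at
# |log2 FC| > 1 and p < 0.05.

suppressMessages(library(tesnet))

nes <- as.matrix(read.delim("results/nes.tsv", row.names = 1,
                            check.names = FALSE))
prop <- as.matrix(read.delim("results/propagated_profile.tsv",
                             row.names = 1, check.names = FALSE))
labels_tab <- read.delim("results/tes_labels.tsv")
labels <- setNames(labels_tab$tes_label, labels_tab$sample_id)

cmp <- compare_features_by_group(nes[names(labels), ], labels)
cat("NES comparisons:", sum(cmp$p_value < 0.05), "of", nrow(cmp),
    "gene sets differ at p < 0.05\n")
print(table(stars = cmp$stars))

dg <- differential_genes(prop[names(labels), ], labels,
                         lfc_threshold = 1.0, p_threshold = 0.05)
cat("Differential propagated genes (|log2FC| > 1, p < 0.05):",
    sum(dg$passes_filter), "of", nrow(dg), "\n")

write.table(cmp, "results/nes_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(dg, "results/differential_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
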