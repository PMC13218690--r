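#!/usr/bin/env Rscript
# Score each propagated profile against the ecosystem gene sets with
# ssGSEA (alpha = 0.25) and normalize the raw scores by the global range
# to obtain NES. Writes results/nes.tsv.

suppressMessages(library(tesnet))

prop <- as.matrix(read.delim("results/propagated_profile.tsv",
                             row.names = 1, check.names = FALSE))
genesets <- read_gmt("results/cohort/genesets.gmt")

nes <- normalize_nes(ssgsea_matrix(prop, genesets, alpha = 0.25))

cat("NES matrix:", nrow(nes), "samples x", ncol(nes), "gene sets\n")
cat("Global normalization constant (raw ES range):",
    round(attr(nes, "normalization_constant"), 4), "\n")
cat("NES range:", round(min(nes), 4), "to", round(max(nes), 4), "\n")

write.table(cbind(sample_id = rownames(nes), as.data.frame(nes)),
            "results/nes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
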