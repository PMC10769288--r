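#!/usr/bin/env Rscript
# QC and normalization of the synthetic cortical section, HVG selection, and
# re-derivation of the A/B/C identity-gene panel from the planted labels.
# Run analysis/01_simulate.R first.

suppressMessages(library(l23continuum))

sec <- read_count_matrix("scratch/data/section")
truth <- readRDS("scratch/data/section_truth.rds")
gs <- truth$gene_sets

message("-- first-pass QC (volume 50-2000, > 10 transcripts, < 5% blanks)")
m <- qc_filter_cells(sec, volume_range = c(50, 2000), min_transcripts = 10,
                     max_blank_rate = 0.05)
message(sprintf("kept %d / %d cells", nrow(m$counts), nrow(sec$counts)))

message("-- stricter pass (> 50 transcripts) for type-level analyses")
m50 <- qc_filter_cells(m, min_transcripts = 50)
message(sprintf("kept %d cells at > 50 transcripts", nrow(m50$counts)))

message("-- MERFISH normalization (mean 250 per sample, IEGs excluded)")
nm <- normalize_merfish(m, target_mean = 250, exclude = gs$iegs)
for (p in nm$provenance) message("   ", p)

message("-- HVG selection (decile bins, top 30% variance/mean)")
hvgs <- select_hvgs(m, min_cells = 10, n_bins = 10, top_fraction = 0.30)
message(sprintf("%d HVGs selected out of %d genes", length(hvgs),
                length(m$gene_ids)))
writeLines(hvgs, "results/02_hvgs.txt")

message("-- identity markers (Wilcoxon one-vs-rest, FC > 2, FDR < 0.05, > 30% expressed)")
l23 <- m$cell_meta$subclass == "L23"
types <- truth$cell_table$type_true[match(m$cell_ids, truth$cell_table$cell_id)]
mk <- derive_identity_genes(subset_cells(m, which(l23)), types[l23])
markers <- mk[mk$marker, c("gene", "type", "fc", "fdr", "frac_in")]
write.table(mk, "results/02_identity_marker_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("%d marker calls across types", nrow(markers)))

# how well does the re-derived panel recover the planted identity sets?
planted <- list(A = gs$identity_A, B = gs$identity_B, C = gs$identity_C)
rec <- vapply(names(planted), function(ty) {
  got <- markers$gene[markers$type == ty]
  mean(planted[[ty]] %in% got)
}, numeric(1))
qc_tab <- data.frame(type = names(planted),
                     planted_genes = lengths(planted),
                     recovered_fraction = round(rec, 3))
write.csv(qc_tab, "results/02_marker_recovery.csv", row.names = FALSE)
print(qc_tab)

saveRDS(list(m = m, m50 = m50, nm = nm, types = types),
        "scratch/data/02_preprocessed.rds")
message("wrote scratch/data/02_preprocessed.rds")
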