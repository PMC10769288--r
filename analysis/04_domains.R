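#!/usr/bin/env Rscript
# Spatial-domain clustering of the section on the hybrid (expression +
# space) graph, and kNN label transfer between halves of the data as a
# stand-in for cross-modality transfer. Run 01-03 first.

suppressMessages(library(l23continuum))

pre <- readRDS("scratch/data/02_preprocessed.rds")
truth <- readRDS("scratch/data/section_truth.rds")
m <- pre$m; nm <- pre$nm

message("-- hybrid spatial+expression graph (equal weighting), Leiden")
pc <- pca_identity(nm$z, n_components = 20)$scores
coords <- cbind(m$cell_meta$x_um, m$cell_meta$y_um)
g <- build_hybrid_graph(pc, coords, k = 15, blend_weight = 0.5)
cl <- cluster_domains(g, resolution = 1, seed = 201)
subclass <- truth$cell_table$subclass[match(m$cell_ids,
                                            truth$cell_table$cell_id)]
tab <- table(domain = cl, subclass = subclass)
purity <- sum(apply(tab, 1, max)) / sum(tab)
message(sprintf("%d spatial domains; laminar purity %.3f",
                length(unique(cl)), purity))
write.csv(as.data.frame.matrix(tab), "results/04_domain_by_subclass.csv")

message("-- kNN label transfer (reference half -> query half)")
set.seed(202)
idx <- sample(nrow(pc), round(0.5 * nrow(pc)))
lab <- transfer_labels(pc[idx, ], subclass[idx], pc[-idx, ], k = 30,
                       min_ref_neighbors = 2)
acc <- mean(lab == subclass[-idx], na.rm = TRUE)
message(sprintf("subclass transfer accuracy %.3f (%.1f%% abstained)",
                acc, 100 * mean(is.na(lab))))
transfer_tab <- data.frame(metric = c("accuracy", "abstention_rate",
                                      "n_query"),
                           value = c(acc, mean(is.na(lab)),
                                     length(lab)))
write.csv(transfer_tab, "results/04_label_transfer.csv", row.names = FALSE)

saveRDS(list(domains = cl, transfer = lab, holdout = idx),
        "scratch/data/04_domains.rds")
message("wrote scratch/data/04_domains.rds")
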