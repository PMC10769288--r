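#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses use:
#   (a) a 1-D latent expression continuum (600 cells x 60 genes, scaled
#       Poisson), (b) three discrete marker types with leaky expression and
#       chained shared markers, (c) a triangular archetype mixture, and
#   (d) a curved cortical section with pial anchors, laminar subclasses,
#       depth-graded A/B/C identity programs, a V1 marker interval, and a
#       planted IEG upshift in the dark-reared samples.
# Raw matrices go to scratch/data (regenerable); summary tables to results/.

suppressMessages(library(l23continuum))

out_data <- "scratch/data"
dir.create(out_data, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

message("-- continuum simulator (Nc = 600, Ng = 60, s = 100, eps = 0.2)")
cont <- simulate_continuum(n_cells = 600, n_genes = 60, epsilon = 0.2,
                           scale = 100, seed = 101)
write_count_matrix(cont$matrix, file.path(out_data, "continuum"))
saveRDS(cont$truth, file.path(out_data, "continuum_truth.rds"))

message("-- discrete-type simulator (3 types x 20 markers x 200 cells, 6 shared)")
disc <- simulate_discrete_types(n_types = 3, markers_per_type = 20,
                                cells_per_type = 200, shared_markers = 6,
                                epsilon = 0.1, scale = 100, seed = 102)
write_count_matrix(disc$matrix, file.path(out_data, "discrete"))
saveRDS(disc$truth, file.path(out_data, "discrete_truth.rds"))

message("-- archetype mixture (uniform Dirichlet over 3 profiles)")
mix <- simulate_archetype_mixture(n_cells = 600, n_genes = 60, scale = 100,
                                  seed = 103)
write_count_matrix(mix$matrix, file.path(out_data, "mixture"))
saveRDS(mix$truth, file.path(out_data, "mixture_truth.rds"))

message("-- cortical section emulator (4 samples: 2 NR + 2 DR)")
spec <- spatial_section_spec(seed = 104)
sec <- simulate_cortical_section(spec)
write_count_matrix(sec$matrix, file.path(out_data, "section"))
saveRDS(sec$truth, file.path(out_data, "section_truth.rds"))
saveRDS(spec, file.path(out_data, "section_spec.rds"))
jsonlite::write_json(sec$truth$planted_effects,
                     file.path(out_data, "section_planted.json"),
                     auto_unbox = TRUE, digits = NA)

summary_tab <- data.frame(
  dataset = c("continuum", "discrete", "mixture", "section"),
  cells = c(nrow(cont$matrix$counts), nrow(disc$matrix$counts),
            nrow(mix$matrix$counts), nrow(sec$matrix$counts)),
  genes = c(ncol(cont$matrix$counts), ncol(disc$matrix$counts),
            ncol(mix$matrix$counts), ncol(sec$matrix$counts)),
  mean_total_counts = round(c(mean(rowSums(cont$matrix$counts)),
                              mean(rowSums(disc$matrix$counts)),
                              mean(rowSums(mix$matrix$counts)),
                              mean(rowSums(sec$matrix$counts))), 1))
write.csv(summary_tab, "results/01_simulation_summary.csv", row.names = FALSE)
message("wrote results/01_simulation_summary.csv")
print(summary_tab)
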