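#!/usr/bin/env Rscript
# Curved cortical coordinates: fit the pial curve from anchor cells, assign
# depth/tangential coordinates, locate V1 from the marker pair, normalize
# tangential coordinates, and profile identity genes along depth.
# Run 01 and 02 first.

suppressMessages(library(l23continuum))

pre <- readRDS("scratch/data/02_preprocessed.rds")
truth <- readRDS("scratch/data/section_truth.rds")
gs <- truth$gene_sets
m <- pre$m; nm <- pre$nm

message("-- pial curve from anchor (VLMC-like) cells")
cells <- spatial_cell_table(m, anchor_gene = gs$anchor)
fit <- fit_pial_surface(cells, max_iter = 10, prune_fraction = 0.5)
message(sprintf("retained %d anchors", attr(fit, "n_anchors_retained")))
planted <- truth$planted_effects$pial_curve_coeffs
xs <- seq(attr(fit, "domain")[1], attr(fit, "domain")[2], length.out = 200)
dev <- max(abs(l23continuum:::polyval(as.numeric(fit), xs) -
                 l23continuum:::polyval(planted, xs)))
message(sprintf("max deviation from the planted curve: %.2f um", dev))
jsonlite::write_json(list(coefficients = as.numeric(fit),
                          domain = attr(fit, "domain"),
                          max_deviation_um = dev),
                     "results/03_pial_curve.json", auto_unbox = TRUE,
                     digits = NA)

message("-- depth / tangential coordinates")
frame <- assign_cortical_coordinates(cells, fit)
tt <- truth$cell_table[match(frame$cell_id, truth$cell_table$cell_id), ]
message(sprintf("depth correlation vs latent truth: %.5f",
                cor(frame$depth_um, tt$depth_true)))

message("-- locating V1 from the enrichment/depletion marker pair")
v1 <- locate_v1(frame, nm$lognorm[, gs$v1_on], nm$lognorm[, gs$v1_off],
                smoothing_um = 100)
message(sprintf("V1 interval: %.0f - %.0f um (planted %.0f - %.0f)",
                v1[1], v1[2], truth$planted_effects$v1_interval[1],
                truth$planted_effects$v1_interval[2]))
frame <- normalize_tangential(frame, v1)
write.csv(frame, "scratch/data/03_cortical_frame.csv", row.names = FALSE)
jsonlite::write_json(list(tm = v1[["tm"]], tl = v1[["tl"]],
                          width_um = diff(v1),
                          frac_in_v1 = mean(frame$tangent_norm >= 0 &
                                              frame$tangent_norm <= 1)),
                     "results/03_v1_interval.json", auto_unbox = TRUE,
                     digits = NA)

message("-- identity-gene expression profiles along cortical depth")
l23_depth <- range(tt$depth_true[tt$subclass == "L23"])
profs <- lapply(list(A = gs$identity_A, B = gs$identity_B,
                     C = gs$identity_C), function(g)
  depth_expression_profile(frame, nm, g, n_bins = 15,
                           depth_range = c(50, 400)))
prof_tab <- do.call(rbind, Map(function(p, nmn) cbind(set = nmn, p),
                               profs, names(profs)))
write.csv(prof_tab, "results/03_depth_profiles.csv", row.names = FALSE)
peaks <- vapply(profs, function(p) p$bin_mid_um[which.max(p$mean)],
                numeric(1))
message("profile peaks (um): ", paste(names(peaks), round(peaks),
                                      sep = "=", collapse = ", "),
        "  (planted centers: ",
        paste(truth$planted_effects$abc_gradient_centers, collapse = ", "),
        ")")

saveRDS(list(frame = frame, v1 = v1), "scratch/data/03_geometry.rds")
message("wrote scratch/data/03_geometry.rds")
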