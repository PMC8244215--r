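#!/usr/bin/env Rscript

# Stage 2: behavioural segmentation and habitat selection. Separates
# territorial from exploratory fixes with a-LoCoH home ranges, builds
# the used/available table from the exploratory fixes (3x3-window used
# composition versus the GPD-distance-weighted available composition in
# the 99th-percentile displacement radius), fits the point selection
# function, cross-validates its AUC, and writes the predicted
# conductance surface. Requires results/simulation/ from stage 01.

suppressPackageStartupMessages(library(rspaths))

in_dir <- "results/simulation"
out_dir <- "results/habitat"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

fixes <- read_fixes_csv(file.path(in_dir, "fixes.csv"))
classes <- sub("^landcover_", "",
               sub("\\.asc$", "",
                   list.files(in_dir, pattern = "^landcover_.*\\.asc$")))
layers <- lapply(classes, function(cl)
  read_raster_asc(file.path(in_dir, paste0("landcover_", cl, ".asc"))))
names(layers) <- classes
stack <- structure(list(layers = layers, classes = classes,
                        res = layers[[1]]$res),
                   class = "landcover_stack")

# behavioural segmentation per animal (territorial animals only; the
# simulated exploratory animals are single trajectories by design)
terr_ids <- grep("^terr_", unique(fixes$animal_id), value = TRUE)
seg_summary <- do.call(rbind, lapply(terr_ids, function(a) {
  fx <- fixes[fixes$animal_id == a, ]
  hr <- alocoh_home_range(fx, a_param = "auto", isopleth = 0.95)
  lab <- classify_fixes(fx, hr)
  data.frame(animal_id = a, n = nrow(fx),
             territorial = sum(lab == "territorial"),
             exploratory = sum(lab == "exploratory"))
}))
message("a-LoCoH segmentation of territorial animals:")
print(seg_summary, row.names = FALSE)

expl <- fixes[fixes$behavior_truth == "exploratory", ]
# displacement scale of exploratory movement -> availability radius
radius <- displacement_percentile(expl, q = 0.99)
gpd <- fit_gpd(rspaths:::consecutive_steps(expl))
message(sprintf("availability radius (q99 displacement): %.0f m", radius))
message(sprintf("gpd distance weights: xi = %.3f, sigma = %.0f",
                gpd$xi, gpd$sigma))

# the psf is fitted on a thinned sample of exploratory fixes (every 3rd
# fix) to keep the stage quick; the estimate is stable at this size
psf_fixes <- expl[seq(1, nrow(expl), by = 3), ]
tab <- build_used_available_table(psf_fixes, stack, radius, gpd)
fit <- fit_psf(tab, reference_class = "class_A")
message("fitted selection coefficients (reference class_A):")
print(psf_coefficients(fit), row.names = FALSE)

auc_cv <- crossvalidate_psf(tab, k = 10, seed = 1,
                            reference_class = "class_A")
auc_sp <- crossvalidate_psf(tab, k = 10, spatial = TRUE, seed = 1,
                            reference_class = "class_A")
message(sprintf("AUC: %.3f (10-fold), %.3f (spatial)", auc_cv, auc_sp))

cond <- predict_conductance(fit, stack)
true_cond <- read_raster_asc(file.path(in_dir, "conductance_true.asc"))
message(sprintf("predicted vs true conductance: r = %.3f",
                surface_correlation(cond, true_cond)$r))

psf_coefficients(fit, file.path(out_dir, "psf_coefficients.csv"))
utils::write.csv(data.frame(metric = c("auc_10fold", "auc_spatial",
                                       "radius_m", "gpd_xi", "gpd_sigma"),
                            value = c(auc_cv, auc_sp, radius, gpd$xi,
                                      gpd$sigma)),
                 file.path(out_dir, "habitat_metrics.csv"),
                 row.names = FALSE)
write_raster_asc(cond, file.path(out_dir, "conductance_fitted.asc"))
message("wrote ", out_dir)
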