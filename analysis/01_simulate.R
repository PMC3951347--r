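#!/usr/bin/env Rscript
# Stage 1: synthesize the study landscape and kill sites.
#
# Generates the elongated island (544 km2 with inner lakes), six habitat
# rasters, and the two kill-site classes: class_a ("prime-like") in many
# small near-shore clusters with canopy-positive / conifer-negative habitat
# preference, and class_b ("senescent-like") concentrated in one inland
# high-elevation / high-conifer zone. Writes all products under
# results/synthetic/.

source("analysis/00_config.R")

cfg <- analysis_config()
syn <- cfg$synthetic

region <- generate_island(killzones:::stage_seed(cfg$seed, 1L),
                          target_area = syn$target_area_km2 * 1e6)
cat(sprintf("island: %.1f km2, %d lakes, bbox %.1f x %.1f km\n",
            region$area / 1e6, length(region$lakes),
            diff(region_bbox(region)[1:2]) / 1000,
            diff(region_bbox(region)[3:4]) / 1000))

fields <- generate_habitat_fields(region, cell_size = syn$cell_size_m,
                                  field_params = syn$field_params,
                                  seed = killzones:::stage_seed(cfg$seed, 2L))
print(fields)

write_region_geojson(region, file.path(OUT, "synthetic", "region.geojson"))
for (layer in names(fields$layers))
  write_ascii_grid(fields, layer,
                   file.path(OUT, "synthetic", paste0(layer, ".asc")))

pats <- list()
k <- 3L
for (cl in names(syn$classes)) {
  cc <- syn$classes[[cl]]
  tr <- sim_truth(cc$beta, cc$n_points, cc$cluster,
                  seed = killzones:::stage_seed(cfg$seed, k))
  pats[[cl]] <- simulate_kill_sites(fields, tr, cl)
  cat(sprintf("%s (%s): %d kill sites\n", cl, cc$display, pats[[cl]]$n))
  k <- k + 1L
}
all_pts <- point_pattern(unlist(lapply(pats, `[[`, "x")),
                         unlist(lapply(pats, `[[`, "y")),
                         unlist(lapply(pats, `[[`, "labels")), region)
write_points_csv(all_pts, file.path(OUT, "synthetic", "points.csv"))
write_points_geojson(all_pts, file.path(OUT, "synthetic", "points.geojson"))
cat("stage 1 products written to", file.path(OUT, "synthetic"), "\n")
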