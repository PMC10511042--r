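#!/usr/bin/env Rscript
# Generates the four synthetic datasets the downstream analyses consume:
# a 3:1 rounding mask movie (with a fusion-jump variant), a 3D+t nuclei
# movie with mixed coherent/independent motion, a hexagonal junction
# image, and a spheroid-doublet fusion movie. Images go to scratch/data/
# (regenerable, not part of the repository); ground truth and metadata go
# with them as CSV/JSON.

suppressMessages(library(spheromorph))

data_dir <- "scratch/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260101L

## Rounding: elongated 3:1 mass, latent to 5 h, rising to 18 h
kin <- rounding_kinetics(c_inf = 0.95, t_latent = 5, t_static = 18)
g_round <- generate_rounding_movie(3, kin, frames = 25, interval_h = 1,
                                   seed = seed)
write_movie_tiff(g_round$movie, file.path(data_dir, "rounding.tif"))
write_ground_truth(g_round$truth, g_round$meta, data_dir, "rounding")

kin_j <- rounding_kinetics(c_inf = 0.8, t_latent = 5, t_static = 18,
                           jumps = data.frame(time_h = 10, delta = 0.15))
g_jump <- generate_rounding_movie(3, kin_j, frames = 25, interval_h = 1,
                                  seed = seed)
write_movie_tiff(g_jump$movie, file.path(data_dir, "rounding_jump.tif"))
write_ground_truth(g_jump$truth, g_jump$meta, data_dir, "rounding_jump")
cat(sprintf("rounding movies: %d frames, initial circularity %.3f\n",
            25, g_round$truth$circularity[1]))

## Nuclei: 30 cells, half moving as coherent pairs, 15 h at 0.25 h/frame
mm <- motion_model("mixture", n_cells = 30, step_scale = 3,
                   mixture_weight = 0.5)
g_nuc <- generate_nuclei_movie(mm, shape = c(24, 130, 130), frames = 60,
                               snr = 5, seed = seed, interval_h = 0.25)
write_movie_tiff(g_nuc$movie, file.path(data_dir, "nuclei.tif"))
write_ground_truth(g_nuc$truth, g_nuc$meta, data_dir, "nuclei")
cat(sprintf("nuclei movie: %d coherent of %d pairs, SNR 5\n",
            sum(g_nuc$truth$pairs$coherent), nrow(g_nuc$truth$pairs)))

## Junctions: hexagonal epithelium with PA spots on the borders
g_junc <- generate_junction_image(n_cells = 12,
                                  pa_spec = list(n = 8, length_px = 10),
                                  side = 20, seed = seed)
for (ch in names(g_junc$channels)) {
  write_movie_tiff(array(g_junc$channels[[ch]],
                         dim = c(dim(g_junc$channels[[ch]]), 1)),
                   file.path(data_dir, sprintf("junction_%s.tif", ch)))
}
jt <- g_junc$truth
saveRDS_free <- list(tj_length_px = jt$tj_length_px, n_cells = jt$n_cells,
                     pa_lengths_px = jt$pa_lengths_px)
jsonlite::write_json(saveRDS_free, file.path(data_dir, "junction_truth.json"),
                     auto_unbox = TRUE, digits = NA)
utils::write.csv(as.data.frame(jt$edges),
                 file.path(data_dir, "junction_edges.csv"), row.names = FALSE)
cat(sprintf("junction image: %d cells, %.0f px of programmed TJ edge\n",
            jt$n_cells, jt$tj_length_px))

## Fusion: equal 30 px spheroids, linear neck growth 6 px/h
g_fus <- generate_fusion_movie(radii = c(30, 30), neck_growth = list(rate = 6),
                               frames = 16, interval_h = 0.5, seed = seed)
write_movie_tiff(g_fus$movie, file.path(data_dir, "fusion.tif"))
write_ground_truth(g_fus$truth, g_fus$meta, data_dir, "fusion")
cat(sprintf("fusion movie: %d frames, doublet starts at %.0f px\n",
            16, g_fus$truth$doublet_length_px[1]))
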