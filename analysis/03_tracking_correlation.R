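#!/usr/bin/env Rscript
# Nuclei tracking and neighbor displacement-direction correlation on the
# synthetic 3D+t movie: DoG detection, nearest-neighbor linking, pair
# correlation table, time-resolved r density, and the coordinated
# fraction (r > 0.8) in the 6-9 h window.

suppressMessages({
  library(spheromorph)
  library(ggplot2)
})

data_dir <- "scratch/data"
res_dir <- "results"
dir.create(file.path(res_dir, "figures"), showWarnings = FALSE,
           recursive = TRUE)

movie <- read_movie_tiff(file.path(data_dir, "nuclei.tif"), nz = 24)
meta <- jsonlite::read_json(file.path(data_dir, "nuclei_meta.json"))
truth <- utils::read.csv(file.path(data_dir, "nuclei_positions.csv"))
interval_h <- meta$meta$interval_h

trk <- track_nuclei(movie, max_link_dist = 6)
utils::write.csv(trk$detections, file.path(res_dir, "detections.csv"),
                 row.names = FALSE)
utils::write.csv(trk$trajectories, file.path(res_dir, "trajectories.csv"),
                 row.names = FALSE)

sc <- detection_scores(trk$detections, truth, radius = 2.5)
acc <- link_accuracy(trk$trajectories, truth)
cat(sprintf("detection: precision %.3f, recall %.3f; link accuracy %.3f\n",
            sc$precision, sc$recall, acc))

tab <- pair_correlations(trk$trajectories, interval_h = interval_h)
utils::write.csv(tab, file.path(res_dir, "pairs.csv"), row.names = FALSE)
rec <- pair_r_recovery(tab, trk$trajectories, truth)
cat(sprintf("pair r: %d neighbor-pair records, MAE vs ground truth %.3f\n",
            nrow(tab), rec$mae))

dens <- correlation_density(tab, r_bins = 40, t_bin_h = 1)
utils::write.csv(as.data.frame(unclass(dens)),
                 file.path(res_dir, "density.csv"), row.names = FALSE)

frac <- fraction_above(tab, r_min = 0.8, window = c(6, 9))
cat(sprintf("coordinated fraction (r > 0.8, 6-9 h): %.3f\n", frac))
jsonlite::write_json(list(fraction_above_0p8_6_9h = frac,
                          pair_r_mae = rec$mae,
                          detection_precision = sc$precision,
                          detection_recall = sc$recall,
                          link_accuracy = acc),
                     file.path(res_dir, "correlation_summary.json"),
                     auto_unbox = TRUE, digits = NA)

dd <- data.frame(
  r = rep(head(attr(dens, "r_breaks"), -1) + diff(attr(dens, "r_breaks")) / 2,
          ncol(dens)),
  t = rep(head(attr(dens, "t_breaks"), -1), each = nrow(dens)),
  density = as.vector(dens)
)
p <- ggplot(dd, aes(t, r, fill = density)) +
  geom_tile() +
  scale_fill_viridis_c() +
  labs(x = "time (h)", y = "displacement correlation r",
       title = "Neighbor-pair direction correlation over time") +
  theme_minimal()
ggsave(file.path(res_dir, "figures", "correlation_density.png"), p,
       width = 6, height = 4, dpi = 150)

ph <- ggplot(tab, aes(r)) +
  geom_histogram(bins = 40, boundary = -1) +
  labs(x = "displacement correlation r", y = "pair-frame count",
       title = "Bimodal structure: coherent mode at +1 over a flat background") +
  theme_minimal()
ggsave(file.path(res_dir, "figures", "correlation_histogram.png"), ph,
       width = 6, height = 4, dpi = 150)
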