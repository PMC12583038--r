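#!/usr/bin/env Rscript
# Generates the synthetic study data every later analysis step consumes:
#  * 2 x 12 single-frame cell images (consolidated vs fragmented vacuome)
#    for the morphology analysis,
#  * a 2 x 12 set of 61-frame single-cell movies (slow vs fast membrane
#    motion, emulating a motility-impaired mutant vs wild type),
#  * one drifting movie pair for the registration demonstration.
# Images go to scratch/ (TIFF), tables and ROIs to results/sim/.

suppressMessages(library(tonodyn))

seed <- 20260925L
out_tab <- "results/sim"; out_img <- "scratch/sim"
dir.create(out_tab, recursive = TRUE, showWarnings = FALSE)
dir.create(out_img, recursive = TRUE, showWarnings = FALSE)

op <- optics_spec()  # 0.11 um/px, 16-bit-like scale, shot + read noise

message("-- morphology frames: 12 cells per vacuome preset")
geom <- list()
for (preset in c("consolidated", "fragmented")) {
  cells <- generate_cell_population(12, preset, seed = seed)
  for (i in seq_along(cells)) {
    fr <- render_frame(list(cells[[i]]), op, seed = seed + 100 + i)
    mv <- tono_movie(fr$image, pixel_size_um = op$pixel_size_um)
    write_movie_tiff(mv, file.path(out_img,
                                   sprintf("morph_%s_%02d.tif", preset, i)))
    geom[[length(geom) + 1]] <- synth_roi(cells[[i]])
  }
  tab <- population_table(cells)
  utils::write.csv(tab, file.path(out_tab,
                                  sprintf("cells_%s.csv", preset)),
                   row.names = FALSE)
}
write_rois(geom, file.path(out_tab, "morphology_rois.json"))

message("-- motility movies: 12 cells x {slow 0.3, fast 1.5} px/frame")
speed_groups <- c(slow = 0.3, fast = 1.5)
roi_rows <- list()
for (g in names(speed_groups)) {
  for (i in 1:12) {
    cells <- generate_cell_population(
      1, "fragmented", seed = seed + 1000 * match(g, names(speed_groups)) + i,
      condition_label = g)
    mo <- motion_spec(n_frames = 61, frame_interval_s = 2,
                      membrane_speed = speed_groups[[g]],
                      seed = seed + 2000 * match(g, names(speed_groups)) + i)
    sim <- simulate_timelapse(cells, op, mo)
    write_movie_tiff(sim$movie,
                     file.path(out_img, sprintf("motility_%s_%02d.tif", g, i)))
    roi <- synth_roi(cells[[1]])
    roi_rows[[length(roi_rows) + 1]] <- roi
    write_rois(list(roi),
               file.path(out_tab, sprintf("motility_%s_%02d_roi.json", g, i)))
  }
}

message("-- drift demo: motionless cell with 1 px/frame growth drift")
cells <- generate_cell_population(1, "fragmented", seed = seed + 5000)
mo <- motion_spec(n_frames = 61, membrane_speed = 0,
                  drift_per_frame = c(1, 0, 0), seed = seed + 5001)
sim <- simulate_timelapse(cells, op, mo, dim = c(190, 150))
write_movie_tiff(sim$movie, file.path(out_img, "drift_demo.tif"))
write_rois(list(synth_roi(cells[[1]])),
           file.path(out_tab, "drift_demo_roi.json"))
write_ground_truth(sim$truth, file.path(out_tab, "drift_demo_truth"))

message("done: images under ", out_img, ", tables under ", out_tab)
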