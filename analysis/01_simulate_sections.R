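#!/usr/bin/env Rscript
# Step 1 — simulate cross-section images.
#
# Renders one section of each of the five shank shapes (round, crescent,
# bell, horseshoe, irregular) plus a batch of round sections that stand
# in for repeated acquisitions, and writes 8-bit PNGs with their
# ground-truth JSON next to them. Everything downstream reads these
# files, so the whole workflow runs from disk exactly as it would on
# real scans.

suppressMessages(library(shankvb))

out_dir <- "results/sections"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

shapes <- c("round", "crescent", "bell", "horseshoe", "irregular")
for (i in seq_along(shapes)) {
  sc <- generate_cross_section(section_shape_spec(shapes[i]),
                               bundle_spec(), seed = 100 + i)
  write_section_png(sc$image, file.path(out_dir,
                                        sprintf("shape_%s.png", shapes[i])))
  write_ground_truth_json(sc$truth, file.path(out_dir,
                                              sprintf("shape_%s.json", shapes[i])))
  cat(sprintf("%-10s %4d bundles, section %.1f mm^2\n", shapes[i],
              nrow(sc$truth$bundles),
              sc$truth$section_area_px * (sc$truth$resolution / 1000)^2))
}

# batch of round sections (different seeds = different sections)
for (s in 1:6) {
  sc <- generate_cross_section(section_shape_spec("round"),
                               bundle_spec(), seed = s)
  write_section_png(sc$image, file.path(out_dir, sprintf("batch_%02d.png", s)))
  write_ground_truth_json(sc$truth,
                          file.path(out_dir, sprintf("batch_%02d.json", s)))
}
cat("wrote", length(shapes) + 6, "sections to", out_dir, "\n")
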