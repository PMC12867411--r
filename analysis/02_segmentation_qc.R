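#!/usr/bin/env Rscript
# Segment the nuclear-stain frames: two-pass Otsu population capture,
# peri-nuclear rings, permeabilization QC. Writes the per-object table
# and a QC summary.

library(nucflux)

grid <- readRDS("results/condition_grid.rds")

objects <- list(); qc_rows <- list()
for (e in grid) {
  pre <- preprocess(e$stack$rd2)
  ns <- detect_nuclei_two_pass(pre)
  qc <- qc_permeabilization(ns, total_cells = e$truth$n_cells)
  objects[[length(objects) + 1]] <- cbind(
    data.frame(line = e$line, cargo = e$cargo, field = e$field),
    ns$features
  )
  qc_rows[[length(qc_rows) + 1]] <- data.frame(
    line = e$line, cargo = e$cargo, field = e$field, qc_pass = qc$pass,
    permeabilized_fraction = qc$permeabilized_fraction,
    well_defined_fraction = qc$well_defined_fraction
  )
}
objects <- do.call(rbind, objects)
qc_tab <- do.call(rbind, qc_rows)
write.csv(objects, "results/nucleus_objects.csv", row.names = FALSE)
write.csv(qc_tab, "results/qc_report.csv", row.names = FALSE)

message(nrow(objects), " nuclei detected across ", nrow(qc_tab), " fields; ",
        sum(qc_tab$qc_pass), " fields pass the 60%/30% permeabilization QC.")
message("Median nucleus area ", round(median(objects$area_px2)),
        " px^2, median circularity ", round(median(objects$circularity), 2), ".")
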