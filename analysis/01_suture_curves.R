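#!/usr/bin/env Rscript
# Suture-line families: generates the lobate (3-6 lobes) and Koch
# (iterations 1-3) curves used by the model suite, wraps them on the
# 9.11 mm shell tube, and measures the self-intersection offset limit that
# forces Koch septa to be thin.  Writes results/curves/.

library(phragmoFEM)
out <- "results/curves"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

r <- 9.11
amp <- 0.2 * r
rows <- list()

for (n in 3:6) {
  cu <- lobate_curve(n, amp)
  su <- wrap_on_cylinder(cu, r)
  write_suture_csv(su, file.path(out, sprintf("lobate_%d.csv", n)))
  rows[[length(rows) + 1L]] <- data.frame(
    family = "lobate", complexity = n, n_vertices = nrow(cu$points),
    arc_length_mm = suture_arc_length(su),
    safe_offset_mm = max_safe_offset(su))
}
for (it in 1:3) {
  cu <- koch_curve(it, 4L, amp)
  su <- wrap_on_cylinder(cu, r)
  write_suture_csv(su, file.path(out, sprintf("koch_%d.csv", it)))
  rows[[length(rows) + 1L]] <- data.frame(
    family = "koch", complexity = it, n_vertices = nrow(cu$points),
    arc_length_mm = suture_arc_length(su),
    safe_offset_mm = max_safe_offset(su))
}

tab <- do.call(rbind, rows)
tab$max_septal_thickness_mm <- 2 * tab$safe_offset_mm
write.csv(tab, file.path(out, "curve_summary.csv"), row.names = FALSE)
print(tab, digits = 3)

cat("\nKoch iteration 3 admits at most a",
    sprintf("%.3f mm", 2 * tab$safe_offset_mm[tab$family == "koch" &
                                              tab$complexity == 3]),
    "septum -- the geometric reason the Koch models use 0.04 mm septa",
    "while lobate models can carry 0.4 mm.\n")
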