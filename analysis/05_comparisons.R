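#!/usr/bin/env Rscript
# The comparative experiments, from the suite outputs of 04_model_suite.R:
#   - septal spacing (5/10/20 mm): stress magnitudes and strain energy
#   - shell thickness (0.5 vs 0.1 mm): the dominant variable
#   - lobate complexity (3-6 lobes): weak, non-monotone effects
#   - Koch iterations (1-3): septal vs wall stress trade-off
#   - depth equivalence from the published iteration table
# Writes results/comparisons/.

library(phragmoFEM)
out <- "results/comparisons"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
res <- read.csv("results/suite/suite_results.csv", stringsAsFactors = FALSE)

# --- spacing ---------------------------------------------------------------
sp <- res[res$model %in% c("sexilobate", "sexilobate_s10", "sexilobate_s20") &
            res$pressure_MPa == 2,
          c("model", "spacing_mm", "wall_mean_MPa", "probe_peak_tangential_MPa",
            "strain_energy_mJ", "centre_disp_um")]
sp <- sp[order(sp$spacing_mm), ]
write.csv(sp, file.path(out, "spacing.csv"), row.names = FALSE)
cat("Septal spacing (5/10/20 mm):\n"); print(sp, digits = 3)

# --- thickness -------------------------------------------------------------
th <- compare_models(res, "sexilobate", "sexilobate_thin",
                     quantities = c("probe_peak_tangential_MPa",
                                    "probe_mean_tangential_MPa"))
th2 <- compare_models(res, "trilobate", "trilobate_thin",
                      quantities = c("probe_peak_tangential_MPa",
                                     "probe_mean_tangential_MPa"))
th$pair <- "sexilobate"; th2$pair <- "trilobate"
thick <- rbind(th, th2)
thick$theory_pct <- (hoop_stress_theory(2, 9.11, 0.1) /
                       hoop_stress_theory(2, 9.11, 0.5) - 1) * 100
write.csv(thick, file.path(out, "thickness.csv"), row.names = FALSE)
cat("\nShell thickness 0.5 -> 0.1 mm (theory: +400%):\n")
print(thick, digits = 3)

# --- lobate complexity -----------------------------------------------------
lob <- res[res$model %in% c("trilobate", "quadrilobate", "quinquelobate",
                            "sexilobate") & res$pressure_MPa == 2, ]
lob <- lob[order(lob$complexity),
           c("model", "complexity", "probe_peak_tangential_MPa",
             "wall_mean_MPa", "septum_mean_MPa", "septum_peak_MPa",
             "centre_disp_um")]
write.csv(lob, file.path(out, "lobate.csv"), row.names = FALSE)
cat("\nLobate complexity 3-6 (weak, non-monotone):\n")
print(lob, digits = 3)

# --- Koch iterations -------------------------------------------------------
ko <- res[res$model %in% c("koch_i1", "koch_i2", "koch_i3"), ]
ko <- ko[order(ko$complexity, ko$pressure_MPa),
         c("model", "complexity", "pressure_MPa", "wall_mean_MPa",
           "wall_sd_MPa", "septum_mean_MPa", "septum_sd_MPa",
           "septum_peak_MPa", "strain_energy_mJ", "centre_disp_um")]
write.csv(ko, file.path(out, "koch.csv"), row.names = FALSE)
cat("\nKoch iterations x pressures:\n")
print(ko, digits = 3)

# --- depth equivalence -----------------------------------------------------
# worked example on the published iteration table (no FEA involved)
pub <- published_koch_stats()
wall <- pub[pub$region == "shell_wall", ]
tab <- function(it) data.frame(pressure = wall$pressure[wall$iteration == it],
                               mean_MPa = wall$mean_MPa[wall$iteration == it])
eq2 <- depth_equivalent(tab(1), tab(2), reference_pressure = 2)
eq3 <- depth_equivalent(tab(1), tab(3), reference_pressure = 2)
depth <- data.frame(comparison = c("iteration 2 vs 1", "iteration 3 vs 1"),
                    equivalent_pressure_MPa = c(eq2$pressure, eq3$pressure),
                    extra_depth_m = c(eq2$extra_depth_m, eq3$extra_depth_m))
write.csv(depth, file.path(out, "depth_equivalence.csv"), row.names = FALSE)
cat("\nDepth equivalence from the published shell-wall means:\n")
print(depth, digits = 4)

# the same trend lines on this package's own suite results
own <- lapply(1:3, function(it) {
  k <- ko[ko$complexity == it, ]
  data.frame(pressure = k$pressure_MPa, mean_MPa = k$wall_mean_MPa)
})
if (all(vapply(own, nrow, 1L) >= 2)) {
  own_eq <- try({
    data.frame(comparison = c("own iteration 2 vs 1", "own iteration 3 vs 1"),
               equivalent_pressure_MPa =
                 c(depth_equivalent(own[[1]], own[[2]])$pressure,
                   depth_equivalent(own[[1]], own[[3]])$pressure))
  }, silent = TRUE)
  if (!inherits(own_eq, "try-error")) {
    write.csv(own_eq, file.path(out, "depth_equivalence_own.csv"),
              row.names = FALSE)
    cat("\nSame construction on this suite's own wall means:\n")
    print(own_eq, digits = 4)
  }
}
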