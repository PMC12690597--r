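#!/usr/bin/env Rscript
# Excess charge-ratio rescaling: compositions at different RNA
# concentrations with the same excess polycation concentration map onto
# the same alpha N/P* abscissa, so curves recorded against alpha N/P at
# different c_RNA collapse when replotted against alpha N/P*.
library(polyplexmd)
dir.create("results", showWarnings = FALSE)

u <- reduced_units()
c_ref <- concentrations(system_spec(8, 100, 0, 1, 200), u)$c_rna$mM  # 0.77 mM

grid <- expand.grid(alpha_np = c(0.5, 1, 2, 4, 8, 16),
                    box_edge = c(200, 252, 317.5))
grid$c_rna <- vapply(grid$box_edge, function(L)
  concentrations(system_spec(8, 100, 0, 1, L), u)$c_rna$mM, numeric(1))
star <- np_star_transform(grid$alpha_np, grid$c_rna, c_ref,
                          np_ratio = 2 * grid$alpha_np, np_iso = 2)
out <- cbind(grid, star)
write.csv(out, "results/scaling_collapse.csv", row.names = FALSE)
print(out, row.names = FALSE)
message("Rows sharing (alpha N/P - 1) * c_RNA share alpha N/P*; ",
        "alpha N/P = 1 is a fixed point at every concentration.")
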