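#!/usr/bin/env Rscript
# Verify the respiratory stabilization stage on a phantom with known
# injected translation: a static fundus scene breathing at 4 px amplitude.
# The SSD search should recover every injected shift exactly; the shift
# trace is written for inspection.

library(cinemotility)

spec <- fundus_spec(grid = c(64L, 64L), spacing = c(2, 2), n_frames = 20L,
                    semi_axes = c(25, 18), oscillation_amp = 0,
                    resp_amp_px = 4, resp_period = 4, noise_sd = 0.03,
                    seed = 42L)
ph <- make_fundus_phantom(spec)
res <- stabilize_stack(ph$stack, c(9L, 56L, 9L, 56L), search_radius = 6L)

recovered <- res$cumulative[, "y"]
injected <- ph$truth$resp_px
cat(sprintf("injected vs recovered cumulative y-shift: %d/%d frames exact\n",
            sum(recovered == injected), length(injected)))

dir.create("results", showWarnings = FALSE)
trace <- res$trace
trace$cum_dy_recovered <- recovered[-1]
trace$cum_dy_injected <- injected[-1]
write.csv(trace, "results/stabilization_shifts.csv", row.names = FALSE)
cat("wrote results/stabilization_shifts.csv\n")
stopifnot(all(recovered == injected))
cat("stabilization recovered the respiratory translation exactly.\n")
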