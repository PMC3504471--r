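#!/usr/bin/env Rscript
# Stage 5: the timeline figure — FA maturation curves for rat, ferret and
# human on a log postconceptional-age axis, with the rat critical period and
# its fraction-matched translations shaded.

library(cortexclock)

registry <- default_species_registry()
rat_window <- dev_window("rat", 25.5, 27.5)
windows <- list(
  rat_window,
  translate_window(rat_window, registry$rat, registry$ferret),
  translate_window(rat_window, registry$rat, registry$human)
)

dir.create("results", showWarnings = FALSE)
suppressWarnings(  # the registry's cat entry has no FA clock and is skipped
  run_plot_trajectories(registry, windows = windows,
                        out_file = "results/05_fa_trajectories.pdf"))
cat("Written to results/05_fa_trajectories.pdf\n")
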