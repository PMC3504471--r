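#!/usr/bin/env Rscript
# Stage 1: express the rat critical period for visual callosal connections
# (P4-P6) in fractional-FA-decay coordinates and translate it onto the human
# and ferret maturation clocks; compare with the Translating Time windows.
#
# Finds: the rat window spans fractions 0.50 -> 0.33 of the FA range; the
# human prediction is gestational days 201-217 (28.7-31 wk), about nine
# weeks later than the Translating Time window (138-150); the ferret
# prediction PC56-PC61 nearly abuts its Translating Time window (PC52-56.5).

library(cortexclock)

out_dir <- "results/01_translation"
report <- run_predict("rat", c(4, 6), window_frame = "postnatal",
                      targets = c("human", "ferret"), out_dir = out_dir,
                      seed = 1)

cat(readLines(file.path(out_dir, "prediction.txt")), sep = "\n")
cat("\nWritten to", out_dir, "\n")
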