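#!/usr/bin/env Rscript
# Stage 2: parameter recovery for the FA maturation clock. Simulates noisy
# FA-versus-age observations from each species' published clock (noise sd
# 0.02 FA units, 50 ages spanning the decay) and refits, with the decay
# onset t_init either fixed (as the published fits treat it, tied to the end
# of pyramidal-cell migration) or profiled freely.
#
# Finds: tau is recovered within a few percent with t_init fixed, and the
# free-breakpoint profile search lands within a couple of days of the
# generating t_init (the breakpoint is weakly identified under noise when
# few observations sit on the plateau).

library(cortexclock)

registry <- default_species_registry()
rows <- list()
for (sp in c("rat", "ferret", "human")) {
  p <- registry[[sp]]
  ages <- seq(p$t_init + 1, p$t_init + 4 * p$tau, length.out = 50)
  obs <- gen_fa_observations(p, ages, noise_sd = 0.02, seed = 100 + nchar(sp))
  fit_fixed <- fit_fa_params(obs, fixed = c(t_init = p$t_init),
                             species_name = sp)
  fit_free <- fit_fa_params(obs, species_name = sp)
  rows[[sp]] <- tibble::tibble(
    species = sp, tau_true = p$tau,
    tau_fixed_tinit = fit_fixed$params$tau,
    tau_free_tinit = fit_free$params$tau,
    t_init_true = p$t_init, t_init_free = fit_free$params$t_init,
    rss_fixed = fit_fixed$residual_sum_of_squares,
    converged = fit_fixed$converged && fit_free$converged
  )
}
tab <- dplyr::bind_rows(rows)

dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/02_fa_fit_recovery.csv", row.names = FALSE)
print(as.data.frame(tab), digits = 4)
cat("\nWritten to results/02_fa_fit_recovery.csv\n")
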