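#!/usr/bin/env Rscript
# Report constituent effects on the study's percent scale and compare the
# posterior estimates with the generator's truth.

suppressPackageStartupMessages(library(bhpm))
out <- "results/study"

fit <- readRDS(file.path(out, "fit_allsites.rds"))
truth <- readRDS(file.path(out, "truth.rds"))

tab <- render_effect_table(fit)
write.csv(tab, file.path(out, "effects.csv"), row.names = FALSE)

message("constituent effects, % per 1-SD (95% posterior interval):")
for (eff in c("main", "modifier")) {
  message(if (eff == "main") {
    "  mortality-rate main effects (intercept equation):"
  } else {
    "  exposure-association modifiers (slope equation):"
  })
  sub <- tab[tab$effect == eff, ]
  tv <- if (eff == "main") truth$beta else truth$gamma
  for (i in seq_len(nrow(sub))) {
    message(sprintf("    %-4s %-18s truth %5.1f%%", sub$term[i],
                    sub$formatted[i],
                    100 * (exp(tv[[sub$term[i]]]) - 1)))
  }
}
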