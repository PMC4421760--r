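#!/usr/bin/env Rscript
# Stage 1: per-location Poisson regression of monthly deaths on centered
# previous-year exposure with a log population offset, yielding spatially
# varying baseline mortality rates and exposure-mortality slopes with
# their sampling covariance.

suppressPackageStartupMessages(library(bhpm))
out <- "results/study"

panel <- read.csv(file.path(out, "panel.csv"))
stage1 <- fit_all_locations(panel)
write.csv(stage1, file.path(out, "stage1.csv"), row.names = FALSE)

ok <- stage1$converged
rate <- 1000 * exp(stage1$alpha0_hat[ok])
pct <- slope_percent_scale(stage1[ok, ])$pct_per_ugm3
message(sum(ok), " of ", nrow(stage1), " locations converged")
message("baseline mortality rate (deaths/month/1,000): ",
        paste(round(quantile(rate, c(0.05, 0.5, 0.95)), 2), collapse = " / "),
        " (5th/50th/95th percentile)")
message("slope, % increase per 1 ug/m3 previous-year exposure: ",
        paste(round(quantile(pct, c(0.05, 0.5, 0.95)), 2), collapse = " / "))
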