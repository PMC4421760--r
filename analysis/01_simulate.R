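#!/usr/bin/env Rscript
# Build the synthetic study that the remaining analysis steps consume:
# a clustered 518-monitor mass network sharing its metropolitan structure
# with a sparser 174-monitor speciation network, linked within 6 miles,
# plus a complete monthly mortality panel and site covariates with known
# second-level truth.

suppressPackageStartupMessages(library(bhpm))
out <- "results/study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260929L

# -- misaligned monitor networks and their 6-mile linkage ----------------
set.seed(seed)
metros <- data.frame(lon = runif(40, -95, -67), lat = runif(40, 25, 47))
mass <- simulate_locations(518, seed = seed + 1, centers = metros)
speciation <- simulate_locations(174, seed = seed + 2, centers = metros)
links <- link_nearest_within(mass, speciation, radius = 6)
n_linked <- sum(!is.na(links$source_id))
message("mass monitors with a speciation monitor within 6 miles: ",
        n_linked, " / 518 (median linked distance ",
        round(median(links$distance_miles, na.rm = TRUE), 2), " miles)")
write.csv(links, file.path(out, "linkage.csv"), row.names = FALSE)

# -- full synthetic study at network scale ------------------------------
truth <- simulation_truth(n_locations = 518, seed = seed + 3)
study <- simulate_study(truth)
message("panel: ", nrow(study$panel), " location-months over ",
        nrow(study$locations), " monitors; mean monthly mortality rate ",
        round(1000 * sum(study$panel$deaths) / sum(study$panel$at_risk), 2),
        " deaths/1,000 persons")

write.csv(study$panel, file.path(out, "panel.csv"), row.names = FALSE)
write.csv(study$covariates, file.path(out, "covariates_true.csv"),
          row.names = FALSE)
write.csv(study$locations, file.path(out, "locations.csv"), row.names = FALSE)
write.csv(study$alpha, file.path(out, "alpha_true.csv"), row.names = FALSE)
saveRDS(truth, file.path(out, "truth.rds"))

# mask 53% of sites, mirroring the mass/speciation misalignment rate
masked <- mask_constituents(study$covariates, 0.53, seed = seed + 4)
write.csv(masked, file.path(out, "covariates_masked.csv"), row.names = FALSE)
message("constituents masked at ", sum(!masked$observed), " of 518 sites")
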