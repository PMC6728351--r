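#!/usr/bin/env Rscript
# Stage 2: restriction-site normalization, replicate averaging and
# untreated-control background subtraction.

library(polusage)

prev <- readRDS("scratch/state_01.rds")
state <- run_normalize(prev$config, prev$state)

factors <- do.call(rbind, lapply(state$report_normalize$factors, as.data.frame))
write.table(factors, "results/normalization_factors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(list(config = prev$config, state = state), "scratch/state_02.rds")

message(sprintf(
  "Normalized %d samples; factors span %.2f-%.2f (true per-sample depth jitter is log-normal, sd %.2f).",
  nrow(factors), min(factors$factor), max(factors$factor),
  prev$config$noise$depth_jitter_sd))
excl <- state$report_normalize$excluded_sites
message(sprintf("Sites excluded by the zero-count filter: %d.",
                length(excl)))
message(sprintf(
  "Corrected tracks written for strains: %s.",
  paste(names(state$corrected), collapse = ", ")))
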