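#!/usr/bin/env Rscript
# Generate the study cohorts: the default nine-subtype tri-modal cohort, the
# continuous-gradient (basal-arm) cohort, and the twelve-sample toy fixture.
# Writes pipeline-ready TSVs under results/data/.

library(tpgfuse)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

root <- "results/data"
dir.create(root, recursive = TRUE, showWarnings = FALSE)

message("simulating the nine-subtype cohort (seed ", seed, ") ...")
cohort <- simulate_cohort(sim_config(seed = seed))
write_cohort(cohort, file.path(root, "cohort"))
message("  ", nrow(cohort$expression), " samples x ",
        ncol(cohort$expression), " genes / ",
        ncol(cohort$methylation), " probes / ",
        ncol(cohort$microbiome), " genera; subtypes: ",
        paste(sort(unique(cohort$truth$subtype)), collapse = ", "))

message("simulating the continuous-gradient cohort ...")
grad <- simulate_cohort(sim_config(groups = paste0("grad_", 1:4),
                                   gradient_mode = "continuous", seed = seed))
write_cohort(grad, file.path(root, "gradient"))

message("writing the toy fixture ...")
write_cohort(make_toy_fixture(), file.path(root, "toy"))

message("done; inputs under ", normalizePath(root))
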