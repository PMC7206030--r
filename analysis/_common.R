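# Shared header for the analysis drivers: loads the package and computes
# (or reuses) the seed-42 study workflow. Heavy intermediates are cached
# under scratch/ so each driver stays fast; small result tables go to
# results/.

suppressMessages(library(chirpscreen))

SEED <- 42
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

get_workflow <- function() {
  cache <- file.path("scratch", sprintf("workflow_%d.rds", SEED))
  if (file.exists(cache)) return(readRDS(cache))
  res <- run_chirp_workflow(seed = SEED)
  saveRDS(res, cache)
  res
}
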