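# Shared configuration for the numbered analysis drivers.
# Every script can be run standalone from the repository root:
#   Rscript analysis/01_simulate.R
# Later scripts read the files written by earlier ones under results/.

library(methatlas)

SEED <- 20260920
RESULTS <- "results"

SAMPLES <- list(NB = "normal", BT089 = "benign", BT126 = "invasive",
                BT198 = "invasive", HMEC = "cell_line",
                MCF7 = "cell_line", HCC1954 = "cell_line")
NORMAL_SAMPLES <- c("NB", "BT089", "HMEC")

study_genome <- function() {
  generate_genome(genome_config(), seed = derive_seed(SEED, "genome"))
}

dir_for <- function(stage) {
  d <- file.path(RESULTS, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# internal helper reused across drivers
derive_seed <- methatlas:::derive_seed
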