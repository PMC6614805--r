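#!/usr/bin/env Rscript

# Selection-pool enrichment analysis on synthetic sequencing data.
#
# Emulates the study's serial-selection read sets: three rounds (the
# equimolar combination of the parallel pools, then serial rounds S3 and
# S6) spiked with the SCA2.1 family at its reported abundances
# (0.0041% -> 0.39% -> 29%), plus 1% corrupted reads for the trimmer to
# discard. Reads are trimmed to the 30-nt random region, counted, and the
# family trajectory and pool-diversity summaries are tabulated.

suppressPackageStartupMessages(library(selexkit))

n_per_round <- 2e5   # reads per round; enough that 3 multinomial SD < each spike
fractions <- c(combined = 0.0041 / 100, S3 = 0.39 / 100, S6 = 29 / 100)
design <- default_library_design()

ser <- make_round_series(names(fractions), n_per_round, sca21_motif,
                         unname(fractions), malformed_fraction = 0.01,
                         seed = 101)

pools <- lapply(ser$pools, function(p) {
  out <- trim_to_random_region(p$reads, design)
  cat(sprintf("%-9s trimmed %d/%d reads (%d discarded)\n",
              p$reads$pool_id, out$report$kept, out$report$input,
              out$report$discarded))
  count_pool(out$reads)
})

traj <- enrichment_trajectory(pools, sca21_motif)
dir.create("results", showWarnings = FALSE)
write_trajectory(traj, "results/pool_trajectory.tsv")
write_manifest(ser$pools[[3]]$manifest, "results/pool_manifest_S6.yaml")

summaries <- do.call(rbind, lapply(pools, function(p) {
  s <- pool_summary(p)
  data.frame(round_id = p$pool_id, n_unique = s$n_unique,
             p5 = s$percentiles[["p5"]], p50 = s$percentiles[["p50"]],
             p95 = s$percentiles[["p95"]], max_fraction = s$max_fraction)
}))
write_table_tsv(summaries, "results/pool_summaries.tsv")

cat("\nSCA2.1 family trajectory (percent of trimmed reads):\n")
print(transform(as.data.frame(traj),
                family_pct = signif(100 * family_fraction, 3)))

# equimolar combination of the three parallel pools, from their family
# fractions, reproduces the reported combined-pool abundance
parallel_fracs <- c(butylone_P5 = 0.011e-2, ethylone_P5 = 0, aPVP_P9 = 0.00095e-2)
mk <- function(frac, id) {
  fam <- paste0(sca21_motif, strrep("A", 10))
  structure(list(pool_id = id, total_reads = 1000000L, random_length = 30L,
                 entries = data.frame(sequence = c(strrep("C", 30), fam),
                                      reads = round(1e6 * c(1 - frac, frac)),
                                      fraction = c(1 - frac, frac),
                                      rpm = 1e6 * c(1 - frac, frac),
                                      rank = 1:2)),
            class = "pool_counts")
}
cmb <- combine_pools(mapply(mk, parallel_fracs, names(parallel_fracs),
                            SIMPLIFY = FALSE))
cat(sprintf("\nEquimolar combination of parallel pools: SCA2.1 = %.4f%% of the combined pool\n",
            100 * family_fraction(cmb, sca21_motif)))
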