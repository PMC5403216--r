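#!/usr/bin/env Rscript
# Derived replication arithmetic: clamp-loading interval, fork rate,
# Okazaki fragment length and synthesis per polymerase exchange, from the
# kinetic estimates (clamp bound time 47 s, 23 dimers per fork, 4.6 Mbp
# genome replicated by 2 forks in 150 min, polymerase bound times 4-12 s).

suppressPackageStartupMessages(library(replikinetics))

rep <- replication_report(genome_size = 4.6e6, n_forks = 2,
                          replication_time = 150 * 60,
                          beta_dimers_per_fork = 23, beta_unload_time = 47)
cat(sprintf("clamp loading interval: %.3f s exact, ~%g s rounded\n",
            rep$exact$loading_interval_s, rep$loading_interval_s))
cat(sprintf("fork rate: %.1f bp/s exact, ~%g bp/s rounded\n",
            rep$exact$fork_rate_bp_s, rep$fork_rate_bp_s))
cat(sprintf("Okazaki fragment length: %g bp (rounded chain), %.0f bp (exact chain)\n",
            rep$okazaki_length_bp, rep$exact$okazaki_length_bp))

synth <- data.frame(
  pol_bound_time_s = c(4, 12),
  synthesis_bp = c(synthesis_before_exchange(4, rep$fork_rate_bp_s),
                   synthesis_before_exchange(12, rep$fork_rate_bp_s))
)
cat(sprintf("synthesis per polymerase exchange: %.0f-%.0f bp (~1-3 kbp)\n",
            synth$synthesis_bp[1], synth$synthesis_bp[2]))

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(
  metric = c("loading_interval_s", "fork_rate_bp_s", "okazaki_length_bp",
             "okazaki_length_exact_bp", "synthesis_min_bp",
             "synthesis_max_bp"),
  value = c(rep$loading_interval_s, rep$fork_rate_bp_s,
            rep$okazaki_length_bp, rep$exact$okazaki_length_bp,
            synth$synthesis_bp[1], synth$synthesis_bp[2])
), "results/replication_metrics.csv", row.names = FALSE)
cat("wrote results/replication_metrics.csv\n")
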