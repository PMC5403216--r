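#!/usr/bin/env Rscript
# Generate the synthetic study datasets with known ground truth:
#   - an epsilon-like (fast-exchange) localization table, 0.5 s / 1 s
#   - a DnaB-like (near-bleach-limited) track-duration sample, 2 s / 10 s
#   - LacI-like bleach controls for both protocols
#   - FRAP trace ensembles for an alpha-like subunit and a DnaB-like
#     non-recovering focus
# Everything downstream (02-04) starts from these files.

suppressPackageStartupMessages(library(replikinetics))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## sptPALM: epsilon-like fast exchanger, truth T_bound = 10 s -------------
st_eps <- acquisition_settings(exposure_time = 0.5, interval_time = 1,
                               n_frames = 200)
tab <- gen_localization_table(
  track_sim_params(true_bound_time = 10, n_molecules = 200, seed = 101),
  st_eps,
  mixture_spec(n_diffusing = 150, multi_fraction = 0.2))
write_localization_table(tab, file.path(out_dir, "epsilon_localizations.csv"))
cat(sprintf("epsilon-like table: %d localizations, %d bound molecules\n",
            nrow(tab), 200))

## sptPALM: DnaB-like stable binder, truth T_bound = 913 s ----------------
st_dnab <- acquisition_settings(exposure_time = 2, interval_time = 10,
                                n_frames = 600)
dnab <- gen_track_durations(
  track_sim_params(true_bound_time = 913, n_molecules = 150, seed = 102),
  st_dnab, label = "DnaB-like")
if (length(dnab$durations) > 86) dnab$durations <- dnab$durations[1:86]
write.csv(data.frame(duration_s = dnab$durations),
          file.path(out_dir, "dnab_durations.csv"), row.names = FALSE)
cat(sprintf("DnaB-like durations: n = %d, mean %.1f s (bleach-dominated)\n",
            length(dnab$durations), mean(dnab$durations)))

## bleach controls (stable binder, bleaching only) ------------------------
ctrl_fast <- gen_bleach_control(
  track_sim_params(Inf, n_molecules = 300, seed = 103),
  acquisition_settings(0.5, 0.5, 2000), min_localizations = 4)
write.csv(data.frame(duration_s = ctrl_fast$durations),
          file.path(out_dir, "bleach_control_500ms.csv"), row.names = FALSE)
ctrl_slow <- gen_bleach_control(
  track_sim_params(Inf, n_molecules = 300, seed = 104), st_dnab)
write.csv(data.frame(duration_s = ctrl_slow$durations),
          file.path(out_dir, "bleach_control_2s10s.csv"), row.names = FALSE)
cat(sprintf("bleach controls: n = %d (constant exposure), n = %d (2 s/10 s)\n",
            length(ctrl_fast$durations), length(ctrl_slow$durations)))

## FRAP: alpha-like recovering focus, truth k_off = 0.25 /s ---------------
p_alpha <- frap_sim_params(asymptote = 0.8, amplitude = 0.55,
                           unbinding_rate = 0.25, global_bleach_time = 200,
                           noise_sd = 0.05, n_traces = 48, seed = 105)
frap_alpha <- rbind(gen_frap_traces(p_alpha),
                    gen_frap_support_traces(p_alpha,
                                            residual_fraction = 0.85,
                                            n_cells = 20))
write_frap_traces(frap_alpha, file.path(out_dir, "frap_alpha.csv"))

## FRAP: DnaB-like non-recovering focus (pool signal only) ----------------
p_dnab <- frap_sim_params(asymptote = 0.32, amplitude = 0.3,
                          unbinding_rate = 0.004, noise_sd = 0.03,
                          n_traces = 30, seed = 106)
write_frap_traces(gen_frap_traces(p_dnab),
                  file.path(out_dir, "frap_dnab.csv"))
cat("FRAP ensembles written (48 alpha-like, 30 DnaB-like traces)\n")

truth <- list(
  epsilon = list(T_bound_s = 10, T_constant_s = 15),
  dnab = list(T_bound_s = 913, T_constant_s = 15),
  frap_alpha = list(c = 0.8, a = 0.55, b_per_s = 0.25, bound_time_s = 4),
  frap_dnab = list(recovering = FALSE)
)
jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)
cat("ground truth recorded in results/data/ground_truth.json\n")
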