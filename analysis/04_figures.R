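#!/usr/bin/env Rscript
# Publication-style figures from the simulated cohorts: SuperPlots of
# displacement and persistence, worm plots per strain, and the log-log MSD
# panel. Written as PDFs under results/figures/.

suppressMessages(library(pilitrack))
suppressMessages(library(ggplot2))

metrics_path <- file.path("results", "track_stats", "track_metrics.csv")
if (!file.exists(metrics_path)) stop("run analysis/02_track_statistics.R first")
outdir <- file.path("results", "figures")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

metrics <- utils::read.csv(metrics_path)

ggsave(file.path(outdir, "superplot_displacement.pdf"),
       plot_superplot(metrics, "net_displacement_um"), width = 5, height = 4)
ggsave(file.path(outdir, "superplot_persistence.pdf"),
       plot_superplot(metrics, "persistence_ratio"), width = 5, height = 4)

all_tracks <- read_tracks(file.path("results", "sim", "all_tracks.csv"))
for (strain in unique(all_tracks$tracks$group)) {
  sub <- motility_cohort(
    all_tracks$tracks[all_tracks$tracks$group == strain, ],
    frame_interval = all_tracks$frame_interval
  )
  ggsave(file.path(outdir, sprintf("worms_%s.pdf", strain)),
         plot_tracks(sub, max_tracks = 60), width = 4, height = 4)
}

wt <- motility_cohort(all_tracks$tracks[all_tracks$tracks$group == "WT", ],
                      frame_interval = all_tracks$frame_interval)
ggsave(file.path(outdir, "msd_loglog_WT.pdf"), plot_msd(wt, max_tracks = 60),
       width = 4, height = 4)

cat("figures under results/figures/\n")
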