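fake_metrics <- function(disp, group = "G", replicate = NULL) {
  n <- length(disp)
  if (is.null(replicate)) replicate <- paste0("R", (seq_len(n) - 1) %% 3 + 1)
  data.frame(
    track_id = sprintf("%s_%03d", group, seq_len(n)),
    group = group, replicate_id = replicate,
    net_displacement_um = disp,
    path_length_um = disp * 4,
    persistence_ratio = 0.25, alpha = 1,
    motility_class = "motile", diffusion_class = "diffusive",
    stringsAsFactors = FALSE
  )
}

test_that("group summaries follow the replicate-mean (SuperPlot) convention", {
  m <- fake_metrics(c(5, 5, 6, 6, 7, 7), replicate = rep(c("R1", "R2", "R3"), each = 2))
  s <- summarize_group(m, "G")
  expect_equal(unname(s$per_replicate_means), c(5, 6, 7))
  expect_equal(s$grand_mean, 6)
  expect_equal(s$sem, sd(5:7) / sqrt(3))
  expect_equal(s$sem, 0.5773503, tolerance = 1e-6)
  expect_equal(s$n_cells, 6)

  # grand mean ignores unequal replicate sizes when replicate means are equal
  m2 <- fake_metrics(c(4, 4, 4, 4, 4), replicate = c("R1", "R1", "R1", "R2", "R3"))
  expect_equal(summarize_group(m2, "G")$grand_mean, 4)

  # single replicate: SEM undefined and flagged
  m1 <- fake_metrics(c(5, 6), replicate = c("R1", "R1"))
  s1 <- summarize_group(m1, "G")
  expect_true(is.na(s1$sem) && !s1$sem_defined)

  expect_error(summarize_group(m, "G", metric = "nope"), "unknown metric")
  expect_error(summarize_group(m, "missing"), "no tracks")
})

test_that("fraction of non-motile tracks uses the configured threshold", {
  m <- fake_metrics(c(1.5, 3, 4, 5, 6, 7, 8, 9))
  expect_equal(summarize_group(m, "G")$fraction_non_motile, 0.125)
  cfg3 <- analysis_config(non_motile_threshold = 3.5)
  expect_equal(summarize_group(m, "G", config = cfg3)$fraction_non_motile, 0.25)
})

test_that("replicate-mean ANOVA with Tukey matches the first-principles oracle", {
  rm_tab <- data.frame(
    group = rep(c("A", "B", "C"), each = 3),
    replicate_id = rep(c("R1", "R2", "R3"), 3),
    value = c(1, 2, 3, 1, 2, 3, 7, 8, 9)
  )
  res <- anova_tukey(rm_tab)
  oracle <- tukey_oracle(rm_tab$value, rm_tab$group)
  expect_equal(res$f_statistic, oracle$f, tolerance = 1e-6)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-6)
  ord <- match(oracle$pairwise$comparison, res$pairwise$comparison)
  expect_false(anyNA(ord))
  expect_equal(res$pairwise$p_adj[ord], oracle$pairwise$p_adj, tolerance = 1e-6)
  expect_equal(res$pairwise$diff[ord], oracle$pairwise$diff, tolerance = 1e-9)
  # the distant group differs, the identical pair does not
  p_ab <- res$pairwise$p_adj[res$pairwise$comparison %in% c("B-A", "A-B")]
  p_ac <- res$pairwise$p_adj[res$pairwise$comparison %in% c("C-A", "A-C")]
  expect_gt(p_ab, 0.9)
  expect_lt(p_ac, 0.01)
})

test_that("ANOVA degenerate and invariance properties hold", {
  same <- data.frame(group = rep(c("A", "B"), each = 3),
                     replicate_id = rep(paste0("R", 1:3), 2),
                     value = rep(c(1, 2, 3), 2))
  res <- anova_tukey(same)
  expect_equal(res$f_statistic, 0, tolerance = 1e-12)
  expect_equal(res$pairwise$p_adj, 1, tolerance = 1e-9)

  # translation invariance of F
  shifted <- same; shifted$value <- shifted$value + 100
  expect_equal(anova_tukey(shifted)$f_statistic, res$f_statistic, tolerance = 1e-9)

  # zero pooled variance flagged
  flat <- data.frame(group = rep(c("A", "B"), each = 2),
                     replicate_id = rep(c("R1", "R2"), 2),
                     value = c(1, 1, 2, 2))
  expect_warning(resf <- anova_tukey(flat), "zero pooled")
  expect_true(is.na(resf$p_value))

  expect_error(anova_tukey(same[same$group == "A", ]), "at least 2 groups")
  one_rep <- data.frame(group = c("A", "A", "B"), replicate_id = c("R1", "R2", "R1"),
                        value = 1:3)
  expect_error(anova_tukey(one_rep), "B")
})

test_that("displacement histograms are half-open, conserving and threshold-aligned", {
  m <- fake_metrics(c(1, 3, 5))
  h <- displacement_histogram(m, c(0, 2, 4, 6.5))
  expect_equal(h$count, c(1, 1, 1))
  # a value on an edge joins the right-hand bin
  m2 <- fake_metrics(c(2, 3.9))
  h2 <- displacement_histogram(m2, c(0, 2, 4))
  expect_equal(h2$count, c(0, 2))
  expect_error(displacement_histogram(m, c(0, 2, 2)), "strictly increasing")
  expect_error(displacement_histogram(m, c(0, 1, 3, 7), config = analysis_config()),
               "threshold")
  # conservation on a simulated cohort
  p <- builtin_presets()$WT; p$duration <- 30
  metrics <- track_metrics(simulate_cohort(p, 40, 3, seed = 2)$cohort)
  h3 <- displacement_histogram(metrics, c(seq(0, 8, by = 2), Inf),
                               config = analysis_config())
  expect_equal(sum(h3$count), 40)
})

test_that("summarize_cohort covers every group", {
  m <- rbind(fake_metrics(c(5, 6, 7), "A"), fake_metrics(c(1, 1, 1), "B"))
  s <- summarize_cohort(m)
  expect_equal(sort(s$group), c("A", "B"))
  expect_equal(s$grand_mean[s$group == "B"], 1)
})
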