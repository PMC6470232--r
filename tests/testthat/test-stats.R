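test_that("comparison design encodes the Bonferroni scheme", {
  d <- comparison_design()
  expect_equal(d$alpha_condition, round(0.05 / 3, 4))
  expect_equal(d$alpha_condition, 0.0167)
  expect_equal(d$alpha_group, 0.025)
  expect_equal(length(d$condition_contrasts), 3)
  expect_equal(length(d$group_contrasts), 2)
  # alpha always equals family alpha / contrast count
  d2 <- comparison_design(family_alpha = 0.1)
  expect_equal(d2$alpha_group, 0.1 / 2)
})

test_that("mixed ANOVA reproduces hand-computed sums of squares", {
  # balanced 2 groups x 2 conditions, 3 subjects per group
  vals <- c(
    10, 12, # s1 (A)
    11, 14, # s2 (A)
    9, 10, # s3 (A)
    16, 15, # s4 (B)
    18, 16, # s5 (B)
    17, 18 # s6 (B)
  )
  df <- tibble::tibble(
    subject = rep(sprintf("s%d", 1:6), each = 2),
    group = rep(c("A", "B"), each = 6),
    condition = rep(c("c1", "c2"), 6),
    value = vals
  )
  out <- mixed_anova(df)
  # closed-form oracle
  y <- matrix(vals, ncol = 2, byrow = TRUE) # subjects x conditions
  g <- rep(c("A", "B"), each = 3)
  gm <- mean(y)
  ss_between_subj <- 2 * sum((rowMeans(y) - gm)^2)
  ss_group <- 6 * sum((tapply(rowMeans(y), g, mean) - gm)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_cond <- 6 * sum((colMeans(y) - gm)^2)
  cell <- rbind(colMeans(y[1:3, ]), colMeans(y[4:6, ]))
  ss_interact <- 3 * sum((cell - outer(tapply(rowMeans(y), g, mean),
                                       rep(0, 2), "+") -
                            rep(1, 2) %o% colMeans(y) + gm)^2)
  ss_total <- sum((y - gm)^2)
  ss_resid <- ss_total - ss_group - ss_subj_within - ss_cond - ss_interact
  f_group <- (ss_group / 1) / (ss_subj_within / 4)
  f_cond <- (ss_cond / 1) / (ss_resid / 4)
  f_int <- (ss_interact / 1) / (ss_resid / 4)
  expect_equal(out$statistic[out$effect == "group"], f_group,
               tolerance = 1e-10)
  expect_equal(out$statistic[out$effect == "condition"], f_cond,
               tolerance = 1e-10)
  expect_equal(out$statistic[out$effect == "group:condition"], f_int,
               tolerance = 1e-10)
  expect_false(any(out$untestable))
  # location invariance
  df2 <- df; df2$value <- df2$value + 100
  expect_equal(mixed_anova(df2)$statistic, out$statistic,
               tolerance = 1e-10)
  # degenerate data are reported untestable, not crashed
  df3 <- df; df3$value <- 1
  expect_true(all(mixed_anova(df3)$untestable))
})

test_that("permuted group labels give calibrated false-positive rates", {
  set.seed(42)
  n_per <- 6
  base_df <- tidyr::expand_grid(
    subject = sprintf("s%02d", 1:(2 * n_per)),
    condition = c("c1", "c2", "c3"))
  base_df$value <- rnorm(nrow(base_df))
  groups <- rep(c("A", "B"), each = n_per)
  hits <- vapply(1:400, function(i) {
    g <- sample(groups)
    df <- base_df
    df$group <- g[match(df$subject, sprintf("s%02d", 1:(2 * n_per)))]
    df$value <- rnorm(nrow(df))
    p <- mixed_anova(df)$p.value[1]
    p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.01)
  expect_lte(mean(hits), 0.12)
})

test_that("pairwise contrasts apply the adjusted thresholds", {
  set.seed(7)
  subj <- sprintf("s%02d", 1:24)
  grp <- rep(c("control", "R-H", "L-H"), each = 8)
  df <- tidyr::expand_grid(subject = subj,
                           condition = c("resting", "task_S1", "task_S2"))
  df$group <- grp[match(df$subject, subj)]
  df$value <- rnorm(nrow(df), sd = 0.3) +
    ifelse(df$group != "control" & df$condition != "resting", 1.5, 0)
  out <- pairwise_compare(df)
  expect_setequal(unique(out$type), c("condition", "group"))
  expect_equal(unique(out$alpha[out$type == "condition"]), 0.0167)
  expect_equal(unique(out$alpha[out$type == "group"]), 0.025)
  # the threshold rule is exactly p < alpha
  expect_identical(out$significant, out$p.value < out$alpha)
  expect_identical(out$direction == "none", !out$significant)
  # the planted group effect is found with positive direction at task
  task_rows <- out$type == "group" & out$condition == "task_S1"
  expect_true(all(out$significant[task_rows]))
  expect_true(all(out$direction[task_rows] == "increase"))
  # missing cells error
  expect_error(pairwise_compare(df[df$condition == "resting", ]),
               "missing cell")
})

test_that("assumption screening reports without gating", {
  set.seed(1)
  df <- tidyr::expand_grid(subject = sprintf("s%d", 1:12),
                           condition = c("c1", "c2"))
  df$group <- ifelse(as.integer(sub("s", "", df$subject)) <= 6, "A", "B")
  df$value <- rnorm(nrow(df))
  sc <- screen_assumptions(df)
  expect_true(all(c("ks_normality", "levene_homogeneity") %in% sc$check))
  expect_true(all(sc$p.value[!is.na(sc$p.value)] >= 0))
})
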