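#' Group/condition comparison design
#'
#' Three groups (`control`, `R-H`, `L-H`) by three conditions (`resting`,
#' `task_S1`, `task_S2`); three inter-condition contrasts judged at a
#' Bonferroni-adjusted alpha of 0.05/3 = 0.0167 and two patient-vs-control
#' contrasts judged at 0.05/2 = 0.025.
#'
#' @param family_alpha Family-wise error level (default 0.05).
#' @return A list of class `comparison_design`.
#' @export
comparison_design <- function(family_alpha = 0.05) {
  condition_contrasts <- list(c("task_S1", "resting"),
                              c("task_S2", "resting"),
                              c("task_S2", "task_S1"))
  group_contrasts <- list(c("R-H", "control"), c("L-H", "control"))
  structure(list(
    groups = c("control", "R-H", "L-H"),
    conditions = c("resting", "task_S1", "task_S2"),
    condition_contrasts = condition_contrasts,
    alpha_condition = round(family_alpha / length(condition_contrasts), 4),
    group_contrasts = group_contrasts,
    alpha_group = family_alpha / length(group_contrasts)
  ), class = "comparison_design")
}

#' Two-way mixed-design (repeated-measures) ANOVA
#'
#' Group (between-subject) by condition (within-subject) ANOVA of one
#' connectivity value per subject and condition, via `stats::aov` with a
#' subject error stratum. Expects a complete balanced table (every subject
#' measured in every condition).
#'
#' @param data Tibble with columns `value`, `subject`, `group`,
#'   `condition` (other columns ignored).
#' @return Tibble with one row per effect (`group`, `condition`,
#'   `group:condition`): `effect`, `df1`, `df2`, `statistic` (F),
#'   `p.value`, and `untestable` (TRUE when the design is degenerate, e.g.
#'   zero residual variance; statistics are then NA).
#' @export
mixed_anova <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("value", "subject", "group", "condition") %in% names(data)))
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$condition <- factor(data$condition)
  counts <- table(data$subject, data$condition)
  if (any(counts != 1)) {
    stop("each subject must appear exactly once per condition")
  }
  out <- tibble::tibble(
    effect = c("group", "condition", "group:condition"),
    df1 = NA_real_, df2 = NA_real_, statistic = NA_real_,
    p.value = NA_real_, untestable = TRUE)
  if (stats::var(data$value) < 1e-24) return(out)
  fit <- stats::aov(value ~ group * condition + Error(subject / condition),
                    data = data)
  s <- summary(fit)
  grab <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    ir <- match("Residuals", rn)
    if (is.na(i) || is.na(ir) || tab[ir, "Mean Sq"] <= 0) return(NULL)
    c(df1 = tab[i, "Df"], df2 = tab[ir, "Df"],
      statistic = tab[i, "F value"], p.value = tab[i, "Pr(>F)"])
  }
  rows <- list(group = grab("Error: subject", "group"),
               condition = grab("Error: subject:condition", "condition"),
               `group:condition` = grab("Error: subject:condition",
                                        "group:condition"))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (!is.null(r) && all(is.finite(r))) {
      out[i, c("df1", "df2", "statistic", "p.value")] <- as.list(unname(r))
      out$untestable[i] <- FALSE
    }
  }
  out
}

#' Bonferroni pairwise contrasts on region connectivity values
#'
#' Judges the three inter-condition contrasts (paired t-tests across all
#' subjects) at the condition-adjusted alpha and the two patient-vs-control
#' contrasts (pooled-variance two-sample t-tests, per condition) at the
#' group-adjusted alpha, reporting effect directions.
#'
#' @param data Tibble with columns `value`, `subject`, `group`,
#'   `condition`.
#' @param design A [comparison_design()].
#' @return Tibble with columns `type` (`"condition"`/`"group"`),
#'   `contrast`, `condition` (NA for condition contrasts), `estimate`
#'   (mean difference, first-named minus second), `statistic`, `df`,
#'   `p.value`, `alpha`, `significant`, `direction` (`"increase"`,
#'   `"decrease"` or `"none"`).
#' @export
pairwise_compare <- function(data, design = comparison_design()) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("value", "subject", "group", "condition") %in% names(data)))
  rows <- list()
  for (ct in design$condition_contrasts) {
    a <- data[data$condition == ct[1], c("subject", "value")]
    b <- data[data$condition == ct[2], c("subject", "value")]
    m <- dplyr::inner_join(a, b, by = "subject", suffix = c("_a", "_b"))
    if (nrow(m) < 2) stop("missing cell for contrast ",
                          paste(ct, collapse = " vs "))
    tt <- stats::t.test(m$value_a, m$value_b, paired = TRUE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      type = "condition", contrast = paste(ct[1], "vs", ct[2]),
      condition = NA_character_,
      estimate = unname(tt$estimate), statistic = unname(tt$statistic),
      df = unname(tt$parameter), p.value = tt$p.value,
      alpha = design$alpha_condition)
  }
  for (cond in intersect(design$conditions, unique(data$condition))) {
    dsub <- data[data$condition == cond, ]
    for (ct in design$group_contrasts) {
      a <- dsub$value[dsub$group == ct[1]]
      b <- dsub$value[dsub$group == ct[2]]
      if (length(a) < 2 || length(b) < 2) {
        stop("missing cell for contrast ", paste(ct, collapse = " vs "))
      }
      tt <- stats::t.test(a, b, var.equal = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        type = "group", contrast = paste(ct[1], "vs", ct[2]),
        condition = cond,
        estimate = mean(a) - mean(b), statistic = unname(tt$statistic),
        df = unname(tt$parameter), p.value = tt$p.value,
        alpha = design$alpha_group)
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      significant = .data$p.value < .data$alpha,
      direction = dplyr::case_when(
        !.data$significant ~ "none",
        .data$estimate > 0 ~ "increase",
        TRUE ~ "decrease"))
}

#' Advisory normality and homogeneity screening
#'
#' Kolmogorov-Smirnov normality checks per group/condition cell and a
#' Levene-type (Brown-Forsythe, median-centred) homogeneity check across
#' groups. Advisory only: results never gate the pipeline.
#'
#' @param data Tibble with columns `value`, `group`, `condition`.
#' @return Tibble with columns `check`, `cell`, `statistic`, `p.value`.
#' @export
screen_assumptions <- function(data) {
  data <- tibble::as_tibble(data)
  rows <- data |>
    dplyr::group_by(.data$group, .data$condition) |>
    dplyr::group_map(function(d, key) {
      v <- d$value
      if (length(v) < 3 || stats::sd(v) == 0) {
        return(tibble::tibble(check = "ks_normality",
                              cell = paste(key$group, key$condition),
                              statistic = NA_real_, p.value = NA_real_))
      }
      kt <- suppressWarnings(
        stats::ks.test(scale(v), "pnorm"))
      tibble::tibble(check = "ks_normality",
                     cell = paste(key$group, key$condition),
                     statistic = unname(kt$statistic), p.value = kt$p.value)
    }) |> dplyr::bind_rows()
  # Brown-Forsythe: one-way ANOVA on |value - group median|
  z <- abs(data$value - stats::ave(data$value, data$group,
                                   FUN = stats::median))
  lv <- tryCatch({
    fit <- stats::aov(z ~ factor(data$group))
    tab <- summary(fit)[[1]]
    tibble::tibble(check = "levene_homogeneity", cell = "groups",
                   statistic = tab[1, "F value"],
                   p.value = tab[1, "Pr(>F)"])
  }, error = function(e) tibble::tibble(check = "levene_homogeneity",
                                        cell = "groups",
                                        statistic = NA_real_,
                                        p.value = NA_real_))
  dplyr::bind_rows(rows, lv)
}
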