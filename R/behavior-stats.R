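#' Trial rejection
#'
#' Indices of retained trials: the target was identified (`correct`) and no
#' eye movement was flagged. Order is preserved; a trial failing both rules
#' is counted once.
#'
#' @param behavior Trial tibble with logical `correct` and `eye_movement`.
#' @return Integer vector of retained row indices.
#' @export
reject_trials <- function(behavior) {
  stopifnot(all(c("correct", "eye_movement") %in% names(behavior)))
  which(behavior$correct & !behavior$eye_movement)
}

#' Participant exclusion report
#'
#' Applies the three participant-level screens in a single pass, on
#' pre-exclusion group statistics:
#' \itemize{
#'   \item accuracy: excluded when overall accuracy is strictly below the
#'     group mean minus 2 group SDs (the flagged subject's own accuracy is
#'     part of the group statistics);
#'   \item distractor-similarity effect: retained only when a trial-level
#'     Welch t test of correct-trial RTs, most-similar (D1) versus
#'     least-similar (D4) distractor, is significant (two-sided p < 0.05)
#'     with mean RT(D1) > mean RT(D4); a subject with no correct trials in
#'     either cell is unevaluable and excluded;
#'   \item spatial-cue effect: the cued-versus-uncued t test is reported
#'     for audit but never excludes.
#' }
#'
#' @param behavior Trial tibble for the whole cohort with columns
#'   `subject`, `cue_presence`, `distractor`, `rt_ms`, `correct`,
#'   `eye_movement`.
#' @return Tibble with one row per subject: accuracy, group mean/SD, the
#'   test statistics, the per-rule flags, and
#'   `final_included = !(accuracy_excluded | similarity_excluded)`.
#' @export
exclude_subjects <- function(behavior) {
  subjects <- unique(behavior$subject)
  if (length(subjects) < 3) stop("need at least 3 subjects")

  acc <- vapply(subjects, function(s) {
    mean(behavior$correct[behavior$subject == s])
  }, numeric(1))
  g_mean <- mean(acc)
  g_sd <- stats::sd(acc)

  one <- function(s, a) {
    b <- behavior[behavior$subject == s & behavior$correct, ]
    d1 <- b$rt_ms[b$distractor == "D1"]
    d4 <- b$rt_ms[b$distractor == "D4"]
    if (length(d1) < 2 || length(d4) < 2) {
      sim <- list(stat = NA_real_, p = NA_real_, excl = TRUE)
    } else {
      tt <- stats::t.test(d1, d4) # Welch, two-sided
      sim <- list(stat = unname(tt$statistic), p = tt$p.value,
                  excl = !(tt$p.value < 0.05 && mean(d1) > mean(d4)))
    }
    cued <- b$rt_ms[b$cue_presence == "cued"]
    uncued <- b$rt_ms[b$cue_presence == "uncued"]
    if (length(cued) < 2 || length(uncued) < 2) {
      cue <- list(stat = NA_real_, p = NA_real_)
    } else {
      ct <- stats::t.test(uncued, cued)
      cue <- list(stat = unname(ct$statistic), p = ct$p.value)
    }
    acc_excl <- a < g_mean - 2 * g_sd # strictly below
    tibble::tibble(
      subject = s, accuracy = a, group_mean = g_mean, group_sd = g_sd,
      accuracy_excluded = acc_excl,
      d1_d4_t = sim$stat, d1_d4_p = sim$p, similarity_excluded = sim$excl,
      cue_effect_t = cue$stat, cue_effect_p = cue$p,
      final_included = !(acc_excl || sim$excl)
    )
  }
  dplyr::bind_rows(Map(one, subjects, acc))
}

#' Per-subject condition cell means
#'
#' Mean reaction time (retained trials: correct, no eye movement) and
#' accuracy (all trials) per subject and cue-presence x distractor cell.
#'
#' @param behavior Cohort trial tibble (see [exclude_subjects()]).
#' @return Tibble: `subject`, `cue_presence`, `distractor`, `rt_ms`
#'   (mean RT of retained trials), `accuracy`, `n_retained`.
#' @export
subject_cell_means <- function(behavior) {
  behavior |>
    dplyr::group_by(.data$subject, .data$cue_presence, .data$distractor) |>
    dplyr::summarise(
      rt_ms = mean(.data$rt_ms[.data$correct & !.data$eye_movement]),
      accuracy = mean(.data$correct),
      n_retained = sum(.data$correct & !.data$eye_movement),
      .groups = "drop"
    )
}

#' Two-way repeated-measures ANOVA
#'
#' Classical within-subject sums-of-squares decomposition for a fully
#' crossed two-factor repeated-measures design: each effect (factor A,
#' factor B, interaction) is tested against its own effect-by-subject
#' interaction. No sphericity correction is applied. With the 2 x 4
#' cue-by-distractor design the degrees of freedom are cue (1, n-1),
#' distractor (3, 3(n-1)), interaction (3, 3(n-1)).
#'
#' @param cell_means Long tibble with one row per subject x cell, columns
#'   named by the following arguments.
#' @param value Name of the response column (e.g. `"rt_ms"`).
#' @param factor_a,factor_b Names of the two within-subject factor columns.
#' @param subject Name of the subject column.
#' @return Object of class `rm_anova` with a per-effect table (`F`,
#'   `df_num`, `df_den`, `p`); see [tidy.rm_anova()].
#' @examples
#' cm <- subject_cell_means(simulate_behavior(
#'   generate_schedule(sim_params(trials_per_condition = 24), 1),
#'   sim_params(), 2) |> dplyr::mutate(subject = "S01"))
#' @export
rm_anova_2x4 <- function(cell_means, value = "rt_ms",
                         factor_a = "cue_presence", factor_b = "distractor",
                         subject = "subject") {
  df <- as.data.frame(cell_means)
  y <- df[[value]]
  A <- factor(df[[factor_a]])
  B <- factor(df[[factor_b]])
  S <- factor(df[[subject]])
  a <- nlevels(A); b <- nlevels(B); n <- nlevels(S)
  if (n < 2) stop("need at least 2 subjects")
  if (nrow(df) != a * b * n || any(table(A, B, S) != 1)) {
    stop("design must be complete: one value per subject x cell")
  }
  if (any(!is.finite(y))) stop("missing cell means")

  g <- mean(y)
  m_a <- tapply(y, A, mean); m_b <- tapply(y, B, mean)
  m_s <- tapply(y, S, mean)
  m_ab <- tapply(y, list(A, B), mean)
  m_as <- tapply(y, list(A, S), mean)
  m_bs <- tapply(y, list(B, S), mean)

  ss_a <- b * n * sum((m_a - g)^2)
  ss_b <- a * n * sum((m_b - g)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + g)^2)
  ss_as <- b * sum((m_as - outer(m_a, rep(1, n)) -
                      outer(rep(1, a), m_s) + g)^2)
  ss_bs <- a * sum((m_bs - outer(m_b, rep(1, n)) -
                      outer(rep(1, b), m_s) + g)^2)
  ss_s <- a * b * sum((m_s - g)^2)
  ss_tot <- sum((y - g)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs

  eff <- function(name, ss_eff, df_eff, ss_err, df_err) {
    ms_eff <- ss_eff / df_eff
    ms_err <- ss_err / df_err
    # a zero effect is F = 0 even when its error stratum is also zero
    f <- if (ss_eff <= 1e-12 * max(ss_tot, 1)) 0 else ms_eff / ms_err
    tibble::tibble(
      effect = name, ss = ss_eff, ss_error = ss_err,
      df_num = df_eff, df_den = df_err, F = f,
      p = stats::pf(f, df_eff, df_err, lower.tail = FALSE)
    )
  }
  table <- dplyr::bind_rows(
    eff(factor_a, ss_a, a - 1, ss_as, (a - 1) * (n - 1)),
    eff(factor_b, ss_b, b - 1, ss_bs, (b - 1) * (n - 1)),
    eff(paste0(factor_a, ":", factor_b), ss_ab, (a - 1) * (b - 1),
        ss_abs, (a - 1) * (b - 1) * (n - 1))
  )
  structure(
    list(table = table, n_subjects = n, levels = c(a = a, b = b),
         value = value),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("<rm_anova> ", x$levels[["a"]], " x ", x$levels[["b"]],
      " within-subject ANOVA on `", x$value, "`, n = ", x$n_subjects,
      " subjects\n", sep = "")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-28s F(%d,%d) = %.3f, p = %.4g\n", tab$effect[i],
                tab$df_num[i], tab$df_den[i], tab$F[i], tab$p[i]))
  }
  invisible(x)
}

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return Tibble with `term`, `df_num`, `df_den`, `sumsq`, `statistic`
#'   (F), `p.value`.
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(
    term = x$table$effect, df_num = x$table$df_num,
    df_den = x$table$df_den, sumsq = x$table$ss,
    statistic = x$table$F, p.value = x$table$p
  )
}

#' @rdname tidy.rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 n_cells = prod(x$levels),
                 min_p = min(x$table$p))
}

#' Bonferroni-corrected paired contrasts
#'
#' Two-sided paired t test for each requested contrast between condition
#' cells; p-values are multiplied by the family size and capped at 1.
#'
#' @param cell_means Long tibble with columns `subject`, `cell`, `value`
#'   (one row per subject x cell). Build `cell` by pasting the factors,
#'   e.g. `"cued.D1"`.
#' @param contrasts List of 2-element character vectors naming the cells
#'   to compare; `NULL` uses all pairwise combinations.
#' @return Tibble: `contrast`, `estimate` (mean difference), `statistic`,
#'   `df`, `p.value` (raw), `p.adjusted` (Bonferroni, capped at 1).
#' @export
pairwise_bonferroni <- function(cell_means, contrasts = NULL) {
  wide <- tidyr::pivot_wider(cell_means[, c("subject", "cell", "value")],
                             names_from = "cell", values_from = "value")
  if (nrow(wide) < 2) stop("need at least 2 subjects")
  cells <- setdiff(names(wide), "subject")
  if (is.null(contrasts)) {
    contrasts <- utils::combn(cells, 2, simplify = FALSE)
  }
  fam <- length(contrasts)
  rows <- lapply(contrasts, function(cc) {
    stopifnot(length(cc) == 2, all(cc %in% cells))
    d <- wide[[cc[1]]] - wide[[cc[2]]]
    if (stats::sd(d) == 0) {
      est <- mean(d)
      stat <- if (est == 0) 0 else sign(est) * Inf
      p <- if (est == 0) 1 else 0
      dfree <- length(d) - 1
    } else {
      tt <- stats::t.test(d)
      est <- unname(tt$estimate); stat <- unname(tt$statistic)
      p <- tt$p.value; dfree <- unname(tt$parameter)
    }
    tibble::tibble(
      contrast = paste(cc[1], "-", cc[2]), estimate = est,
      statistic = stat, df = dfree, p.value = p,
      p.adjusted = pmin(1, p * fam)
    )
  })
  dplyr::bind_rows(rows)
}

#' One-sample t test of accuracies against chance
#'
#' Two-sided one-sample t of per-subject accuracies against a chance
#' proportion. With three response alternatives chance is exactly 1/3;
#' after ruling out the letter shown in the distractor it is 1/2. When all
#' subjects have identical accuracy the t statistic is degenerate and the
#' exact decision is reported instead: `t = 0, p = 1` at chance, otherwise
#' a signed infinite statistic with `p = 0` and `zero_variance = TRUE`.
#'
#' @param accuracies Numeric vector of per-subject accuracies (n >= 2).
#' @param chance Chance proportion (default `1/3`).
#' @return One-row tibble: `estimate` (mean accuracy), `chance`,
#'   `statistic`, `df`, `p.value`, `zero_variance`.
#' @export
t_vs_chance <- function(accuracies, chance = 1 / 3) {
  n <- length(accuracies)
  if (n < 2) stop("need at least 2 subjects")
  m <- mean(accuracies)
  if (stats::sd(accuracies) == 0) {
    diff0 <- m - chance
    return(tibble::tibble(
      estimate = m, chance = chance,
      statistic = if (diff0 == 0) 0 else sign(diff0) * Inf,
      df = n - 1, p.value = if (diff0 == 0) 1 else 0,
      zero_variance = TRUE
    ))
  }
  tt <- stats::t.test(accuracies, mu = chance)
  tibble::tibble(
    estimate = m, chance = chance, statistic = unname(tt$statistic),
    df = unname(tt$parameter), p.value = tt$p.value, zero_variance = FALSE
  )
}

#' Expected accuracy when guessing from the distractor letter
#'
#' With three possible target letters and a distractor letter that is never
#' the target's, a guesser who reads the distractor letter picks uniformly
#' between the two remaining letters, one of which is the target: expected
#' accuracy is exactly 1/2. Ignoring the distractor gives 1/3.
#'
#' @param n_letters Number of response alternatives (default 3).
#' @param use_distractor Whether the guesser eliminates the distractor
#'   letter.
#' @return Expected accuracy as a proportion.
#' @examples
#' chance_level() # 1/3
#' chance_level(use_distractor = TRUE) # 0.5
#' @export
chance_level <- function(n_letters = 3, use_distractor = FALSE) {
  if (use_distractor) 1 / (n_letters - 1) else 1 / n_letters
}
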