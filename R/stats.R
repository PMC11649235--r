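new_etho_test <- function(test, statistic, df, p, comparisons = NULL,
                          method = test) {
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 comparisons = comparisons, method = method),
            class = "etho_test")
}

#' @export
print.etho_test <- function(x, ...) {
  dfs <- paste(signif(unlist(x$df), 4), collapse = ", ")
  cat(sprintf("<etho_test> %s: statistic = %.4g, df = (%s), p = %.4g\n",
              x$method, x$statistic, dfs, x$p))
  if (!is.null(x$comparisons)) {
    cat(sprintf("  %d Tukey-adjusted pairwise comparisons\n",
                nrow(x$comparisons)))
  }
  invisible(x)
}

#' @export
tidy.etho_test <- function(x, ...) {
  if (!is.null(x$comparisons)) return(x$comparisons)
  tibble(term = x$test, statistic = x$statistic,
         df1 = unlist(x$df)[1],
         df2 = if (length(unlist(x$df)) > 1) unlist(x$df)[2] else NA_real_,
         p.value = x$p)
}

#' @export
glance.etho_test <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p.value = x$p)
}

resolve_samples <- function(data, value, group) {
  if (is.numeric(data) && is.numeric(value)) {
    return(list(a = data, b = value))
  }
  value <- enquo(value); group <- enquo(group)
  v <- dplyr::pull(data, !!value)
  g <- dplyr::pull(data, !!group)
  sp <- split(v, g)
  if (length(sp) != 2L) {
    stop_scsflight("Welch t-test needs exactly two groups.",
                   "scsflight_input_error")
  }
  list(a = sp[[1]], b = sp[[2]])
}

#' Welch's unpaired t-test
#'
#' Unpaired two-sample t-test with Welch's correction (unequal variances;
#' Welch-Satterthwaite degrees of freedom), two-sided.
#'
#' @param data A data frame (then give `value` and `group` columns) or a
#'   numeric vector (then `value` is the second sample).
#' @param value Column of measurements, or the second numeric sample.
#' @param group Two-level grouping column (data-frame interface).
#' @return An `etho_test` with `statistic` (t), `df` and `p`; use [tidy()] /
#'   [glance()] for tibble output.
#' @export
welch_t <- function(data, value, group = NULL) {
  s <- resolve_samples(data, {{ value }}, {{ group }})
  if (length(s$a) < 2 || length(s$b) < 2) {
    stop_scsflight("Each sample needs n >= 2.", "scsflight_input_error")
  }
  if (stats::var(s$a) == 0 && stats::var(s$b) == 0) {
    # degenerate: t.test() errors on two constant samples; identical constants
    # are a no-difference result
    if (mean(s$a) == mean(s$b)) {
      return(new_etho_test("welch_t", 0, list(df = length(s$a) + length(s$b) - 2),
                           1, method = "Welch two-sample t-test"))
    }
    stop_scsflight("Both samples have zero variance.", "scsflight_input_error")
  }
  ht <- stats::t.test(s$a, s$b, var.equal = FALSE)
  new_etho_test("welch_t", unname(ht$statistic), list(df = unname(ht$parameter)),
                ht$p.value, method = "Welch two-sample t-test")
}

#' One-way ANOVA with optional Tukey HSD
#'
#' Ordinary one-way fixed-effects analysis of variance across groups, with
#' Tukey's post-hoc multiple comparisons (studentized-range adjusted p values)
#' on request.
#'
#' @param data Data frame, or a list of numeric samples.
#' @param value,group Columns (data-frame interface).
#' @param tukey If `TRUE`, attach Tukey HSD pairwise comparisons.
#' @return An `etho_test` with `statistic` (F), `df = (df1, df2)`, `p`, and —
#'   when `tukey` — a `comparisons` tibble (`pair`, `estimate`, `adj.p`).
#' @export
anova_oneway <- function(data, value = NULL, group = NULL, tukey = FALSE) {
  if (is.list(data) && !is.data.frame(data)) {
    df <- bind_rows(purrr::imap(data, function(v, i)
      tibble(.value = v, .group = as.character(i))))
  } else {
    df <- tibble(.value = dplyr::pull(data, {{ value }}),
                 .group = as.character(dplyr::pull(data, {{ group }})))
  }
  ns <- table(df$.group)
  if (length(ns) < 2L) {
    stop_scsflight("Need at least two groups.", "scsflight_input_error")
  }
  if (any(ns < 2)) {
    stop_scsflight("Every group needs n >= 2.", "scsflight_input_error")
  }
  df$.group <- factor(df$.group)
  if (stats::var(df$.value) < 1e-20) {
    # all values identical: no effect by convention (aov would divide noise
    # by noise)
    return(new_etho_test("anova1", 0,
                         list(df1 = length(ns) - 1, df2 = nrow(df) - length(ns)),
                         1, method = "One-way ANOVA"))
  }
  fit <- stats::aov(.value ~ .group, data = df)
  sm <- summary(fit)[[1]]
  Fv <- sm$`F value`[1]
  p <- sm$`Pr(>F)`[1]
  if (is.na(Fv)) { Fv <- 0; p <- 1 }  # zero residual variance, no group effect
  comparisons <- NULL
  if (tukey) {
    tk <- stats::TukeyHSD(fit)$.group
    comparisons <- tibble(pair = rownames(tk), estimate = tk[, "diff"],
                          adj.p = tk[, "p adj"])
  }
  new_etho_test("anova1", Fv, list(df1 = sm$Df[1], df2 = sm$Df[2]), p,
                comparisons = comparisons, method = "One-way ANOVA")
}

#' Two-way fixed-effects ANOVA (trial x group)
#'
#' Tests the interaction and both main effects of two crossed fixed factors
#' (typically trial and conditioning group) without repeated-measures
#' structure. Unbalanced designs use Type II sums of squares.
#'
#' @param data Data frame.
#' @param value Measurement column.
#' @param trial,group Factor columns.
#' @param ss_type Sums-of-squares type for unbalanced cells (2 or 3).
#' @return A tibble with one row per term (`group`, `trial`,
#'   `group:trial`): `term, sumsq, df1, df2, statistic, p.value`, plus the SS
#'   type as an attribute.
#' @export
anova_twoway <- function(data, value, trial, group, ss_type = 2) {
  df <- tibble(.value = dplyr::pull(data, {{ value }}),
               .trial = factor(dplyr::pull(data, {{ trial }})),
               .group = factor(dplyr::pull(data, {{ group }})))
  cells <- table(df$.trial, df$.group)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop_scsflight(sprintf("Empty cell: trial %s x group %s.",
                           rownames(cells)[bad[1]], colnames(cells)[bad[2]]),
                   "scsflight_input_error")
  }
  fit <- stats::lm(.value ~ .group * .trial, data = df)
  if (all(abs(stats::residuals(fit)) < 1e-12) &&
      stats::var(df$.value) < 1e-24) {
    # all values identical: every F is 0 by convention
    terms <- c("group", "trial", "group:trial")
    return(structure(tibble(term = terms, sumsq = 0,
                            df1 = NA_real_, df2 = NA_real_,
                            statistic = 0, p.value = 1),
                     ss_type = ss_type))
  }
  an <- car::Anova(fit, type = ss_type)
  rn <- rownames(an)
  resid_df <- an$Df[rn == "Residuals"]
  pick <- function(nm) which(rn == nm)
  out <- tibble(
    term = c("group", "trial", "group:trial"),
    sumsq = an$`Sum Sq`[c(pick(".group"), pick(".trial"),
                          pick(".group:.trial"))],
    df1 = an$Df[c(pick(".group"), pick(".trial"), pick(".group:.trial"))],
    df2 = resid_df,
    statistic = an$`F value`[c(pick(".group"), pick(".trial"),
                               pick(".group:.trial"))],
    p.value = an$`Pr(>F)`[c(pick(".group"), pick(".trial"),
                            pick(".group:.trial"))]
  )
  structure(out, ss_type = ss_type)
}
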