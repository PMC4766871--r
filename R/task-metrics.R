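#' @title Information Sampling Task scoring
#' @description Helpers for the 5x5 box-opening task: probability the chosen
#'   colour is the board majority given the opened evidence, the two reward
#'   schedules, and the sampling/discrimination error classification.
#' @name ist_scoring
NULL

# Normalise an IST trial to: 25 grid colours (row-major), 0-based linear
# indices of opened cells, the choice label and the pair of colour labels.
parse_ist_trial <- function(trial) {
  g <- trial$grid
  if (is.matrix(g)) {
    if (!all(dim(g) == c(5L, 5L))) stop("IST grid must be 5 x 5", call. = FALSE)
    cells <- as.vector(t(g))                  # row-major
  } else if (is.character(g) && length(g) == 1L) {
    cells <- strsplit(g, "")[[1L]]
  } else {
    cells <- as.character(g)
  }
  if (length(cells) != 25L) stop("IST grid must have 25 cells", call. = FALSE)
  cols <- sort(unique(cells))
  if (length(cols) > 2L) stop("IST grid must use exactly two colours", call. = FALSE)

  op <- trial$opened
  if (is.character(op) && length(op) == 1L) {
    pairs <- strsplit(strsplit(op, ";")[[1L]], ",")
    op <- do.call(rbind, lapply(pairs, as.integer))
  }
  if (is.null(dim(op))) op <- matrix(as.integer(op), ncol = 2L, byrow = TRUE)
  if (any(op < 0L) || any(op > 4L)) {
    stop("opened cell coordinates must be 0-based within the 5 x 5 grid",
         call. = FALSE)
  }
  lin <- op[, 1L] * 5L + op[, 2L] + 1L
  if (anyDuplicated(lin)) stop("opened cells must be distinct", call. = FALSE)
  if (length(lin) < 1L || length(lin) > 25L) {
    stop("between 1 and 25 cells must be opened", call. = FALSE)
  }
  choice <- as.character(trial$choice)
  list(cells = cells, opened_idx = lin, opened_cols = cells[lin],
       choice = choice)
}

#' P(correct): probability the chosen colour is the board majority
#'
#' Treats every unopened box as an independent fair coin (the task's
#' generative colour split is close to 50:50) and returns the exact
#' probability that the chosen colour ends up with at least 13 of the 25
#' cells. With `m` opened cells of the chosen colour and `u` unopened
#' cells this is the binomial tail \eqn{\sum_{j \ge 13-m} \binom{u}{j} 2^{-u}},
#' evaluated in exact integer arithmetic (all quantities are well within
#' double precision for \eqn{u \le 24}).
#'
#' @param trial List or one-row data frame with `grid` (25-character string,
#'   row-major, or 5x5 matrix), `opened` (n x 2 matrix of 0-based row/col,
#'   or a `"r,c;r,c"` string) and `choice` (colour label).
#' @return Probability in `[0, 1]`.
#' @export
ist_p_correct <- function(trial) {
  p <- parse_ist_trial(trial)
  m <- sum(p$opened_cols == p$choice)
  u <- 25L - length(p$opened_idx)
  need <- 13L - m
  if (need <= 0L) return(1)
  if (need > u) return(0)
  sum(choose(u, need:u)) / 2^u
}

#' Points awarded on one IST trial
#'
#' Fixed-win: 100 points for a correct decision regardless of boxes opened.
#' Decreasing-win: the win starts at 250 and drops by 10 per box opened
#' (floored at 0 by default). An incorrect decision loses `penalty` points
#' under either schedule.
#'
#' @inheritParams ist_p_correct
#' @param condition `"fixed_win"` or `"decreasing_win"`; defaults to the
#'   trial's own `condition` field.
#' @param schedule Named list overriding `fixed_win` (100),
#'   `decreasing_start` (250), `decreasing_step` (10), `penalty` (100),
#'   `floor` (0).
#' @return Integer points (negative for an incorrect decision).
#' @export
ist_points <- function(trial, condition = NULL, schedule = list()) {
  sch <- utils::modifyList(
    list(fixed_win = 100, decreasing_start = 250, decreasing_step = 10,
         penalty = 100, floor = 0),
    schedule)
  if (is.null(condition)) condition <- trial$condition
  condition <- match.arg(condition, c("fixed_win", "decreasing_win"))
  p <- parse_ist_trial(trial)
  correct <- p$choice == ist_majority(p$cells)
  if (!correct) return(-sch$penalty)
  if (condition == "fixed_win") {
    sch$fixed_win
  } else {
    max(sch$decreasing_start - sch$decreasing_step * length(p$opened_idx),
        sch$floor)
  }
}

# Majority colour of a 25-cell board (25 is odd, so no board tie exists).
ist_majority <- function(cells) {
  tab <- table(cells)
  names(tab)[which.max(tab)]
}

#' Classify an IST decision error
#'
#' A correct decision (choice equals the true board majority) is `"none"`.
#' An incorrect decision that nevertheless followed the majority of the
#' opened boxes is a `"sampling_error"` — the evidence was insufficient,
#' not misread. An incorrect decision against the opened-box majority is a
#' `"discrimination_error"`; a tie among opened boxes counts as a sampling
#' error.
#'
#' @inheritParams ist_p_correct
#' @return One of `"none"`, `"sampling_error"`, `"discrimination_error"`.
#' @export
ist_error_type <- function(trial) {
  p <- parse_ist_trial(trial)
  if (p$choice == ist_majority(p$cells)) return("none")
  n_choice <- sum(p$opened_cols == p$choice)
  n_other <- length(p$opened_cols) - n_choice
  if (n_choice < n_other) "discrimination_error" else "sampling_error"
}

#' The 27-item Monetary Choice Questionnaire
#'
#' Loads the questionnaire's item table (immediate amount, delayed amount,
#' delay in days). The canonical published amounts ship as an editable CSV
#' fixture; pass `path` to use a different item set. The per-item
#' indifference rate `k_indiff = (delayed/immediate - 1) / delay` is added.
#'
#' @param path Optional path to a CSV with columns `item_id`,
#'   `immediate_amount`, `delayed_amount`, `delay_days`.
#' @return Data frame of items with `k_indiff`.
#' @export
kirby_items <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mcq_items.csv", package = "reflectimp",
                        mustWork = TRUE)
  }
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "immediate_amount", "delayed_amount", "delay_days")
  if (!all(need %in% names(items))) {
    stop("MCQ item file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(items$immediate_amount <= 0) ||
      any(items$delayed_amount <= items$immediate_amount) ||
      any(items$delay_days <= 0)) {
    stop("MCQ items must satisfy delayed > immediate > 0 and delay > 0",
         call. = FALSE)
  }
  items$k_indiff <- (items$delayed_amount / items$immediate_amount - 1) /
    items$delay_days
  items
}

#' Estimate the hyperbolic discount rate k from MCQ responses
#'
#' Each item defines an indifference rate; a hyperbolic discounter with
#' rate `k` prefers the immediate reward exactly when `k` exceeds the
#' item's indifference rate. The estimate is the candidate rate (among the
#' item indifference rates) whose implied choice pattern agrees with the
#' observed responses on the most items; ties are resolved by the geometric
#' mean of all maximising candidates. Consistency is the maximal agreement
#' as a proportion of items.
#'
#' @param responses Character vector of `"immediate"` / `"delayed"`, one
#'   per item, in item order.
#' @param items Item table from [kirby_items()].
#' @return List with `k`, `consistency`, `maximizers` (all candidates that
#'   achieve the maximal agreement) and `candidates` (the sorted
#'   indifference rates).
#' @export
kirby_k <- function(responses, items = kirby_items()) {
  responses <- as.character(responses)
  if (length(responses) != nrow(items)) {
    stop(sprintf("expected %d responses, got %d", nrow(items),
                 length(responses)), call. = FALSE)
  }
  if (!all(responses %in% c("immediate", "delayed"))) {
    stop("responses must be 'immediate' or 'delayed'", call. = FALSE)
  }
  imm <- responses == "immediate"
  candidates <- sort(unique(items$k_indiff))
  agreement <- vapply(candidates, function(k) {
    sum((k > items$k_indiff) == imm)
  }, numeric(1))
  best <- max(agreement)
  maximizers <- candidates[agreement == best]
  list(k = exp(mean(log(maximizers))),
       consistency = best / nrow(items),
       maximizers = maximizers,
       candidates = candidates)
}

#' Remove per-group outliers beyond 3 SD of the group mean
#'
#' Single pass: a value is removed when it lies more than 3 standard
#' deviations (sample SD) from its own group's mean. Groups with zero SD
#' remove nothing.
#'
#' @param x Numeric values.
#' @param group Group label per value.
#' @param ids Optional identifiers per value (defaults to indices).
#' @param n_sd Threshold in SD units (default 3).
#' @return List with `kept` (logical vector) and `removed` (ids of removed
#'   values).
#' @export
remove_outliers <- function(x, group, ids = seq_along(x), n_sd = 3) {
  stopifnot(length(x) == length(group), length(ids) == length(x))
  kept <- rep(TRUE, length(x))
  for (g in unique(group)) {
    sel <- which(group == g & !is.na(x))
    if (length(sel) < 3L) next
    m <- mean(x[sel]); s <- stats::sd(x[sel])
    if (!is.finite(s) || s == 0) next
    kept[sel] <- abs(x[sel] - m) <= n_sd * s
  }
  list(kept = kept, removed = ids[!kept])
}

# 2x2 mixed ANOVA (between: group, within: condition, one observation per
# subject x condition) via aov with a subject error stratum.
mixed_anova_2x2 <- function(y_c1, y_c2, group) {
  n <- length(group)
  long <- data.frame(
    y = c(y_c1, y_c2),
    condition = factor(rep(c("c1", "c2"), each = n)),
    group = factor(rep(group, 2L)),
    subject = factor(rep(seq_len(n), 2L))
  )
  fit <- stats::aov(y ~ group * condition + Error(subject), data = long)
  sm <- summary(fit)
  between <- sm[["Error: subject"]][[1L]]
  within <- sm[["Error: Within"]][[1L]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    c(F = tab[i, "F value"], df1 = tab[i, "Df"],
      df2 = tab[nrow(tab), "Df"], p = tab[i, "Pr(>F)"])
  }
  rbind(group = pick(between, "group"),
        cost = pick(within, "condition"),
        `group:cost` = pick(within, "group:condition"))
}

#' Group statistics for the behavioural outcome battery
#'
#' Applies the battery's standard transforms (square root for beads and IST
#' outcomes, log10 for the discount rate k), then runs two-sided
#' pooled-variance t-tests on the primary outcomes, a 2x2 mixed ANOVA
#' (between: group; within: reward condition) on the IST secondary
#' outcomes, a Wilcoxon rank-sum test on the fitted cognitive noise when
#' present, and Pearson correlations of beads draws against any severity
#' covariates. Transformed values are computed on the fly; the input table
#' is never modified, so the original scale is always recoverable.
#'
#' @param table One row per subject with columns `subject_id`, `group`
#'   (two levels; `"HV"`/`"BD"` ordered HV first when present) and any of:
#'   `beads_draws_mean`, `ist_boxes_fixed`, `ist_boxes_decreasing`,
#'   `k_value`, paired secondary columns `<outcome>_fixed` /
#'   `<outcome>_decreasing` for `ist_points`, `ist_pcorrect`,
#'   `ist_sampling_error`, a fitted-noise column `map_t`, and covariate
#'   columns named `audit` or prefixed `cov_`.
#' @param welch Use Welch instead of pooled-variance t-tests.
#' @return Tidy data frame: `test`, `outcome`, `statistic`, `df`, `p`,
#'   `n_1`, `n_2` (group sizes in group-level order; `n_2` is `NA` for
#'   correlations, which pool the groups).
#' @export
group_tests <- function(table, welch = FALSE) {
  if (!all(c("subject_id", "group") %in% names(table))) {
    stop("table needs `subject_id` and `group` columns", call. = FALSE)
  }
  lv <- unique(as.character(table$group))
  if (length(lv) != 2L) stop("exactly two groups are required", call. = FALSE)
  if (all(c("HV", "BD") %in% lv)) lv <- c("HV", "BD")
  g <- factor(table$group, levels = lv)
  rows <- list()
  add <- function(test, outcome, statistic, df, p, n1, n2) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, outcome = outcome, statistic = statistic, df = df, p = p,
      n_1 = n1, n_2 = n2, stringsAsFactors = FALSE)
  }

  run_t <- function(values, outcome) {
    ok <- !is.na(values)
    tt <- stats::t.test(values[ok & g == lv[1]], values[ok & g == lv[2]],
                        var.equal = !welch)
    add("t", outcome, unname(tt$statistic), unname(tt$parameter),
        tt$p.value, sum(ok & g == lv[1]), sum(ok & g == lv[2]))
  }

  if ("beads_draws_mean" %in% names(table)) {
    run_t(sqrt(table$beads_draws_mean), "beads_draws_sqrt")
  }
  for (cc in c("ist_boxes_fixed", "ist_boxes_decreasing")) {
    if (cc %in% names(table)) run_t(sqrt(table[[cc]]), paste0(cc, "_sqrt"))
  }
  if ("k_value" %in% names(table)) {
    bad <- which(!is.na(table$k_value) & table$k_value <= 0)
    if (length(bad)) {
      stop("non-positive k for subject(s): ",
           paste(table$subject_id[bad], collapse = ", "), call. = FALSE)
    }
    run_t(log10(table$k_value), "k_log10")
  }

  for (out in c("ist_points", "ist_pcorrect", "ist_sampling_error")) {
    c1 <- paste0(out, "_fixed"); c2 <- paste0(out, "_decreasing")
    if (all(c(c1, c2) %in% names(table))) {
      ok <- !is.na(table[[c1]]) & !is.na(table[[c2]])
      an <- mixed_anova_2x2(table[[c1]][ok], table[[c2]][ok], g[ok])
      for (eff in rownames(an)) {
        add("mixed_anova_F", paste(out, eff, sep = ":"),
            an[eff, "F"], an[eff, "df2"], an[eff, "p"],
            sum(ok & g == lv[1]), sum(ok & g == lv[2]))
      }
    }
  }

  if ("map_t" %in% names(table)) {
    ok <- !is.na(table$map_t)
    # grid-valued MAP estimates routinely tie; wilcox.test then falls back
    # to the normal approximation on its own
    wt <- suppressWarnings(
      stats::wilcox.test(table$map_t[ok & g == lv[1]],
                         table$map_t[ok & g == lv[2]]))
    add("wilcoxon", "map_t", unname(wt$statistic), NA_real_, wt$p.value,
        sum(ok & g == lv[1]), sum(ok & g == lv[2]))
  }

  covs <- c(intersect("audit", names(table)),
            grep("^cov_", names(table), value = TRUE))
  if ("beads_draws_mean" %in% names(table)) {
    for (cv in covs) {
      ok <- !is.na(table$beads_draws_mean) & !is.na(table[[cv]])
      ct <- stats::cor.test(table$beads_draws_mean[ok], table[[cv]][ok],
                            method = "pearson")
      add("pearson", paste0("beads_draws~", cv), unname(ct$estimate),
          unname(ct$parameter), ct$p.value, sum(ok), NA_integer_)
    }
  }

  do.call(rbind, rows)
}
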