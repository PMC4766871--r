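# helpers to build IST trials compactly: a 25-char grid with the first n
# cells "X", the rest "O", and an opened list over given linear indices
make_grid <- function(n_x) {
  paste(c(rep("X", n_x), rep("O", 25 - n_x)), collapse = "")
}
opened_str <- function(lin) {
  paste(paste((lin - 1) %/% 5, (lin - 1) %% 5, sep = ","), collapse = ";")
}

test_that("P(correct) handles the boundary cases exactly", {
  # whole board opened, majority chosen: certainty
  t1 <- list(grid = make_grid(13), opened = opened_str(1:25), choice = "X")
  expect_equal(ist_p_correct(t1), 1)
  # a single opened box of the chosen colour: Bin(24, 1/2) tail at 12
  t2 <- list(grid = make_grid(13), opened = opened_str(1), choice = "X")
  expect_equal(ist_p_correct(t2), sum(choose(24, 12:24)) / 2^24)
  expect_equal(ist_p_correct(t2), 0.5805901, tolerance = 1e-7)
  # 13 opened boxes all of the chosen colour: majority guaranteed
  t3 <- list(grid = make_grid(13), opened = opened_str(1:13), choice = "X")
  expect_equal(ist_p_correct(t3), 1)
  # chosen colour cannot reach 13 cells (no opened X, 12 unopened)
  t4 <- list(grid = make_grid(1), opened = opened_str(2:14), choice = "X")
  expect_equal(ist_p_correct(t4), 0)
})

test_that("P(correct) equals fair-coin enumeration and is monotone", {
  set.seed(17)
  for (rep in 1:12) {
    n_open <- sample(13:24, 1)           # u <= 12 keeps enumeration honest
    lin <- sample(25, n_open)
    g <- make_grid(sample(8:17, 1))
    cells <- strsplit(g, "")[[1]]
    choice <- sample(c("X", "O"), 1)
    trial <- list(grid = g, opened = opened_str(lin), choice = choice)
    expect_equal(ist_p_correct(trial), oracle_ist_p_correct(trial))
  }
  # opening one more cell of the chosen colour never lowers P(correct)
  g <- make_grid(17)
  x_cells <- 1:17
  p_seq <- vapply(1:14, function(m) {
    ist_p_correct(list(grid = g, opened = opened_str(x_cells[1:m]),
                       choice = "X"))
  }, numeric(1))
  expect_true(all(diff(p_seq) >= 0))
  expect_equal(p_seq[13:14], c(1, 1))
})

test_that("points follow the two reward schedules", {
  g <- make_grid(15)
  correct20 <- list(grid = g, opened = opened_str(1:20), choice = "X")
  expect_equal(ist_points(correct20, "fixed_win"), 100)
  correct5 <- list(grid = g, opened = opened_str(1:5), choice = "X")
  expect_equal(ist_points(correct5, "decreasing_win"), 200)
  correct25 <- list(grid = g, opened = opened_str(1:25), choice = "X")
  expect_equal(ist_points(correct25, "decreasing_win"), 0)
  wrong <- list(grid = g, opened = opened_str(1:5), choice = "O")
  expect_equal(ist_points(wrong, "fixed_win"), -100)
  expect_equal(ist_points(wrong, "decreasing_win"), -100)
  # schedule is configurable
  expect_equal(ist_points(wrong, "fixed_win", schedule = list(penalty = 0)), 0)
  # condition can come from the trial record itself
  correct5$condition <- "decreasing_win"
  expect_equal(ist_points(correct5), 200)
})

test_that("error classification distinguishes sampling from discrimination", {
  g_maj_x <- make_grid(14)
  # correct decision
  t0 <- list(grid = g_maj_x, opened = opened_str(1:3), choice = "X")
  expect_equal(ist_error_type(t0), "none")
  # chose against three opened X cells: discrimination error
  t1 <- list(grid = g_maj_x, opened = opened_str(1:3), choice = "O")
  expect_equal(ist_error_type(t1), "discrimination_error")
  # opened three O cells (true majority O board), chose with them but wrong
  g_maj_o <- make_grid(12)
  t2 <- list(grid = g_maj_o, opened = opened_str(1:3), choice = "X")
  expect_equal(ist_error_type(t2), "sampling_error")
  # exhaustive check over all 8 colourings of 3 opened cells; the 13 fixed
  # X cells keep the board majority at X whatever the opened cells show
  for (bits in 0:7) {
    cols <- ifelse(as.integer(intToBits(bits)[1:3]) == 1, "X", "O")
    cells <- c(cols, rep("X", 13), rep("O", 9))
    trial <- list(grid = paste(cells, collapse = ""),
                  opened = opened_str(1:3), choice = "O")
    n_o <- sum(cols == "O")
    want <- if (n_o > 1) "sampling_error" else "discrimination_error"
    # choice O is always wrong here (X is the 13-cell majority);
    # ties among opened cells cannot occur with 3 opened
    expect_equal(ist_error_type(trial), want)
  }
  # a 2-2 opened tie counts as a sampling error
  cells <- c("X", "X", "O", "O", rep("X", 11), rep("O", 10))
  t_tie <- list(grid = paste(cells, collapse = ""),
                opened = opened_str(1:4), choice = "O")
  expect_equal(ist_error_type(t_tie), "sampling_error")
})

test_that("IST trial validation catches malformed records", {
  expect_error(ist_p_correct(list(grid = "XO", opened = "0,0", choice = "X")),
               "25")
  expect_error(ist_p_correct(list(grid = make_grid(13), opened = "0,0;0,0",
                                  choice = "X")), "distinct")
  expect_error(ist_p_correct(list(grid = make_grid(13), opened = "5,0",
                                  choice = "X")), "0-based")
})

test_that("the shipped MCQ items define valid indifference rates", {
  items <- kirby_items()
  expect_equal(nrow(items), 27)
  expect_true(all(items$delayed_amount > items$immediate_amount))
  expect_true(all(items$k_indiff > 0))
  # spot value: 25 now vs 60 in 14 days
  k8 <- (60 / 25 - 1) / 14
  expect_equal(items$k_indiff[items$item_id == 8], k8)
})

test_that("kirby_k assigns extreme and generated patterns correctly", {
  items <- kirby_items()
  all_delayed <- rep("delayed", 27)
  est <- kirby_k(all_delayed, items)
  expect_equal(est$k, min(items$k_indiff))
  expect_equal(est$consistency, 1)
  # deterministic hyperbolic chooser off the candidate boundaries
  set.seed(9)
  for (k_true in exp(runif(6, log(5e-4), log(0.2)))) {
    if (any(abs(k_true - items$k_indiff) < 1e-12)) next
    resp <- ifelse(items$immediate_amount >
                     items$delayed_amount / (1 + k_true * items$delay_days),
                   "immediate", "delayed")
    est <- kirby_k(resp, items)
    expect_equal(est$consistency, 1)
    # assigned bracket contains the generating rate
    below <- est$candidates[est$candidates < min(est$maximizers)]
    lo <- if (length(below)) max(below) else 0
    expect_true(k_true > lo - 1e-12 && k_true <= max(est$maximizers) + 1e-12)
  }
  # item order must not matter
  set.seed(10)
  resp <- sample(c("immediate", "delayed"), 27, replace = TRUE)
  perm <- sample(27)
  est1 <- kirby_k(resp, items)
  est2 <- kirby_k(resp[perm], items[perm, ])
  expect_equal(est1$k, est2$k)
  expect_equal(est1$consistency, est2$consistency)
  expect_true(est1$k >= min(items$k_indiff) && est1$k <= max(items$k_indiff))
  expect_error(kirby_k(resp[1:20], items), "27")
})

test_that("a bespoke 50-vs-100-in-30-days item pins k = 1/30", {
  items <- data.frame(item_id = 1:3,
                      immediate_amount = c(50, 40, 30),
                      delayed_amount = c(100, 50, 90),
                      delay_days = c(30, 60, 10))
  items$k_indiff <- (items$delayed_amount / items$immediate_amount - 1) /
    items$delay_days
  expect_equal(items$k_indiff[1], 1 / 30)
  k_true <- 1 / 30 + 1e-4                # just above the middle boundary
  resp <- ifelse(items$immediate_amount >
                   items$delayed_amount / (1 + k_true * items$delay_days),
                 "immediate", "delayed")
  est <- kirby_k(resp, items)
  below <- est$candidates[est$candidates < min(est$maximizers)]
  lo <- if (length(below)) max(below) else 0
  expect_true(k_true > lo && k_true <= max(est$maximizers))
  expect_true(lo == 1 / 30 || min(est$maximizers) >= 1 / 30)
})

test_that("outlier removal implements the per-group 3 SD rule", {
  # all equal: zero SD removes nothing
  out <- remove_outliers(rep(5, 6), rep("g", 6))
  expect_true(all(out$kept))
  # hand-computed case: nine zeros and a 100; 3 SD = 94.87 > |100 - 10|
  x <- c(rep(0, 9), 100)
  expect_equal(abs(100 - mean(x)) > 3 * sd(x), FALSE)
  out <- remove_outliers(x, rep("g", 10))
  expect_true(all(out$kept))
  # a genuinely extreme point is removed, and only in its own group
  x <- c(rnorm(20, sd = 0.1), 50, rnorm(20, mean = 50, sd = 0.1))
  grp <- rep(c("a", "b"), c(21, 20))
  out <- remove_outliers(x, grp, ids = seq_along(x))
  expect_equal(out$removed, 21)
  # clean normal samples rarely lose anything
  set.seed(13)
  clean <- vapply(1:100, function(i) {
    all(remove_outliers(rnorm(30), rep("g", 30))$kept)
  }, logical(1))
  expect_gte(mean(clean), 0.9)
})

test_that("group tests reproduce textbook statistics", {
  tab <- data.frame(subject_id = 1:6,
                    group = rep(c("HV", "BD"), each = 3),
                    beads_draws_mean = c(1, 2, 3, 4, 5, 6)^2)
  res <- group_tests(tab)
  tt <- res[res$outcome == "beads_draws_sqrt", ]
  expect_equal(tt$statistic, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$statistic, oracle_pooled_t(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  # identical groups: t exactly 0
  tab0 <- data.frame(subject_id = 1:6, group = rep(c("HV", "BD"), each = 3),
                     beads_draws_mean = rep(c(1, 4, 9), 2))
  res0 <- group_tests(tab0)
  expect_equal(res0$statistic[res0$outcome == "beads_draws_sqrt"], 0)
})

test_that("the Wilcoxon read-out matches exact enumeration", {
  tab <- data.frame(subject_id = 1:4, group = rep(c("HV", "BD"), each = 2),
                    map_t = c(1, 2, 3, 4))
  res <- group_tests(tab)
  w <- res[res$test == "wilcoxon", ]
  expect_equal(w$p, 1 / 3)
  expect_equal(w$p, oracle_wilcoxon_exact_p(c(1, 2), c(3, 4)))
  # random small samples against the enumeration oracle
  set.seed(19)
  for (rep in 1:6) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    tab <- data.frame(subject_id = seq_len(n1 + n2),
                      group = rep(c("HV", "BD"), c(n1, n2)),
                      map_t = c(x, y))
    p_pkg <- group_tests(tab)
    p_pkg <- p_pkg$p[p_pkg$test == "wilcoxon"]
    expect_equal(p_pkg, oracle_wilcoxon_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("the mixed ANOVA matches the closed-form decomposition", {
  set.seed(23)
  for (rep in 1:5) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    grp <- rep(c("HV", "BD"), c(n1, n2))
    y1 <- rnorm(n1 + n2); y2 <- rnorm(n1 + n2) + rep(c(0, 0.5), c(n1, n2))
    tab <- data.frame(subject_id = seq_along(grp), group = grp,
                      ist_points_fixed = y1, ist_points_decreasing = y2)
    res <- group_tests(tab)
    want <- oracle_mixed_anova(y1, y2, grp)
    got <- res[res$test == "mixed_anova_F", ]
    expect_equal(got$statistic[got$outcome == "ist_points:group"],
                 unname(want["F_group"]), tolerance = 1e-8)
    expect_equal(got$statistic[got$outcome == "ist_points:cost"],
                 unname(want["F_cost"]), tolerance = 1e-8)
    expect_equal(got$statistic[got$outcome == "ist_points:group:cost"],
                 unname(want["F_int"]), tolerance = 1e-8)
    expect_equal(got$df[got$outcome == "ist_points:cost"],
                 unname(want["df_err"]))
  }
  # mirror-image groups: no group-by-cost interaction (F exactly 0), with
  # genuine within-cell error so the ratio is well defined
  tabz <- data.frame(subject_id = 1:6, group = rep(c("HV", "BD"), each = 3),
                     ist_points_fixed = c(1, 2, 3, 1, 2, 3),
                     ist_points_decreasing = c(2, 4, 6, 2, 4, 6))
  resz <- group_tests(tabz)
  expect_equal(resz$statistic[resz$outcome == "ist_points:group:cost"], 0)
})

test_that("transforms feed the tests and invalid k is rejected", {
  set.seed(29)
  tab <- data.frame(subject_id = 1:10, group = rep(c("HV", "BD"), each = 5),
                    k_value = exp(rnorm(10, log(0.02), 0.5)))
  res <- group_tests(tab)
  want <- stats::t.test(log10(tab$k_value[1:5]), log10(tab$k_value[6:10]),
                        var.equal = TRUE)
  row <- res[res$outcome == "k_log10", ]
  expect_equal(row$statistic, unname(want$statistic))
  expect_equal(row$p, want$p.value)
  tab$k_value[3] <- 0
  expect_error(group_tests(tab), "subject")
  # Welch option changes the degrees of freedom
  tab$k_value[3] <- 0.02
  res_w <- group_tests(tab, welch = TRUE)
  expect_false(isTRUE(all.equal(res_w$df[res_w$outcome == "k_log10"], 8)))
})

test_that("correlations with severity covariates are Pearson on raw draws", {
  set.seed(37)
  n <- 24
  draws <- runif(n, 2, 15)
  audit <- -0.5 * draws + rnorm(n, 10, 2)
  tab <- data.frame(subject_id = 1:n, group = rep(c("HV", "BD"), each = 12),
                    beads_draws_mean = draws, audit = audit)
  res <- group_tests(tab)
  row <- res[res$test == "pearson", ]
  want <- stats::cor.test(draws, audit)
  expect_equal(row$statistic, unname(want$estimate))
  expect_equal(row$p, want$p.value)
  expect_equal(row$df, n - 2)
})
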