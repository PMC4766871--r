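# Independent reference implementations used to cross-check the package.
# All of these deliberately avoid the code paths they verify: plain
# recursion instead of dynamic programming, bitmask enumeration instead of
# binomial tails, textbook sums-of-squares instead of aov.

# Exhaustive, memoization-free recursion over the bead tree. Posterior by
# direct (non-log) Bayes arithmetic.
oracle_posterior <- function(n_a, n_b, q, prior_a = 0.5) {
  num <- prior_a * q^n_a * (1 - q)^n_b
  den <- num + (1 - prior_a) * (1 - q)^n_a * q^n_b
  num / den
}

oracle_state_value <- function(n_a, n_b, cs, t, config) {
  q <- config$q
  p <- oracle_posterior(n_a, n_b, q, config$prior_a)
  q_a <- p * config$reward_correct + (1 - p) * config$reward_incorrect
  q_b <- (1 - p) * config$reward_correct + p * config$reward_incorrect
  d <- n_a + n_b
  if (d == config$d_max) {
    qs <- c(q_a, q_b)
  } else {
    p_next <- p * q + (1 - p) * (1 - q)
    v_a <- oracle_state_value(n_a + 1, n_b, cs, t, config)
    v_b <- oracle_state_value(n_a, n_b + 1, cs, t, config)
    q_s <- -cs + p_next * v_a + (1 - p_next) * v_b
    qs <- c(q_s, q_a, q_b)
  }
  if (t == 0) return(max(qs))
  w <- exp(qs / t - max(qs / t))
  w <- w / sum(w)
  if (config$value_rule == "softmax_expectation") {
    sum(w * qs)
  } else {
    t * (max(qs / t) + log(sum(exp(qs / t - max(qs / t)))))
  }
}

# Policy probabilities at a state, from the recursive oracle values.
oracle_policy <- function(n_a, n_b, cs, t, config) {
  q <- config$q
  p <- oracle_posterior(n_a, n_b, q, config$prior_a)
  q_a <- p * config$reward_correct + (1 - p) * config$reward_incorrect
  q_b <- (1 - p) * config$reward_correct + p * config$reward_incorrect
  d <- n_a + n_b
  if (d == config$d_max) {
    qs <- c(q_a, q_b); labels <- c("declare_a", "declare_b")
  } else {
    p_next <- p * q + (1 - p) * (1 - q)
    q_s <- -cs + p_next * oracle_state_value(n_a + 1, n_b, cs, t, config) +
      (1 - p_next) * oracle_state_value(n_a, n_b + 1, cs, t, config)
    qs <- c(q_s, q_a, q_b); labels <- c("sample", "declare_a", "declare_b")
  }
  w <- exp(qs / t - max(qs / t))
  stats::setNames(w / sum(w), labels)
}

# Probability of an observed trial record by explicit enumeration of every
# action path: walk all (sample | declare A | declare B) choices along the
# fixed bead sequence and sum the probability of paths that reproduce the
# record. Exactly one path is consistent, but the enumeration neither
# assumes nor exploits that.
oracle_trial_prob <- function(sequence, draws, declared, cs, t, config) {
  seq_chr <- strsplit(sequence, "")[[1]]
  total <- 0
  walk <- function(k, n_a, prob) {
    # k beads have been shown; decision point at state (n_a, k - n_a)
    pol <- oracle_policy(n_a, k - n_a, cs, t, config)
    for (a in names(pol)) {
      pr <- prob * pol[[a]]
      if (pr == 0) next
      if (a == "sample") {
        if (k < config$d_max) {
          n_a2 <- n_a + (seq_chr[k + 1] == "A")
          walk(k + 1, n_a2, pr)
        }
      } else {
        jar <- if (a == "declare_a") "A" else "B"
        if (k == draws && jar == declared) total <<- total + pr
      }
    }
  }
  n_a1 <- as.integer(seq_chr[1] == "A")
  walk(1, n_a1, 1)
  total
}

# Exhaustive enumeration of all 2^u fair-coin completions of the unopened
# IST cells: exact probability that the chosen colour reaches >= 13 cells.
oracle_ist_p_correct <- function(trial) {
  cells <- strsplit(trial$grid, "")[[1]]
  pairs <- strsplit(strsplit(trial$opened, ";")[[1]], ",")
  lin <- vapply(pairs, function(p) {
    as.integer(p[1]) * 5L + as.integer(p[2]) + 1L
  }, integer(1))
  m <- sum(cells[lin] == trial$choice)
  u <- 25L - length(lin)
  hits <- 0L
  for (mask in 0:(2^u - 1)) {
    j <- sum(as.integer(intToBits(mask)[1:u]))
    if (m + j >= 13L) hits <- hits + 1L
  }
  hits / 2^u
}

# Textbook pooled-variance two-sample t statistic.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every
# assignment of the pooled ranks to the first sample (no ties assumed).
oracle_wilcoxon_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- rank(c(x, y))
  w_obs <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  all_ranks <- seq_len(n1 + n2)
  ws <- apply(combos, 2, function(idx) sum(all_ranks[idx]) - n1 * (n1 + 1) / 2)
  mean_w <- n1 * n2 / 2
  p <- mean(abs(ws - mean_w) >= abs(w_obs - mean_w) - 1e-12)
  min(1, p)
}

# Closed-form sums of squares for the 2x2 mixed design (between: group,
# within: 2 conditions, both conditions observed per subject).
oracle_mixed_anova <- function(y_c1, y_c2, group) {
  group <- as.character(group)
  n <- length(group)
  s <- (y_c1 + y_c2) / 2                 # subject means
  d <- y_c2 - y_c1                       # within-subject differences
  gl <- unique(group)
  n_g <- table(factor(group, levels = gl))
  s_g <- tapply(s, factor(group, levels = gl), mean)
  d_g <- tapply(d, factor(group, levels = gl), mean)

  ss_group <- 2 * sum(n_g * (s_g - mean(s))^2)
  ss_sub <- 2 * sum((s - s_g[group])^2)
  f_group <- (ss_group / (length(gl) - 1)) / (ss_sub / (n - length(gl)))

  ss_cost <- sum(d)^2 / (2 * n)
  ss_int <- sum(n_g * d_g^2) / 2 - ss_cost
  ss_err <- sum((d - d_g[group])^2) / 2
  df_err <- n - length(gl)
  c(F_group = f_group,
    F_cost = ss_cost / (ss_err / df_err),
    F_int = (ss_int / (length(gl) - 1)) / (ss_err / df_err),
    df_err = df_err)
}

# Simulate a cohort of beads trials from known per-subject parameters.
simulate_cohort_trials <- function(cs, t, n_trials, config,
                                   ids = sprintf("s%02d", seq_along(cs))) {
  rows <- list()
  for (i in seq_along(cs)) {
    vt <- build_value_table(subject_params(cs[i], t[i]), config)
    for (j in seq_len(n_trials)) {
      tr <- simulate_trial(subject_params(cs[i], t[i]), config,
                           true_jar = sample(c("A", "B"), 1), table = vt)
      tr$subject_id <- ids[i]
      tr$trial_index <- j
      rows[[length(rows) + 1L]] <- tr
    }
  }
  do.call(rbind, rows)
}

# Shared small grid + policy cache so the heavier tests do not rebuild
# 1600 backward inductions each. Built lazily once per test run.
.cache <- new.env(parent = emptyenv())
default_policy_grid <- function() {
  if (is.null(.cache$pg)) {
    .cache$grid <- param_grid()
    .cache$pg <- policy_grid(.cache$grid, beads_config())
  }
  .cache$pg
}
default_grid <- function() {
  default_policy_grid()
  .cache$grid
}
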