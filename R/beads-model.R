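#' Posterior probability of Jar A
#'
#' Bayes rule over the two known binomial sources, computed in log space.
#' With a symmetric prior the posterior depends on the evidence only through
#' the count difference `n_a - n_b`.
#'
#' @param n_a,n_b Number of majority-A and majority-B coloured beads seen.
#' @param config A [beads_config()].
#' @return The posterior probability that the beads come from Jar A.
#' @examples
#' beads_posterior(2, 0, beads_config())  # 16/17
#' @export
beads_posterior <- function(n_a, n_b, config = beads_config()) {
  check_state(n_a, n_b, config)
  log_odds <- log(config$prior_a) - log1p(-config$prior_a) +
    (n_a - n_b) * (log(config$q) - log1p(-config$q))
  stats::plogis(log_odds)
}

#' Predictive probability that the next bead has colour A
#'
#' Marginal one-step-ahead predictive under the current jar posterior,
#' needed by the backward induction to average over bead continuations.
#'
#' @inheritParams beads_posterior
#' @return Probability in (0, 1) that the next bead shows Jar A's majority
#'   colour.
#' @export
beads_predictive <- function(n_a, n_b, config = beads_config()) {
  check_state(n_a, n_b, config)
  if (n_a + n_b >= config$d_max) {
    stop("no further bead can be drawn at the horizon", call. = FALSE)
  }
  p <- beads_posterior(n_a, n_b, config)
  p * config$q + (1 - p) * (1 - config$q)
}

# Posterior P(Jar A) for all states at one depth, vectorised over n_a = 0..d.
posterior_depth <- function(d, config) {
  n_a <- 0:d
  log_odds <- log(config$prior_a) - log1p(-config$prior_a) +
    (n_a - (d - n_a)) * (log(config$q) - log1p(-config$q))
  stats::plogis(log_odds)
}

# Row-wise log-softmax of a value matrix at temperature t (> 0).
# Returns log choice probabilities; -Inf entries mark unavailable actions.
log_softmax_rows <- function(m, t) {
  z <- m / t
  mx <- apply(z, 1L, max, na.rm = TRUE)
  z <- z - mx
  z[is.na(z)] <- -Inf
  z - log(rowSums(exp(z)))
}

# Deterministic (t = 0) log-policy: one-hot on the argmax with ties broken
# by the configured preference order. Columns: sample, declare_a, declare_b.
log_argmax_rows <- function(m, tie_break) {
  tol <- 1e-12
  pref <- if (tie_break == "prefer_sample") c(1L, 2L, 3L) else c(2L, 3L, 1L)
  lp <- matrix(-Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    mx <- max(v, na.rm = TRUE)
    cand <- which(!is.na(v) & v >= mx - tol)
    pick <- cand[order(match(cand, pref))][1L]
    lp[i, pick] <- 0
  }
  lp
}

#' Build the backward-induction value table
#'
#' Runs dynamic programming from the forced decision at the horizon back to
#' the empty belief state. At every state the declare values are the
#' expected declaration utilities under the jar posterior; where a further
#' bead may be drawn, the sample value is the predictive-weighted value of
#' the successor states minus the cost of sampling. The choice policy is a
#' softmax over the available action values at temperature `t`, and the
#' state value propagated to earlier depths is (by default) the
#' policy-weighted action value, so that high cognitive noise genuinely
#' dilutes the influence of outcomes deep in the tree. Because the horizon
#' is finite, the implied declaration boundaries relax as the end of the
#' task approaches.
#'
#' @param params A [subject_params()] (cost of sampling, cognitive noise).
#' @param config A [beads_config()].
#' @return An object of class `beads_value_table`: per-depth matrices of
#'   action values `Q` (columns `sample`, `declare_a`, `declare_b`), log
#'   choice policies, state values, and the flattened log-policy matrix used
#'   by the likelihood routines.
#' @seealso [policy_at()], [trial_loglik()], [simulate_trial()]
#' @examples
#' vt <- build_value_table(subject_params(0.02, 0.4), beads_config())
#' policy_at(1, 0, vt)
#' @export
build_value_table <- function(params, config = beads_config()) {
  stopifnot(inherits(config, "beads_config"))
  if (!inherits(params, "subject_params")) {
    params <- subject_params(params$cs, params$t)
  }
  cs <- params$cs
  t <- params$t
  d_max <- config$d_max
  rc <- config$reward_correct
  ri <- config$reward_incorrect

  Q <- vector("list", d_max + 1L)       # [[d + 1]]: (d+1) x 3 matrix
  log_policy <- vector("list", d_max + 1L)
  V <- vector("list", d_max + 1L)
  post <- vector("list", d_max + 1L)

  for (d in d_max:0) {
    p <- posterior_depth(d, config)
    post[[d + 1L]] <- p
    q_a <- p * rc + (1 - p) * ri
    q_b <- (1 - p) * rc + p * ri
    if (d == d_max) {
      q_s <- rep(NA_real_, d + 1L)
    } else {
      p_next <- p * config$q + (1 - p) * (1 - config$q)
      v_next <- V[[d + 2L]]
      # successor on colour A is (d+1, n_a+1); on colour B is (d+1, n_a)
      q_s <- -cs + p_next * v_next[2:(d + 2L)] +
        (1 - p_next) * v_next[1:(d + 1L)]
    }
    qm <- cbind(sample = q_s, declare_a = q_a, declare_b = q_b)
    if (t > 0) {
      lp <- log_softmax_rows(qm, t)
      if (config$value_rule == "softmax_expectation") {
        qz <- qm
        qz[is.na(qz)] <- 0     # zero-probability actions contribute nothing
        v <- rowSums(exp(lp) * qz)
      } else {                 # logsumexp soft-maximum
        mx <- apply(qm / t, 1L, max, na.rm = TRUE)
        z <- qm / t - mx
        z[is.na(z)] <- -Inf
        v <- t * (mx + log(rowSums(exp(z))))
      }
    } else {
      lp <- log_argmax_rows(qm, config$tie_break)
      v <- apply(qm, 1L, max, na.rm = TRUE)
    }
    colnames(lp) <- c("sample", "declare_a", "declare_b")
    Q[[d + 1L]] <- qm
    log_policy[[d + 1L]] <- lp
    V[[d + 1L]] <- v
  }

  # flattened [n_states x 3] log-policy for fast likelihood lookups
  lp_flat <- do.call(rbind, log_policy)
  structure(
    list(params = params, config = config, Q = Q, log_policy = log_policy,
         V = V, posterior = post, lp_flat = lp_flat),
    class = "beads_value_table"
  )
}

#' @export
print.beads_value_table <- function(x, ...) {
  cat(sprintf(
    "Beads value table: d_max = %d (%d belief states), cs = %g, t = %g\n",
    x$config$d_max, n_states(x$config$d_max), x$params$cs, x$params$t))
  cat(sprintf("  V(empty state) = %.4f\n", x$V[[1L]][1L]))
  invisible(x)
}

#' Choice policy at a belief state
#'
#' The softmax choice probabilities over the actions available after seeing
#' `n_a` beads of colour A and `n_b` of colour B. At the horizon only the
#' two declarations are available and the sample probability is zero.
#'
#' @inheritParams beads_posterior
#' @param table A [build_value_table()] result.
#' @return Named numeric vector `c(sample, declare_a, declare_b)` summing
#'   to 1.
#' @export
policy_at <- function(n_a, n_b, table) {
  stopifnot(inherits(table, "beads_value_table"))
  check_state(n_a, n_b, table$config)
  d <- n_a + n_b
  pr <- exp(table$log_policy[[d + 1L]][n_a + 1L, ])
  pr[is.na(pr)] <- 0
  pr / sum(pr)
}

# Normalise a trial's bead sequence to a character vector over {"A","B"}.
parse_sequence <- function(sequence) {
  if (length(sequence) == 1L && is.character(sequence)) {
    sequence <- strsplit(sequence, "")[[1L]]
  }
  sequence <- toupper(as.character(sequence))
  if (!all(sequence %in% c("A", "B"))) {
    stop("bead sequence must contain only colours 'A' and 'B'", call. = FALSE)
  }
  sequence
}

# Flattened state indices and action column (1 sample, 2 declare A,
# 3 declare B) of the decision points of one trial record.
trial_decision_points <- function(sequence, draws, declared) {
  seq_chr <- parse_sequence(sequence)
  draws <- as.integer(draws)
  if (is.na(draws) || draws < 1L) {
    stop("`draws` must be at least 1 (the first decision follows the first bead)",
         call. = FALSE)
  }
  if (length(seq_chr) < draws) {
    stop("bead sequence is shorter than the number of draws", call. = FALSE)
  }
  declared <- toupper(as.character(declared))
  if (!declared %in% c("A", "B")) {
    stop("`declared` must be 'A' or 'B'", call. = FALSE)
  }
  n_a <- cumsum(seq_chr[seq_len(draws)] == "A")
  d <- seq_len(draws)
  idx <- state_index(d, n_a)
  act <- c(rep(1L, draws - 1L), if (declared == "A") 2L else 3L)
  list(idx = idx, act = act)
}

#' Log-likelihood of one beads trial
#'
#' Sums the log choice probability of the observed action at every decision
#' point: "sample" after each of the first `draws - 1` beads and the
#' declared jar after the last. Natural log throughout.
#'
#' @param trial A list or one-row data frame with fields `sequence` (string
#'   or character vector over A/B), `draws`, and `declared`.
#' @param params A [subject_params()]; ignored when `table` is supplied.
#' @param config A [beads_config()].
#' @param table Optionally a prebuilt [build_value_table()] for these
#'   parameters, to avoid rebuilding it per trial.
#' @return Log-probability in nats (`<= 0`).
#' @export
trial_loglik <- function(trial, params, config = beads_config(),
                         table = NULL) {
  if (is.null(table)) table <- build_value_table(params, config)
  dp <- trial_decision_points(trial$sequence, trial$draws, trial$declared)
  if (trial$draws > table$config$d_max) {
    stop("trial has more draws than the configured horizon", call. = FALSE)
  }
  sum(table$lp_flat[cbind(dp$idx, dp$act)])
}

#' Simulate one beads trial from the model
#'
#' Draws a bead sequence i.i.d. from the true jar's colour distribution and
#' walks the observer's softmax policy until a jar is declared (forced at
#' the horizon). The full drawable sequence of length `d_max` is returned so
#' the record can be replayed under any parameter values.
#'
#' @param params A [subject_params()].
#' @param config A [beads_config()].
#' @param true_jar `"A"` or `"B"`.
#' @param seed Optional integer seed for reproducibility. When `NULL` the
#'   current RNG stream is used (so a caller can seed once for a whole
#'   cohort).
#' @param table Optional prebuilt value table for `params`.
#' @return A one-row data frame with `sequence`, `draws`, `declared`,
#'   `true_jar`, `correct`.
#' @export
simulate_trial <- function(params, config = beads_config(), true_jar = "A",
                           seed = NULL, table = NULL) {
  true_jar <- toupper(true_jar)
  stopifnot(true_jar %in% c("A", "B"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(table)) table <- build_value_table(params, config)
  p_a <- if (true_jar == "A") config$q else 1 - config$q
  beads <- ifelse(stats::runif(config$d_max) < p_a, "A", "B")
  n_a <- 0L
  declared <- NA_character_
  draws <- config$d_max
  for (k in seq_len(config$d_max)) {
    if (beads[k] == "A") n_a <- n_a + 1L
    pr <- exp(table$log_policy[[k + 1L]][n_a + 1L, ])
    pr[is.na(pr)] <- 0
    a <- sample.int(3L, 1L, prob = pr)
    if (a > 1L) {
      declared <- if (a == 2L) "A" else "B"
      draws <- k
      break
    }
  }
  if (is.na(declared)) {
    # horizon reached without declaring cannot happen (sample prob is 0
    # at d_max), but guard against numerical surprises
    declared <- "A"
  }
  data.frame(sequence = paste(beads, collapse = ""), draws = draws,
             declared = declared, true_jar = true_jar,
             correct = declared == true_jar, stringsAsFactors = FALSE)
}
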