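#' Beads task environment configuration
#'
#' Describes the fixed environment of the beads task: two jars with
#' complementary colour ratios, a cap on the number of beads that can be
#' viewed, and the utilities attached to a correct or incorrect jar
#' declaration. Colour "A" is, by convention, the majority colour of Jar A.
#'
#' @param q Majority-colour proportion of each jar. The classic task uses
#'   0.80 (Jar A: 80A/20B, Jar B: 20A/80B). Must lie in (0.5, 1).
#' @param d_max Maximum number of beads a subject may view (default 20).
#' @param reward_correct Utility of a correct declaration (default 1).
#' @param reward_incorrect Utility of an incorrect declaration (default 0).
#'   The cost of sampling and the cognitive noise of [subject_params()] are
#'   expressed in these units, so with the 1/0 default both parameters are
#'   fractions of the declaration reward.
#' @param prior_a Prior probability that the jar is Jar A (default 0.5).
#' @param tie_break How exact ties between action values are broken in the
#'   deterministic (zero-noise) limit: `"prefer_sample"` (default, the
#'   ideal-observer convention at zero sampling cost) or `"prefer_declare"`.
#' @param value_rule How the value of a belief state is propagated through
#'   the backward induction: `"softmax_expectation"` (default) weights each
#'   action value by its softmax choice probability, so high cognitive noise
#'   attenuates the influence of distant outcomes; `"logsumexp"` uses the
#'   soft-maximum \eqn{T \log \sum_a e^{Q_a/T}}. Both recover the
#'   ideal-observer maximum as the noise goes to zero.
#'
#' @return An object of class `beads_config`.
#' @examples
#' cfg <- beads_config()
#' cfg$q
#' @export
beads_config <- function(q = 0.8, d_max = 20L,
                         reward_correct = 1, reward_incorrect = 0,
                         prior_a = 0.5,
                         tie_break = c("prefer_sample", "prefer_declare"),
                         value_rule = c("softmax_expectation", "logsumexp")) {
  tie_break <- match.arg(tie_break)
  value_rule <- match.arg(value_rule)
  if (!is.numeric(q) || length(q) != 1 || q <= 0.5 || q >= 1) {
    stop("`q` must be a single number in (0.5, 1)", call. = FALSE)
  }
  d_max <- as.integer(d_max)
  if (is.na(d_max) || d_max < 1) stop("`d_max` must be >= 1", call. = FALSE)
  if (!(reward_correct > reward_incorrect)) {
    stop("`reward_correct` must exceed `reward_incorrect`", call. = FALSE)
  }
  if (prior_a <= 0 || prior_a >= 1) {
    stop("`prior_a` must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(
    list(q = q, d_max = d_max,
         reward_correct = reward_correct,
         reward_incorrect = reward_incorrect,
         prior_a = prior_a, tie_break = tie_break, value_rule = value_rule),
    class = "beads_config"
  )
}

#' @export
print.beads_config <- function(x, ...) {
  cat("Beads task configuration\n")
  cat(sprintf("  jar ratio q        : %.3f\n", x$q))
  cat(sprintf("  max draws          : %d\n", x$d_max))
  cat(sprintf("  rewards (ok/wrong) : %g / %g\n",
              x$reward_correct, x$reward_incorrect))
  cat(sprintf("  prior P(Jar A)     : %.3f\n", x$prior_a))
  cat(sprintf("  tie break          : %s\n", x$tie_break))
  cat(sprintf("  value propagation  : %s\n", x$value_rule))
  invisible(x)
}

#' Subject-level model parameters
#'
#' The two free parameters of the beads-task observer model: the subjective
#' cost of sampling `cs` charged for every bead viewed, and the cognitive
#' noise `t`, a softmax temperature that governs both choice consistency and
#' how strongly cognitively distant outcomes propagate into current action
#' values. Both are in units of the declaration reward.
#'
#' `t = 0` is accepted and denotes the deterministic ideal-observer limit,
#' in which choices are the argmax of the action values with ties broken by
#' the configuration's `tie_break` rule.
#'
#' @param cs Cost per sample, `>= 0`.
#' @param t Cognitive noise (softmax temperature), `>= 0`.
#' @return An object of class `subject_params`.
#' @examples
#' subject_params(cs = 0.02, t = 0.4)
#' @export
subject_params <- function(cs, t) {
  if (!is.numeric(cs) || length(cs) != 1 || is.na(cs) || cs < 0) {
    stop("`cs` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0) {
    stop("`t` must be a single non-negative number (0 = deterministic limit)",
         call. = FALSE)
  }
  structure(list(cs = cs, t = t), class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("Subject parameters: cs = %g, t = %g\n", x$cs, x$t))
  invisible(x)
}

# Linear index of belief state (d, n_a) in the flattened lattice,
# d = 0..d_max, n_a = 0..d. Depth-major; 1-based.
state_index <- function(d, n_a) {
  d * (d + 1L) / 2L + n_a + 1L
}

n_states <- function(d_max) {
  (d_max + 1L) * (d_max + 2L) / 2L
}

check_state <- function(n_a, n_b, config) {
  if (length(n_a) != 1 || length(n_b) != 1 || is.na(n_a) || is.na(n_b) ||
      n_a < 0 || n_b < 0) {
    stop("bead counts must be single non-negative numbers", call. = FALSE)
  }
  if (n_a + n_b > config$d_max) {
    stop(sprintf("state (%d, %d) exceeds the %d-draw horizon",
                 as.integer(n_a), as.integer(n_b), config$d_max),
         call. = FALSE)
  }
  invisible(TRUE)
}
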