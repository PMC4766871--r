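#' Gamma population prior
#'
#' Shape/rate parameterisation; the mean is `shape / rate`. Used as the
#' population distribution over each of the two subject-level parameters.
#'
#' @param shape,rate Positive gamma parameters.
#' @return An object of class `gamma_prior` with fields `shape`, `rate`,
#'   `mean`, `sd`.
#' @export
gamma_prior <- function(shape, rate) {
  if (!is.finite(shape) || shape <= 0 || !is.finite(rate) || rate <= 0) {
    stop("gamma `shape` and `rate` must be positive and finite", call. = FALSE)
  }
  structure(list(shape = shape, rate = rate, mean = shape / rate,
                 sd = sqrt(shape) / rate),
            class = "gamma_prior")
}

#' Gamma prior from mean and standard deviation
#'
#' Convenience constructor: `shape = (mean/sd)^2`, `rate = mean/sd^2`.
#'
#' @param mean,sd Positive mean and standard deviation.
#' @export
gamma_prior_ms <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("`mean` and `sd` must be positive", call. = FALSE)
  gamma_prior(shape = (mean / sd)^2, rate = mean / sd^2)
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf("Gamma(shape = %.4g, rate = %.4g): mean = %.4g, sd = %.4g\n",
              x$shape, x$rate, x$mean, x$sd))
  invisible(x)
}

#' Population model: gamma priors over cost of sampling and cognitive noise
#'
#' @param prior_cs,prior_t [gamma_prior()] objects for the cost of sampling
#'   and the cognitive noise.
#' @return An object of class `population_model`.
#' @export
population_model <- function(prior_cs, prior_t) {
  stopifnot(inherits(prior_cs, "gamma_prior"), inherits(prior_t, "gamma_prior"))
  structure(list(prior_cs = prior_cs, prior_t = prior_t),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population model\n  cs: "); print(x$prior_cs)
  cat("  t : "); print(x$prior_t)
  invisible(x)
}

#' Log-spaced grid over (cs, t) for the E-step
#'
#' The subject-level posterior is represented on a fixed product grid,
#' log-spaced so that the small cost-of-sampling values typical of real
#' cohorts are well resolved. Quadrature cell areas (midpoint rule in the
#' raw parameter space) are attached for normalising posterior masses.
#'
#' @param n_cs,n_t Number of nodes per axis (default 40 each).
#' @param cs_range,t_range Ranges of the two axes; all nodes positive.
#' @return An object of class `param_grid`: data frame of `cs`, `t` nodes
#'   (cs varying fastest) with `log_area` quadrature weights.
#' @export
param_grid <- function(n_cs = 40L, n_t = 40L,
                       cs_range = c(1e-4, 0.5), t_range = c(0.01, 5)) {
  if (any(c(cs_range, t_range) <= 0)) {
    stop("grid nodes must be strictly positive", call. = FALSE)
  }
  cs_vals <- exp(seq(log(cs_range[1]), log(cs_range[2]), length.out = n_cs))
  t_vals <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = n_t))
  mid_widths <- function(x) {
    e <- c(x[1], (x[-length(x)] + x[-1]) / 2, x[length(x)])
    diff(e)
  }
  w_cs <- mid_widths(cs_vals)
  w_t <- mid_widths(t_vals)
  g <- expand.grid(cs = cs_vals, t = t_vals, KEEP.OUT.ATTRS = FALSE)
  g$log_area <- log(rep(w_cs, times = n_t)) + log(rep(w_t, each = n_cs))
  structure(list(points = g, cs_vals = cs_vals, t_vals = t_vals),
            class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat(sprintf("Parameter grid: %d cs nodes in [%.2g, %.2g] x %d t nodes in [%.2g, %.2g]\n",
              length(x$cs_vals), min(x$cs_vals), max(x$cs_vals),
              length(x$t_vals), min(x$t_vals), max(x$t_vals)))
  invisible(x)
}

#' Precompute choice policies over a parameter grid
#'
#' Builds the backward-induction value table at every grid node once, so
#' that trial likelihoods for any number of subjects, EM iterations or
#' replicate cohorts can be evaluated by table lookup. The result depends
#' only on the grid and the task configuration, never on the data.
#'
#' @param grid A [param_grid()].
#' @param config A [beads_config()].
#' @return An object of class `policy_grid` holding one flattened
#'   log-policy matrix per grid node.
#' @export
policy_grid <- function(grid, config = beads_config()) {
  stopifnot(inherits(grid, "param_grid"))
  pts <- grid$points
  lp <- vector("list", nrow(pts))
  for (g in seq_len(nrow(pts))) {
    lp[[g]] <- build_value_table(subject_params(pts$cs[g], pts$t[g]),
                                 config)$lp_flat
  }
  structure(list(lp = lp, grid = grid, config = config),
            class = "policy_grid")
}

# Per-subject log-likelihood of every grid node: matrix [subject x node],
# plus the number of decision points (actions) per subject.
cohort_grid_loglik <- function(trials, pg) {
  stopifnot(inherits(pg, "policy_grid"))
  subjects <- unique(trials$subject_id)
  idx <- integer(0); act <- integer(0); sub <- integer(0)
  for (r in seq_len(nrow(trials))) {
    dp <- trial_decision_points(trials$sequence[r], trials$draws[r],
                                trials$declared[r])
    idx <- c(idx, dp$idx)
    act <- c(act, dp$act)
    sub <- c(sub, rep(match(trials$subject_id[r], subjects), length(dp$idx)))
  }
  G <- length(pg$lp)
  L <- matrix(0, length(subjects), G,
              dimnames = list(as.character(subjects), NULL))
  look <- cbind(idx, act)
  for (g in seq_len(G)) {
    L[, g] <- rowsum(pg$lp[[g]][look], sub, reorder = TRUE)
  }
  n_actions <- as.vector(rowsum(rep(1L, length(sub)), sub, reorder = TRUE))
  list(L = L, subjects = subjects, n_actions = n_actions)
}

# Gamma log-density of the prior at every grid node.
grid_log_prior <- function(grid, population) {
  pts <- grid$points
  stats::dgamma(pts$cs, population$prior_cs$shape,
                population$prior_cs$rate, log = TRUE) +
    stats::dgamma(pts$t, population$prior_t$shape,
                  population$prior_t$rate, log = TRUE)
}

# MAP node index under the tie rule: highest log joint density; ties go to
# the smallest cs, then the smallest t.
map_index <- function(log_joint, grid) {
  tol <- 1e-12
  mx <- max(log_joint)
  cand <- which(log_joint >= mx - tol)
  pts <- grid$points
  cand[order(pts$cs[cand], pts$t[cand])][1L]
}

# Posterior moments of one weight vector on the grid.
grid_moments <- function(w, grid) {
  pts <- grid$points
  c(m_cs = sum(w * pts$cs), l_cs = sum(w * log(pts$cs)),
    s_cs = sum(w * pts$cs^2),
    m_t = sum(w * pts$t), l_t = sum(w * log(pts$t)),
    s_t = sum(w * pts$t^2))
}

#' E-step: posterior over (cs, t) for one subject
#'
#' Combines the gamma population prior with the summed trial
#' log-likelihoods on the parameter grid. Posterior masses use the grid's
#' quadrature areas; the MAP maximises the joint density (prior times
#' likelihood), with ties resolved toward the smallest cost of sampling and
#' then the smallest noise.
#'
#' @param trials Data frame of this subject's beads trials (`sequence`,
#'   `draws`, `declared`).
#' @param population A [population_model()].
#' @param config A [beads_config()].
#' @param grid A [param_grid()].
#' @param pg Optional prebuilt [policy_grid()] (must match `grid` and
#'   `config`); strongly recommended when fitting many subjects.
#' @return An object of class `subject_posterior`: weights, MAP estimate,
#'   posterior means, the log-likelihood at the MAP and the number of
#'   decision points contributing.
#' @export
subject_e_step <- function(trials, population, config = beads_config(),
                           grid = param_grid(), pg = NULL) {
  if (nrow(trials) == 0) stop("subject has no trials", call. = FALSE)
  if (is.null(pg)) pg <- policy_grid(grid, config)
  if (length(unique(trials$subject_id)) > 1) {
    stop("`subject_e_step` expects trials from a single subject", call. = FALSE)
  }
  if (is.null(trials$subject_id)) trials$subject_id <- "s1"
  cl <- cohort_grid_loglik(trials, pg)
  lp <- grid_log_prior(grid, population)
  log_joint <- cl$L[1L, ] + lp
  lm <- log_joint + grid$points$log_area
  w <- exp(lm - max(lm))
  w <- w / sum(w)
  mi <- map_index(log_joint, grid)
  mom <- grid_moments(w, grid)
  structure(
    list(grid = grid, log_joint = log_joint, weights = w,
         map_estimate = subject_params(grid$points$cs[mi], grid$points$t[mi]),
         post_mean_cs = mom[["m_cs"]], post_mean_t = mom[["m_t"]],
         moments = mom,
         subject_loglik = cl$L[1L, mi], n_actions = cl$n_actions[1L]),
    class = "subject_posterior"
  )
}

# Gamma maximum likelihood from a mean and a mean-log (digamma equation),
# with moment matching as the degenerate fallback.
gamma_mle <- function(mean_x, meanlog_x, var_x) {
  delta <- log(mean_x) - meanlog_x
  if (!is.finite(delta) || delta < 1e-10) {
    warning("degenerate posterior moments; falling back to moment matching",
            call. = FALSE)
    var_x <- max(var_x, mean_x^2 / 1e8)
    shape <- min(mean_x^2 / var_x, 1e8)
    return(gamma_prior(shape = shape, rate = shape / mean_x))
  }
  f <- function(s) log(s) - digamma(s) - delta
  # log(s) - digamma(s) decreases from +Inf to 0 on (0, Inf)
  root <- stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-12)$root
  gamma_prior(shape = root, rate = root / mean_x)
}

#' M-step: gamma hyperparameter update
#'
#' Pools the posterior-weighted first moments and mean logs across
#' subjects and solves the gamma maximum-likelihood (digamma) equation by
#' safeguarded root finding, independently for the cost of sampling and the
#' noise. When the pooled moments are degenerate (all posterior mass on a
#' single point), moment matching with a large capped shape is used instead
#' and a warning is raised.
#'
#' @param subjects List of [subject_e_step()] results (at least 2).
#' @return A [population_model()].
#' @export
m_step <- function(subjects) {
  if (length(subjects) < 2) stop("m_step needs at least 2 subjects", call. = FALSE)
  mom <- sapply(subjects, function(s) s$moments)
  m <- rowMeans(mom)
  population_model(
    prior_cs = gamma_mle(m[["m_cs"]], m[["l_cs"]],
                         max(m[["s_cs"]] - m[["m_cs"]]^2, 0)),
    prior_t = gamma_mle(m[["m_t"]], m[["l_t"]],
                        max(m[["s_t"]] - m[["m_t"]]^2, 0))
  )
}

#' Hierarchical empirical-Bayes EM fit of the beads model
#'
#' Alternates an E-step (grid posterior over each subject's cost of
#' sampling and cognitive noise, given gamma population priors) with an
#' M-step (gamma maximum-likelihood update of the priors from the pooled
#' posterior moments) until the hyperparameters stabilise. The model-fit
#' metric reported per subject is the log probability of that subject's
#' choices at the MAP parameters divided by the number of decision points.
#'
#' @param trials Cohort data frame with columns `subject_id`, `sequence`,
#'   `draws`, `declared` (and optionally `group`, carried through).
#' @param config A [beads_config()].
#' @param init Initial [population_model()]; the default puts gamma(shape 2)
#'   priors with means 0.05 (cs) and 0.5 (t).
#' @param grid A [param_grid()].
#' @param max_iter,tol EM stops when the relative change of all four
#'   hyperparameters falls below `tol` (default `1e-3`) or after `max_iter`
#'   iterations (default 200); non-convergence is flagged, not an error.
#' @param pg Optional prebuilt [policy_grid()]; reuse one across fits or
#'   replicate cohorts to avoid recomputing 1600 backward inductions.
#' @return An object of class `beads_fit`: final `population`, the
#'   per-iteration `population_path` and grid-quadrature `log_marginal`
#'   path, a `subjects` data frame (MAP and posterior-mean parameters,
#'   log-likelihood, number of actions, fit metric), the posterior `weights`
#'   matrix, and convergence flags.
#' @export
fit_em <- function(trials, config = beads_config(), init = NULL,
                   grid = param_grid(), max_iter = 200L, tol = 1e-3,
                   pg = NULL) {
  need <- c("subject_id", "sequence", "draws", "declared")
  if (!all(need %in% names(trials))) {
    stop("cohort table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(init)) {
    init <- population_model(gamma_prior(2, 2 / 0.05), gamma_prior(2, 2 / 0.5))
  }
  if (is.null(pg)) pg <- policy_grid(grid, config)
  cl <- cohort_grid_loglik(trials, pg)
  L <- cl$L
  n_sub <- nrow(L)
  log_area <- grid$points$log_area

  pop <- init
  pop_path <- list()
  lml_path <- numeric(0)
  converged <- FALSE
  it <- 0L
  W <- NULL
  notes <- character(0)
  collect_notes <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      notes <<- unique(c(notes, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }
  for (it in seq_len(max_iter)) {
    lp <- grid_log_prior(grid, pop)
    lj <- sweep(L, 2L, lp + log_area, "+")
    mx <- apply(lj, 1L, max)
    W <- exp(lj - mx)
    rs <- rowSums(W)
    W <- W / rs
    lml_path <- c(lml_path, sum(mx + log(rs)))
    mom <- apply(W, 1L, grid_moments, grid = grid)   # 6 x n_sub
    m <- rowMeans(mom)
    new_pop <- collect_notes(population_model(
      prior_cs = gamma_mle(m[["m_cs"]], m[["l_cs"]],
                           max(m[["s_cs"]] - m[["m_cs"]]^2, 0)),
      prior_t = gamma_mle(m[["m_t"]], m[["l_t"]],
                          max(m[["s_t"]] - m[["m_t"]]^2, 0))
    ))
    pop_path[[it]] <- new_pop
    old <- c(pop$prior_cs$shape, pop$prior_cs$rate,
             pop$prior_t$shape, pop$prior_t$rate)
    new <- c(new_pop$prior_cs$shape, new_pop$prior_cs$rate,
             new_pop$prior_t$shape, new_pop$prior_t$rate)
    pop <- new_pop
    if (max(abs(new - old) / pmax(abs(old), 1e-12)) < tol) {
      converged <- TRUE
      break
    }
  }

  # final subject summaries under the converged priors
  lp <- grid_log_prior(grid, pop)
  lj_dens <- sweep(L, 2L, lp, "+")
  map_idx <- apply(lj_dens, 1L, map_index, grid = grid)
  lj <- sweep(lj_dens, 2L, log_area, "+")
  mx <- apply(lj, 1L, max)
  W <- exp(lj - mx); W <- W / rowSums(W)
  mom <- apply(W, 1L, grid_moments, grid = grid)
  pts <- grid$points
  subjects_df <- data.frame(
    subject_id = cl$subjects,
    map_cs = pts$cs[map_idx], map_t = pts$t[map_idx],
    post_mean_cs = mom["m_cs", ], post_mean_t = mom["m_t", ],
    subject_loglik = L[cbind(seq_len(n_sub), map_idx)],
    n_actions = cl$n_actions,
    stringsAsFactors = FALSE
  )
  subjects_df$fit_metric <- subjects_df$subject_loglik / subjects_df$n_actions
  if ("group" %in% names(trials)) {
    grp <- trials$group[match(subjects_df$subject_id, trials$subject_id)]
    subjects_df <- cbind(subjects_df[1], group = grp, subjects_df[-1])
  }
  structure(
    list(population = pop, population_path = pop_path,
         log_marginal = lml_path, subjects = subjects_df, weights = W,
         grid = grid, config = config, converged = converged,
         iterations = it, notes = notes),
    class = "beads_fit"
  )
}

#' @export
print.beads_fit <- function(x, ...) {
  cat(sprintf("Hierarchical beads-model fit: %d subjects, %d EM iterations (%s)\n",
              nrow(x$subjects), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  cs prior: mean %.4g (sd %.4g)\n",
              x$population$prior_cs$mean, x$population$prior_cs$sd))
  cat(sprintf("  t  prior: mean %.4g (sd %.4g)\n",
              x$population$prior_t$mean, x$population$prior_t$sd))
  cat(sprintf("  median fit metric (log prob per action): %.3f\n",
              stats::median(x$subjects$fit_metric)))
  invisible(x)
}

#' Exclude subjects who always sample to the horizon
#'
#' Subjects whose draws-to-decision equals the task maximum on every trial
#' are plausibly using a simple "sample everything" heuristic rather than
#' prospective valuation, and a conservative reanalysis removes them before
#' fitting. The rule applies only to all-maximal subjects: a single
#' below-maximum trial keeps the subject.
#'
#' @param trials Cohort data frame with `subject_id` and `draws`.
#' @param config A [beads_config()] supplying the horizon.
#' @return List with `kept` (trials of retained subjects) and `excluded`
#'   (character vector of removed subject ids).
#' @export
exclude_max_draw_subjects <- function(trials, config = beads_config()) {
  if (nrow(trials) == 0) {
    return(list(kept = trials, excluded = character(0)))
  }
  all_max <- tapply(trials$draws, trials$subject_id,
                    function(d) all(d == config$d_max))
  excluded <- names(all_max)[all_max]
  list(kept = trials[!(trials$subject_id %in% excluded), , drop = FALSE],
       excluded = excluded)
}
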