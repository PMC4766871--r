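#' Specification of a synthetic two-group cohort
#'
#' Describes a fully synthetic study emulating a healthy-volunteer (HV)
#' versus binge-drinker (BD) contrast: per-group gamma populations over the
#' beads-model parameters (the BD noise distribution has a higher mean and
#' larger spread, while the cost of sampling is small and identical in both
#' groups), threshold-policy agents for the Information Sampling Task,
#' log-normal discount rates for the Monetary Choice Questionnaire, and an
#' alcohol-severity covariate correlated with the generating noise.
#'
#' @param n_hv,n_bd Subjects per group (default 30 each).
#' @param trials_per_subject Beads trials per subject (default 3, the
#'   classic block structure; raise to 20+ for parameter-recovery studies).
#' @param config A [beads_config()].
#' @param hv_model,bd_model [population_model()]s generating `(cs, t)` per
#'   group. Defaults: both groups `cs ~ Gamma(mean 0.02, sd 0.01)`;
#'   HV `t ~ Gamma(mean 0.25, sd 0.12)`, BD `t ~ Gamma(mean 0.6, sd 0.35)`.
#' @param ist Named list of IST agent settings: `trials_per_condition`
#'   (default 10), `threshold_mean`, `threshold_sd` (evidence-margin
#'   stopping threshold, default 5 and 1.5), `cost_sensitivity` (threshold
#'   reduction under the decreasing-win schedule, default 2).
#' @param mcq Named list: `meanlog`, `sdlog` of the per-subject log-normal
#'   discount rate (defaults `log(0.015)`, 1.2; identical across groups, as
#'   no group difference in discounting is being emulated), `noise`
#'   (logistic choice temperature on the value difference, default 1).
#' @param audit Named list: `hv_mean`, `hv_sd`, `bd_mean`, `bd_sd` of the
#'   severity covariate (defaults 4/2 and 16/5) and `rho_t`, its
#'   within-group correlation with the generating noise (default 0.3).
#' @param seed Integer seed; the entire cohort is a deterministic function
#'   of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hv = 30L, n_bd = 30L, trials_per_subject = 3L,
                        config = beads_config(),
                        hv_model = population_model(
                          gamma_prior_ms(0.02, 0.01), gamma_prior_ms(0.25, 0.12)),
                        bd_model = population_model(
                          gamma_prior_ms(0.02, 0.01), gamma_prior_ms(0.6, 0.35)),
                        ist = list(), mcq = list(), audit = list(),
                        seed = 1L) {
  if (n_hv < 2L || n_bd < 2L) stop("group sizes must be >= 2", call. = FALSE)
  ist <- utils::modifyList(
    list(trials_per_condition = 10L, threshold_mean = 5, threshold_sd = 1.5,
         cost_sensitivity = 2),
    ist)
  mcq <- utils::modifyList(
    list(meanlog = log(0.015), sdlog = 1.2, noise = 1), mcq)
  audit <- utils::modifyList(
    list(hv_mean = 4, hv_sd = 2, bd_mean = 16, bd_sd = 5, rho_t = 0.3),
    audit)
  structure(
    list(n_hv = as.integer(n_hv), n_bd = as.integer(n_bd),
         trials_per_subject = as.integer(trials_per_subject),
         config = config, hv_model = hv_model, bd_model = bd_model,
         ist = ist, mcq = mcq, audit = audit, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d HV + %d BD, %d beads trials each, seed %d\n",
              x$n_hv, x$n_bd, x$trials_per_subject, x$seed))
  invisible(x)
}

# Simulate one IST trial for a threshold agent: open boxes in random order
# until the opened colour margin reaches the threshold (or the board is
# exhausted), then choose the opened-majority colour.
simulate_ist_trial <- function(threshold) {
  maj_n <- sample(13:17, 1L)
  maj_col <- sample(c("X", "O"), 1L)
  min_col <- setdiff(c("X", "O"), maj_col)
  cells <- sample(c(rep(maj_col, maj_n), rep(min_col, 25L - maj_n)))
  order_open <- sample.int(25L)
  margin <- cumsum(ifelse(cells[order_open] == "X", 1L, -1L))
  stop_at <- which(abs(margin) >= threshold)
  n_open <- if (length(stop_at)) stop_at[1L] else 25L
  opened <- order_open[seq_len(n_open)]
  final <- margin[n_open]
  choice <- if (final > 0L) "X" else if (final < 0L) "O" else
    sample(c("X", "O"), 1L)
  rc <- cbind((opened - 1L) %/% 5L, (opened - 1L) %% 5L)
  list(grid = paste(cells, collapse = ""),
       opened = paste(paste(rc[, 1L], rc[, 2L], sep = ","), collapse = ";"),
       choice = choice, majority = maj_col)
}

# Simulate the 27 MCQ choices of a hyperbolic discounter with logistic
# choice noise on the value difference.
simulate_mcq_responses <- function(k, items, noise = 1) {
  v_imm <- items$immediate_amount
  v_del <- items$delayed_amount / (1 + k * items$delay_days)
  if (noise <= 0) {
    ifelse(v_imm > v_del, "immediate", "delayed")
  } else {
    p_imm <- stats::plogis((v_imm - v_del) / noise)
    ifelse(stats::runif(length(p_imm)) < p_imm, "immediate", "delayed")
  }
}

#' Generate a complete synthetic cohort
#'
#' Draws per-subject ground-truth parameters from the group populations,
#' then simulates the beads trials forward from the observer model, the IST
#' trials from the threshold agents, and the MCQ responses from noisy
#' hyperbolic discounters. Every record is a deterministic function of the
#' spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort` with data frames `beads`,
#'   `ist`, `mcq`, the per-subject `ground_truth` (generating `cs`, `t`,
#'   IST threshold, discount rate `k`, severity covariate `audit`), and the
#'   spec itself.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  items <- kirby_items()
  config <- spec$config
  groups <- c(rep("HV", spec$n_hv), rep("BD", spec$n_bd))
  ids <- sprintf("%s%02d", groups, c(seq_len(spec$n_hv), seq_len(spec$n_bd)))

  beads_rows <- list(); ist_rows <- list(); mcq_rows <- list()
  gt_rows <- list()
  for (i in seq_along(ids)) {
    model <- if (groups[i] == "HV") spec$hv_model else spec$bd_model
    cs <- stats::rgamma(1L, model$prior_cs$shape, model$prior_cs$rate)
    t <- stats::rgamma(1L, model$prior_t$shape, model$prior_t$rate)
    vt <- build_value_table(subject_params(cs, t), config)

    for (j in seq_len(spec$trials_per_subject)) {
      jar <- sample(c("A", "B"), 1L)
      tr <- simulate_trial(subject_params(cs, t), config, true_jar = jar,
                           table = vt)
      conf <- beads_posterior(
        sum(strsplit(tr$sequence, "")[[1L]][seq_len(tr$draws)] == "A"),
        sum(strsplit(tr$sequence, "")[[1L]][seq_len(tr$draws)] == "B"),
        config)
      if (tr$declared == "B") conf <- 1 - conf
      beads_rows[[length(beads_rows) + 1L]] <- data.frame(
        subject_id = ids[i], group = groups[i], trial_index = j,
        sequence = tr$sequence, draws = tr$draws, declared = tr$declared,
        true_jar = tr$true_jar, confidence = round(conf, 4),
        stringsAsFactors = FALSE)
    }

    thr <- max(1L, round(stats::rnorm(1L, spec$ist$threshold_mean,
                                      spec$ist$threshold_sd)))
    for (cond in c("fixed_win", "decreasing_win")) {
      thr_eff <- if (cond == "fixed_win") thr else
        max(1L, thr - round(spec$ist$cost_sensitivity))
      for (j in seq_len(spec$ist$trials_per_condition)) {
        trial <- simulate_ist_trial(thr_eff)
        ist_rows[[length(ist_rows) + 1L]] <- data.frame(
          subject_id = ids[i], trial_index = j, condition = cond,
          grid = trial$grid, opened = trial$opened, choice = trial$choice,
          stringsAsFactors = FALSE)
      }
    }

    k <- stats::rlnorm(1L, spec$mcq$meanlog, spec$mcq$sdlog)
    resp <- simulate_mcq_responses(k, items, spec$mcq$noise)
    mcq_rows[[length(mcq_rows) + 1L]] <- data.frame(
      subject_id = ids[i], item_id = items$item_id, choice = resp,
      stringsAsFactors = FALSE)

    au <- spec$audit
    mu <- if (groups[i] == "HV") au$hv_mean else au$bd_mean
    sdv <- if (groups[i] == "HV") au$hv_sd else au$bd_sd
    model_t <- model$prior_t
    z_t <- (t - model_t$mean) / model_t$sd
    audit_score <- max(0, mu + sdv * (au$rho_t * z_t +
                                        sqrt(1 - au$rho_t^2) * stats::rnorm(1L)))
    gt_rows[[length(gt_rows) + 1L]] <- data.frame(
      subject_id = ids[i], group = groups[i], cs = cs, t = t,
      ist_threshold = thr, k = k, audit = audit_score,
      stringsAsFactors = FALSE)
  }

  structure(
    list(beads = do.call(rbind, beads_rows),
         ist = do.call(rbind, ist_rows),
         mcq = do.call(rbind, mcq_rows),
         ground_truth = do.call(rbind, gt_rows),
         spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d HV, %d BD)\n",
              nrow(x$ground_truth), sum(x$ground_truth$group == "HV"),
              sum(x$ground_truth$group == "BD")))
  cat(sprintf("  beads trials: %d, IST trials: %d, MCQ responses: %d\n",
              nrow(x$beads), nrow(x$ist), nrow(x$mcq)))
  invisible(x)
}

#' Write a small fixture suite to disk
#'
#' Generates a seeded miniature cohort (6 subjects per group, 3 beads
#' trials, 2 IST trials per condition) and writes its tables together with
#' expected per-trial IST scores and per-subject discount rates computed by
#' the package's scorers, for use in regression tests. Re-running with the
#' same seed reproduces every file byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (default 123).
#' @return Invisibly, the manifest: file names, seed, and the spec used.
#' @export
generate_fixture_suite <- function(out_dir, seed = 123L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort_spec(n_hv = 6L, n_bd = 6L, trials_per_subject = 3L,
                      ist = list(trials_per_condition = 2L), seed = seed)
  cohort <- generate_cohort(spec)

  ist_scores <- do.call(rbind, lapply(seq_len(nrow(cohort$ist)), function(r) {
    trial <- cohort$ist[r, ]
    data.frame(subject_id = trial$subject_id,
               trial_index = trial$trial_index,
               condition = trial$condition,
               boxes_opened = length(strsplit(trial$opened, ";")[[1L]]),
               p_correct = ist_p_correct(trial),
               points = ist_points(trial),
               error_type = ist_error_type(trial),
               stringsAsFactors = FALSE)
  }))
  items <- kirby_items()
  mcq_k <- do.call(rbind, lapply(split(cohort$mcq, cohort$mcq$subject_id),
                                 function(d) {
    d <- d[order(d$item_id), ]
    est <- kirby_k(d$choice, items)
    data.frame(subject_id = d$subject_id[1L], k = est$k,
               consistency = est$consistency, stringsAsFactors = FALSE)
  }))
  mcq_k <- mcq_k[order(mcq_k$subject_id), ]

  files <- c(beads = "beads.csv", ist = "ist.csv", mcq = "mcq.csv",
             ground_truth = "ground_truth.csv",
             expected_ist_scores = "expected_ist_scores.csv",
             expected_mcq_k = "expected_mcq_k.csv")
  utils::write.csv(cohort$beads, file.path(out_dir, files["beads"]),
                   row.names = FALSE)
  utils::write.csv(cohort$ist, file.path(out_dir, files["ist"]),
                   row.names = FALSE)
  utils::write.csv(cohort$mcq, file.path(out_dir, files["mcq"]),
                   row.names = FALSE)
  utils::write.csv(cohort$ground_truth,
                   file.path(out_dir, files["ground_truth"]),
                   row.names = FALSE)
  utils::write.csv(ist_scores,
                   file.path(out_dir, files["expected_ist_scores"]),
                   row.names = FALSE)
  utils::write.csv(mcq_k, file.path(out_dir, files["expected_mcq_k"]),
                   row.names = FALSE)
  manifest <- list(files = as.list(files), seed = seed,
                   n_hv = spec$n_hv, n_bd = spec$n_bd,
                   trials_per_subject = spec$trials_per_subject)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$files$manifest <- "manifest.json"
  invisible(manifest)
}
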