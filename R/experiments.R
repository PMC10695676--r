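#' Experiment design templates
#'
#' Desk-scale replicas of the four experimental designs:
#' \describe{
#'   \item{design_exp1}{between-subject; 45 free-exploration trials, then one
#'     task with 10 visible + 10 hidden questions in random order.}
#'   \item{design_exp2}{as exp1, plus five visible preview questions after
#'     trials 10, 15, 18, 25 and 30 of the learning phase (recorded for
#'     format fidelity; they do not change the agent).}
#'   \item{design_exp3}{within-subject; 60 learning trials, all three tasks
#'     in counterbalanced order, 5 visible then 5 hidden questions each.}
#'   \item{design_exp4}{16 free-interaction trials, then threshold-gated
#'     feedback learning on one task (15-question blocks, 65% accuracy
#'     threshold, up to 3 attempts per visible/hidden part; exclusion when
#'     both parts fail), then no-feedback transfer blocks of 10 visible +
#'     10 hidden questions on each untrained task.}
#' }
#' The 65% threshold on a 15-question block is implemented as at least
#' `ceiling(0.65 * 15) = 10` correct.
#'
#' @param ... Named overrides of the defaults.
#' @return A design list.
#' @export
design_exp1 <- function(...) {
  utils::modifyList(list(name = "exp1", learning_trials = 45, preview = NULL,
                  within = FALSE, n_visible = 10, n_hidden = 10,
                  order = "random", replace = TRUE), list(...))
}

#' @rdname design_exp1
#' @export
design_exp2 <- function(...) {
  utils::modifyList(design_exp1(name = "exp2", preview = c(10, 15, 18, 25, 30)),
             list(...))
}

#' @rdname design_exp1
#' @export
design_exp3 <- function(...) {
  utils::modifyList(list(name = "exp3", learning_trials = 60, preview = NULL,
                  within = TRUE, n_visible = 5, n_hidden = 5,
                  order = "visible_first", replace = TRUE), list(...))
}

#' @rdname design_exp1
#' @export
design_exp4 <- function(...) {
  d <- utils::modifyList(list(name = "exp4", learning_trials = 16, threshold = 0.65,
                       block_size = 15, max_attempts = 3,
                       transfer_visible = 10, transfer_hidden = 10,
                       replace = TRUE), list(...))
  if (!is.null(d$threshold) && (d$threshold <= 0.5 || d$threshold >= 1))
    stop("threshold must lie in (0.5, 1)")
  if (d$max_attempts < 1) stop("max_attempts must be >= 1")
  d
}

#' Between-subject experiment harness (free exploration then one task)
#'
#' Simulates a cohort under an exp1/exp2-style design and runs the aggregate
#' analyses per task x form: mental-model accuracy, pooled beta fits under
#' the normative and alternative-neglect labelings, and the
#' likelihood-ratio comparison between the two answer rules. All labelings
#' use each participant's own fitted mental model, pooled within condition.
#'
#' @param machine True `"fsm"`.
#' @param n_participants Cohort size.
#' @param agent `"agent_config"` template.
#' @param design Design list (default [design_exp1()]).
#' @param tasks Tasks to include (default all three, assigned
#'   between-subject).
#' @param epsilon Evidence regularizer.
#' @param seed Optional master seed.
#' @return List of class `"results_table"`: `accuracy` (per participant x
#'   form), `fits` (per task x form x answer model), `comparisons` (per task
#'   x form), and the `cohort`.
#' @export
run_exp12 <- function(machine, n_participants, agent, design = design_exp1(),
                      tasks = TASKS, epsilon = 0.1, seed = NULL) {
  design$tasks <- tasks
  cohort <- simulate_cohort(machine, design, n_participants, agent,
                            epsilon = epsilon, seed = seed)
  acc_rows <- list(); fit_rows <- list(); cmp_rows <- list()
  for (task in tasks) {
    members <- Filter(function(p) task %in% p$tasks, cohort)
    for (form in FORMS) {
      recs <- list(norm = list(), an = list())
      for (p in members) {
        sel <- p$responses$task == task & p$responses$form == form
        resp <- p$responses[sel, c("question_id", "choice")]
        bank <- p$bank[p$bank$task == task & p$bank$form == form, ]
        acc <- mm_accuracy(resp, bank, p$model, "normative", epsilon)
        acc_an <- mm_accuracy(resp, bank, p$model, "alternative_neglect",
                              epsilon)
        acc_rows[[length(acc_rows) + 1L]] <- data.frame(
          participant = p$id, task = task, form = form,
          mm_accuracy = acc$accuracy, mm_accuracy_an = acc_an$accuracy,
          n_scored = acc$n_scored)
        recs$norm[[length(recs$norm) + 1L]] <-
          build_evidence_records(resp, bank, p$model, "normative", epsilon)
        recs$an[[length(recs$an) + 1L]] <-
          build_evidence_records(resp, bank, p$model, "alternative_neglect",
                                 epsilon)
      }
      rec_norm <- do.call(rbind, recs$norm)
      rec_an <- do.call(rbind, recs$an)
      for (am in c("normative", "alternative_neglect")) {
        rec <- if (am == "normative") rec_norm else rec_an
        f <- tryCatch(fit_beta(rec), error = function(e) NULL)
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          task = task, form = form, answer_model = am,
          beta = if (is.null(f)) NA_real_ else f$beta,
          se = if (is.null(f)) NA_real_ else f$se,
          loglik = if (is.null(f)) NA_real_ else f$loglik,
          n = nrow(rec),
          separation = if (is.null(f)) NA else f$separation)
      }
      ll_n <- tryCatch(fit_beta(rec_norm)$loglik, error = function(e) NA_real_)
      ll_a <- tryCatch(fit_beta(rec_an)$loglik, error = function(e) NA_real_)
      dls <- ll_a - ll_n
      cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
        task = task, form = form,
        favored = if (is.na(dls)) NA_character_
                  else if (dls >= 0) "alternative_neglect" else "normative",
        delta_L = abs(dls), statistic = 2 * abs(dls),
        p_chi2_2dL = stats::pchisq(2 * abs(dls), 1, lower.tail = FALSE),
        p_chi2_dL = stats::pchisq(abs(dls), 1, lower.tail = FALSE),
        n = nrow(rec_norm))
    }
  }
  structure(list(accuracy = do.call(rbind, acc_rows),
                 fits = do.call(rbind, fit_rows),
                 comparisons = do.call(rbind, cmp_rows),
                 cohort = cohort),
            class = "results_table")
}

#' Within-subject experiment harness with cross-task beta correlations
#'
#' Simulates an exp3-style cohort (all three tasks per participant,
#' counterbalanced order, 5 visible then 5 hidden questions per task), fits
#' a per-participant beta for every task x form from the participant's own
#' mental-model labeling, and reports Pearson correlations across
#' participants for each task pair within each form. Participants whose
#' records are degenerate for a cell (every question tied under their model)
#' get `NA` there and are dropped pairwise from correlations; the tally is
#' reported.
#'
#' @inheritParams run_exp12
#' @param design Default [design_exp3()].
#' @param betas Optional per-participant sensitivity vector (shared across
#'   tasks) or `n x 3` matrix (task-specific; columns in the order
#'   prediction, explanation, control).
#' @return List of class `"results_table"`: `betas` (participant x task x
#'   form), `correlations` (form x task pair), `n_degenerate`, `cohort`.
#' @export
run_exp3 <- function(machine, n_participants, agent, design = design_exp3(),
                     epsilon = 0.1, seed = NULL, betas = NULL) {
  cohort <- simulate_cohort(machine, design, n_participants, agent,
                            epsilon = epsilon, seed = seed, betas = betas)
  rows <- list()
  for (p in cohort) {
    for (task in TASKS) for (form in FORMS) {
      sel <- p$responses$task == task & p$responses$form == form
      resp <- p$responses[sel, c("question_id", "choice")]
      bank <- p$bank[p$bank$task == task & p$bank$form == form, ]
      f <- tryCatch(fit_beta(build_evidence_records(resp, bank, p$model,
                                                    "normative", epsilon)),
                    error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p$id, task = task, form = form,
        order = match(task, p$tasks),
        beta = if (is.null(f)) NA_real_ else f$beta,
        separation = if (is.null(f)) NA else f$separation)
    }
  }
  betas_df <- do.call(rbind, rows)
  cors <- list()
  pairs <- utils::combn(TASKS, 2)
  for (form in FORMS) {
    for (j in seq_len(ncol(pairs))) {
      t1 <- pairs[1, j]; t2 <- pairs[2, j]
      b1 <- betas_df$beta[betas_df$task == t1 & betas_df$form == form]
      b2 <- betas_df$beta[betas_df$task == t2 & betas_df$form == form]
      ok <- is.finite(b1) & is.finite(b2)
      r <- if (sum(ok) > 2 && stats::sd(b1[ok]) > 0 && stats::sd(b2[ok]) > 0)
        stats::cor(b1[ok], b2[ok]) else NA_real_
      cors[[length(cors) + 1L]] <- data.frame(
        form = form, task1 = t1, task2 = t2, r = r, n = sum(ok))
    }
  }
  structure(list(betas = betas_df, correlations = do.call(rbind, cors),
                 n_degenerate = sum(is.na(betas_df$beta)), cohort = cohort),
            class = "results_table")
}

#' Threshold-gated feedback training with transfer testing
#'
#' Each participant: 16 free-interaction trials, then feedback learning on
#' the trained task in two parts (visible then hidden), each part a
#' 15-question block passed at >= `ceiling(threshold * block_size)` correct
#' (correctness against the true machine's normative answers), with up to 3
#' attempts. The feedback mechanism is modeled as: after every feedback
#' block the agent's beta increases by `agent$beta_step`, and the agent's
#' mental model absorbs the fully visible transitions shown in that block's
#' visible episodes as extra observations. Participants failing both parts
#' are excluded. Survivors take no-feedback transfer blocks (10 visible +
#' 10 hidden) on the two untrained tasks; betas are fitted per task x form
#' against the final mental model, and trained-vs-transfer correlations are
#' computed per form.
#'
#' @inheritParams run_exp12
#' @param trained_task Task trained with feedback.
#' @param design Default [design_exp4()].
#' @return List of class `"results_table"`: `participants` (attempts, pass
#'   flags, exclusion, trained betas), `transfer` (per participant x task x
#'   form betas), `correlations`, `summary` (attempt means, exclusion
#'   tally), `cohort` (per-participant final models).
#' @export
run_exp4 <- function(machine, n_participants, agent,
                     trained_task = "control", design = design_exp4(),
                     epsilon = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1, n_participants)
  pass_need <- ceiling(design$threshold * design$block_size)
  others <- setdiff(TASKS, trained_task)
  part_rows <- list(); transfer_rows <- list(); cohort <- list()
  for (i in seq_len(n_participants)) {
    set.seed(child_seeds[i])
    learn <- simulate_learning(machine, design$learning_trials)
    model <- learn$model
    beta <- agent$beta
    attempts <- c(visible = 0L, hidden = 0L)
    passed <- c(visible = FALSE, hidden = FALSE)
    final_recs <- list()
    next_id <- 1L
    for (form in c("visible", "hidden")) {
      for (a in seq_len(design$max_attempts)) {
        attempts[form] <- attempts[form] + 1L
        bank <- generate_questions(machine, trained_task, form,
                                   design$block_size, replace = TRUE,
                                   epsilon = epsilon, id_start = next_id)
        next_id <- next_id + nrow(bank)
        use_model <- if (agent$model_source == "true_machine") machine
                     else model
        resp <- answer_bank(agent, bank, use_model, epsilon, beta = beta)
        correct <- resp$choice ==
          bank$truth_normative[match(resp$question_id, bank$id)]
        # feedback block effects: sensitivity increment + absorbing the
        # visible transitions shown in the block
        beta <- beta + agent$beta_step
        if (form == "visible") {
          triples <- do.call(rbind, lapply(bank$episode, function(e) {
            ep <- parse_episode(e, machine)
            tr <- data.frame(state = ep$start, input = ep$input1,
                             next_state = ep$mid)
            if (ep$task == "explanation")
              tr <- rbind(tr, data.frame(state = ep$mid, input = ep$input2,
                                         next_state = ep$final))
            tr
          }))
          model <- update_mental_model(model, triples)
        }
        done <- sum(correct) >= pass_need
        if (done || a == design$max_attempts) {
          final_recs[[form]] <- build_evidence_records(
            resp, bank, if (agent$model_source == "true_machine") machine
                        else model,
            "normative", epsilon)
          passed[form] <- done
          break
        }
      }
    }
    excluded <- !passed["visible"] && !passed["hidden"]
    trained_beta <- vapply(c("visible", "hidden"), function(f) {
      fit <- tryCatch(fit_beta(final_recs[[f]]), error = function(e) NULL)
      if (is.null(fit)) NA_real_ else fit$beta
    }, 0)
    if (!excluded) {
      use_model <- if (agent$model_source == "true_machine") machine else model
      for (task in sample(others)) {       # counterbalanced transfer order
        bank <- generate_test_block(machine, task, design$transfer_visible,
                                    design$transfer_hidden, order = "random",
                                    replace = TRUE, epsilon = epsilon,
                                    id_start = next_id)
        next_id <- next_id + nrow(bank)
        resp <- answer_bank(agent, bank, use_model, epsilon, beta = beta)
        for (f in FORMS) {
          b <- bank[bank$form == f, ]
          r <- resp[resp$question_id %in% b$id, ]
          fit <- tryCatch(fit_beta(build_evidence_records(r, b, use_model,
                                                          "normative",
                                                          epsilon)),
                          error = function(e) NULL)
          transfer_rows[[length(transfer_rows) + 1L]] <- data.frame(
            participant = i, task = task, form = f,
            beta = if (is.null(fit)) NA_real_ else fit$beta)
        }
      }
    }
    part_rows[[length(part_rows) + 1L]] <- data.frame(
      participant = i, trained_task = trained_task,
      attempts_visible = attempts[["visible"]],
      attempts_hidden = attempts[["hidden"]],
      passed_visible = passed[["visible"]], passed_hidden = passed[["hidden"]],
      excluded = excluded, final_beta = beta,
      trained_beta_visible = trained_beta[["visible"]],
      trained_beta_hidden = trained_beta[["hidden"]])
    cohort[[i]] <- list(id = i, model = model, log = learn$log,
                        seed = child_seeds[i])
  }
  participants <- do.call(rbind, part_rows)
  transfer <- if (length(transfer_rows) > 0) do.call(rbind, transfer_rows)
              else NULL
  cors <- list()
  if (!is.null(transfer)) {
    for (task in others) for (f in FORMS) {
      tb <- participants[[paste0("trained_beta_", f)]]
      xb <- rep(NA_real_, n_participants)
      sel <- transfer$task == task & transfer$form == f
      xb[transfer$participant[sel]] <- transfer$beta[sel]
      ok <- is.finite(tb) & is.finite(xb) & !participants$excluded
      r <- if (sum(ok) > 2 && stats::sd(tb[ok]) > 0 && stats::sd(xb[ok]) > 0)
        stats::cor(tb[ok], xb[ok]) else NA_real_
      cors[[length(cors) + 1L]] <- data.frame(
        form = f, trained_task = trained_task, transfer_task = task,
        r = r, n = sum(ok))
    }
  }
  n_exc <- sum(participants$excluded)
  structure(list(
    participants = participants, transfer = transfer,
    correlations = if (length(cors)) do.call(rbind, cors) else NULL,
    summary = list(n = n_participants, n_excluded = n_exc,
                   n_analyzed = n_participants - n_exc,
                   mean_attempts = mean(c(participants$attempts_visible,
                                          participants$attempts_hidden)),
                   pass_first_visible = mean(participants$attempts_visible ==
                                               1 & participants$passed_visible)),
    cohort = cohort),
    class = "results_table")
}

#' Two-type mixture thought experiment for cross-task score correlations
#'
#' Monte-Carlo power analysis: a cohort mixes participants who possess a
#' mental model (per-question accuracy `acc_with` on both tasks) with pure
#' guessers (`acc_without`, typically 0.5). Each participant's two task
#' scores are independent Binomial(`n_questions`, accuracy) proportions
#' given their type. Per replicate cohort the Pearson correlation between
#' task scores is computed, and positivity is tested one-sided at `alpha`
#' with the Fisher z transform. The analytic expectation
#' `Var(p) / (Var(p) + E[p(1-p)] / n_questions)` is reported as an oracle.
#'
#' @param acc_with,acc_without Per-question accuracies of the two types, in
#'   `[0.5, 1]`.
#' @param n_questions Questions per task.
#' @param n_participants Cohort size per replicate.
#' @param mixture Fraction of with-model participants.
#' @param alpha One-sided significance level for the positivity test.
#' @param n_replicates Number of simulated cohorts.
#' @param mode `"scores"` correlates raw proportion-correct scores;
#'   `"beta"` first maps each score to the equivalent sensitivity estimate
#'   (the no-intercept logistic coefficient at unit evidence, capped at 20)
#'   and correlates those.
#' @param seed Optional integer seed.
#' @return List: `mean_cor`, `type2_rate` (fraction of cohorts failing to
#'   reject `rho <= 0`), `closed_form` (analytic correlation),
#'   `degenerate` (TRUE when the two accuracies coincide, making the
#'   population correlation undefined as a mixture effect), `cors` (per
#'   replicate), and the call parameters.
#' @export
thought_experiment <- function(acc_with = 0.7, acc_without = 0.5,
                               n_questions = 5, n_participants = 200,
                               mixture = 0.5, alpha = 0.05,
                               n_replicates = 10000,
                               mode = c("scores", "beta"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(acc_with >= 0.5, acc_with <= 1, acc_without >= 0.5,
            acc_without <= 1, n_questions >= 1, n_participants >= 4,
            n_replicates >= 1)
  degenerate <- abs(acc_with - acc_without) < 1e-12
  n <- n_participants * n_replicates
  type <- stats::rbinom(n, 1, mixture)
  acc <- ifelse(type == 1, acc_with, acc_without)
  s1 <- stats::rbinom(n, n_questions, acc) / n_questions
  s2 <- stats::rbinom(n, n_questions, acc) / n_questions
  if (mode == "beta") {
    to_beta <- function(s) {
      s <- pmin(pmax(s, 1e-6), 1 - 1e-6)
      pmin(pmax(stats::qlogis(s) / 2, -20), 20)
    }
    s1 <- to_beta(s1); s2 <- to_beta(s2)
  }
  dim(s1) <- dim(s2) <- c(n_participants, n_replicates)
  m1 <- colMeans(s1); m2 <- colMeans(s2)
  cov12 <- colMeans(s1 * s2) - m1 * m2
  v1 <- colMeans(s1^2) - m1^2
  v2 <- colMeans(s2^2) - m2^2
  r <- ifelse(v1 > 0 & v2 > 0, cov12 / sqrt(v1 * v2), NA_real_)
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)) * sqrt(n_participants - 3)
  reject <- !is.na(z) & z > stats::qnorm(1 - alpha)
  list(mean_cor = mean(r, na.rm = TRUE),
       type2_rate = mean(!reject),
       closed_form = te_closed_form_cor(acc_with, acc_without, n_questions,
                                        mixture),
       degenerate = degenerate, cors = r,
       params = list(acc_with = acc_with, acc_without = acc_without,
                     n_questions = n_questions,
                     n_participants = n_participants, mixture = mixture,
                     alpha = alpha, n_replicates = n_replicates, mode = mode))
}

#' Closed-form score correlation for the two-type mixture
#'
#' `Var(p) / (Var(p) + E[p(1 - p)] / n_questions)` where `p` is the
#' per-question accuracy across the two types: the between-type variance of
#' true accuracy attenuated by within-participant binomial noise.
#'
#' @inheritParams thought_experiment
#' @return The analytic Pearson correlation between the two task scores.
#' @export
te_closed_form_cor <- function(acc_with, acc_without, n_questions,
                               mixture = 0.5) {
  p <- c(acc_with, acc_without); w <- c(mixture, 1 - mixture)
  m <- sum(w * p)
  v <- sum(w * (p - m)^2)
  noise <- sum(w * p * (1 - p)) / n_questions
  if (v + noise == 0) return(NA_real_)
  v / (v + noise)
}

#' @export
print.results_table <- function(x, ...) {
  cat("<results_table: ", paste(setdiff(names(x), "cohort"), collapse = ", "),
      ">\n", sep = "")
  invisible(x)
}
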