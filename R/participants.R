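#' Configure a synthetic participant
#'
#' Agents embody the modeling assumptions of the analysis pipeline so that
#' every downstream stage can be exercised on data with known structure.
#' Four response strategies are built in, plus a calibration agent:
#' \describe{
#'   \item{normative}{scores each question with the Bayesian rule on its
#'     probability model and chooses the favored option with probability
#'     `p_C(beta, R)`.}
#'   \item{alternative_neglect}{as above, but hidden questions are scored
#'     with the greedy heuristic.}
#'   \item{recency}{explanation questions only: chooses the most recent
#'     input with probability `recency_strength`.}
#'   \item{random}{fair coin on every question.}
#'   \item{fixed_accuracy}{chooses the true-machine normative answer with
#'     probability `accuracy`, regardless of its own model (useful as a
#'     known-accuracy oracle for threshold designs).}
#' }
#'
#' @param answer_model One of the strategies above.
#' @param beta Sensitivity for evidence-driven agents (>= 0).
#' @param model_source `"learned"` (use the agent's own fitted mental model)
#'   or `"true_machine"`.
#' @param recency_strength Probability of choosing `input2` (recency agent).
#' @param accuracy Per-question success probability (fixed_accuracy agent).
#' @param beta_step Additive increment to `beta` after each feedback block
#'   (threshold-gated training designs).
#' @return List of class `"agent_config"`.
#' @export
agent_config <- function(answer_model = c("normative", "alternative_neglect",
                                          "recency", "random",
                                          "fixed_accuracy"),
                         beta = 1, model_source = c("learned", "true_machine"),
                         recency_strength = 0.58, accuracy = 0.6,
                         beta_step = 0) {
  answer_model <- match.arg(answer_model)
  model_source <- match.arg(model_source)
  if (beta < 0) stop("generative agents require beta >= 0")
  if (recency_strength < 0 || recency_strength > 1)
    stop("recency_strength must be in [0, 1]")
  structure(list(answer_model = answer_model, beta = beta,
                 model_source = model_source,
                 recency_strength = recency_strength, accuracy = accuracy,
                 beta_step = beta_step),
            class = "agent_config")
}

#' Simulate a learning phase and fit the resulting mental model
#'
#' Runs a free-exploration session (uniform-random input choice from a
#' uniformly random start state) and fits the frequency-based mental model
#' from the resulting log. `n_trials = 0` yields an empty log and an
#' all-uniform model.
#'
#' @param machine True `"fsm"`.
#' @param n_trials Number of exploration trials (>= 0).
#' @param seed Optional integer seed.
#' @return List with `log` and `model`.
#' @export
simulate_learning <- function(machine, n_trials, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  log <- if (n_trials == 0) {
    data.frame(trial = integer(), state = character(), input = character(),
               next_state = character(), stringsAsFactors = FALSE)
  } else {
    simulate_session(machine, n_trials)
  }
  list(log = log, model = fit_mental_model(log, machine))
}

#' Have an agent answer one test question
#'
#' @param agent An `"agent_config"`.
#' @param question One-row question data frame.
#' @param model Probability model for evidence-driven agents (the agent's
#'   mental model or the true machine, per `agent$model_source`).
#' @param epsilon Evidence regularizer.
#' @param beta Optional override of `agent$beta` (used by training designs
#'   where beta evolves).
#' @return The chosen option (one of the question's options).
#' @export
answer_question <- function(agent, question, model = NULL, epsilon = 0.1,
                            beta = NULL) {
  q <- as_question(question)
  opts <- c(q$option1, q$option2)
  am <- agent$answer_model
  if (am == "random") return(sample(opts, 1))
  if (am == "recency") {
    if (q$task != "explanation")
      stop("recency agents answer explanation questions only")
    pick <- if (stats::runif(1) < agent$recency_strength) "input2" else "input1"
    return(pick)
  }
  if (am == "fixed_accuracy") {
    truth <- q$truth_normative
    other <- setdiff(opts, truth)
    return(if (stats::runif(1) < agent$accuracy) truth else other)
  }
  if (is.null(model)) stop("evidence-driven agents need a probability model")
  s <- if (am == "normative") normative_scores(q, model, epsilon)
       else an_scores(q, model, epsilon)
  if (identical(s$favored, "TIE")) return(sample(opts, 1))
  b <- if (is.null(beta)) agent$beta else beta
  p <- choice_prob(b, s$R)
  other <- setdiff(opts, s$favored)
  if (stats::runif(1) < p) s$favored else other
}

#' Have an agent answer every question in a bank
#'
#' @inheritParams answer_question
#' @param bank Question bank data frame.
#' @return `data.frame(question_id, choice)` in bank order.
#' @export
answer_bank <- function(agent, bank, model = NULL, epsilon = 0.1,
                        beta = NULL) {
  data.frame(question_id = bank$id,
             choice = vapply(seq_len(nrow(bank)), function(i)
               answer_question(agent, bank[i, ], model, epsilon, beta), ""),
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of synthetic participants
#'
#' Each participant gets an independent seed stream, a learning phase, a
#' per-participant question bank drawn according to the design, and
#' responses from the agent. Between-subject designs assign each participant
#' one task (balanced across the cohort, in randomized order); within-subject
#' designs give every participant all three tasks in a counterbalanced order.
#'
#' @param machine True `"fsm"`.
#' @param design An experiment design (see [design_exp1()] and friends) with
#'   fields `learning_trials`, `n_visible`, `n_hidden`, `order`, `within`,
#'   and optionally `tasks`, `preview`, `replace`.
#' @param n_participants Cohort size.
#' @param agent `"agent_config"` template shared by the cohort.
#' @param epsilon Evidence regularizer used when answering.
#' @param seed Optional master seed; participants derive child seeds, so the
#'   same master seed reproduces the full cohort.
#' @param betas Optional numeric vector (length `n_participants`) of
#'   per-participant sensitivities overriding `agent$beta`, or a matrix with
#'   one column per task (within-subject designs) for task-specific betas.
#' @return List of participant datasets, each a list `id, machine, tasks,
#'   log, model, bank, responses (question_id, choice, task, form), preview,
#'   meta`.
#' @export
simulate_cohort <- function(machine, design, n_participants, agent,
                            epsilon = 0.1, seed = NULL, betas = NULL) {
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1, n_participants)
  tasks_all <- TASKS
  within <- isTRUE(design$within)
  if (!within) {
    pool <- if (is.null(design$tasks)) tasks_all else design$tasks
    assigned <- sample(rep(pool, length.out = n_participants))
  }
  replace <- isTRUE(design$replace)
  lapply(seq_len(n_participants), function(i) {
    set.seed(child_seeds[i])
    learn <- simulate_learning(machine, design$learning_trials)
    model <- if (agent$model_source == "true_machine") machine else learn$model
    my_tasks <- if (within) sample(tasks_all) else assigned[i]
    beta_i <- function(task_idx) {
      if (is.null(betas)) return(agent$beta)
      if (is.matrix(betas)) return(betas[i, task_idx])
      betas[i]
    }
    banks <- list(); resps <- list()
    next_id <- 1L
    for (ti in seq_along(my_tasks)) {
      task <- my_tasks[ti]
      bank <- generate_test_block(machine, task, design$n_visible,
                                  design$n_hidden, order = design$order,
                                  replace = replace, epsilon = epsilon,
                                  id_start = next_id)
      next_id <- next_id + nrow(bank)
      r <- answer_bank(agent, bank, model, epsilon,
                       beta = beta_i(match(task, tasks_all)))
      r$task <- task
      r$form <- bank$form[match(r$question_id, bank$id)]
      banks[[ti]] <- bank; resps[[ti]] <- r
    }
    bank <- do.call(rbind, banks)
    attr(bank, "machine") <- machine$name
    preview <- NULL
    if (!is.null(design$preview) && length(design$preview) > 0) {
      # preview questions: extra visible questions recorded for format
      # fidelity only; they do not alter the agent or its model
      pb <- generate_questions(machine, my_tasks[1], "visible",
                               length(design$preview), replace = TRUE,
                               epsilon = epsilon, id_start = 9000L)
      pr <- answer_bank(agent, pb, model, epsilon)
      preview <- list(trials = design$preview, bank = pb, responses = pr)
    }
    list(id = i, machine = machine$name, tasks = my_tasks, log = learn$log,
         model = learn$model, bank = bank, responses = do.call(rbind, resps),
         preview = preview,
         meta = list(seed = child_seeds[i], agent = agent))
  })
}

#' Write a participant dataset to a directory
#'
#' Layout: `participants/<id>/log.csv`, `model.json`, `responses.csv`
#' (`question_id,choice`), `questions.jsonl`, `meta.json`.
#'
#' @param dataset One element of a [simulate_cohort()] result.
#' @param dir Root output directory.
#' @return The participant directory path, invisibly.
#' @export
write_participant_dataset <- function(dataset, dir) {
  pdir <- file.path(dir, "participants", dataset$id)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  write_interaction_log(dataset$log, file.path(pdir, "log.csv"))
  write_fsm(dataset$model, file.path(pdir, "model.json"))
  utils::write.csv(dataset$responses[, c("question_id", "choice")],
                   file.path(pdir, "responses.csv"), row.names = FALSE,
                   quote = FALSE)
  write_question_bank(dataset$bank, file.path(pdir, "questions.jsonl"))
  jsonlite::write_json(list(id = dataset$id, machine = dataset$machine,
                            tasks = dataset$tasks, seed = dataset$meta$seed,
                            agent = unclass(dataset$meta$agent)),
                       file.path(pdir, "meta.json"), auto_unbox = TRUE)
  invisible(pdir)
}
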