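#' Regularized log-evidence between two option quantities
#'
#' `R = log((max(p1, p2) + epsilon) / (min(p1, p2) + epsilon))` (natural
#' logarithm). `R` is 0 when the options are indistinguishable and grows with
#' the ratio of the larger to the smaller quantity; the regularizer keeps it
#' finite when the smaller quantity is 0 (at the defaults, probabilities
#' (1, 0) give `log(1.1/0.1) = 2.398`, the maximum attainable value).
#'
#' @param p1,p2 Nonnegative option quantities (vectorized).
#' @param epsilon Regularizer (> 0), default 0.1.
#' @return Nonnegative evidence value(s), in nats.
#' @export
evidence_R <- function(p1, p2, epsilon = 0.1) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  log((pmax(p1, p2) + epsilon) / (pmin(p1, p2) + epsilon))
}

as_question <- function(question) {
  if (is.data.frame(question)) {
    if (nrow(question) != 1) stop("expected a single question row")
    as.list(question)
  } else question
}

model_kernel <- function(model) {
  if (is.null(model$kernel)) stop("model must carry a transition kernel")
  model$kernel
}

# Quantities of the two options per the normative rules (heuristic = FALSE)
# or the alternative-neglect rules (heuristic = TRUE; hidden forms only).
option_quantities <- function(q, model, heuristic = FALSE) {
  k <- model_kernel(model)
  states <- model$states
  ep <- parse_episode(q$episode, model)
  if (!identical(ep$task, q$task) || !identical(ep$form, q$form))
    stop("episode '", q$episode, "' does not match the declared task/form")
  opts <- c(q$option1, q$option2)
  # greedy intermediate-state set: argmax_k P(k | s, u), ties kept
  greedy <- function(s, u) {
    p <- k[s, u, ]
    states[p >= max(p) - 1e-12]
  }
  # path quantity for (start, first input u, second input w, endpoint target):
  # normative marginalizes over the intermediate state; AN averages over the
  # tied greedy states g of P(target | g, w) * P(g | s, u).
  hidden_path <- function(s, u, w, target) {
    if (heuristic) {
      g <- greedy(s, u)
      mean(k[s, u, g] * k[cbind(g, w, target)])
    } else {
      sum(k[s, u, ] * k[, w, target])
    }
  }
  if (q$task == "prediction") {
    if (q$form == "visible") {
      v <- k[ep$mid, ep$input2, opts]
    } else {
      v <- vapply(opts, function(o)
        hidden_path(ep$start, ep$input1, ep$input2, o), 0)
    }
  } else if (q$task == "control") {
    if (q$form == "visible") {
      v <- k[ep$mid, opts, ep$final]
    } else {
      v <- vapply(opts, function(o) {
        if (nchar(o) != 2) stop("hidden control options must be input pairs")
        hidden_path(ep$start, substr(o, 1, 1), substr(o, 2, 2), ep$final)
      }, 0)
    }
  } else { # explanation: counterfactual input flips, intermediate state
    # held fixed when visible, marginalized (or greedy) when hidden. The
    # quantity credited to an input is the path probability when the OTHER
    # input is flipped: the cause is the input whose own flip would most
    # change the outcome, i.e. whose rival's flip leaves it most intact.
    j1 <- flip_input(model, ep$input1)
    j2 <- flip_input(model, ep$input2)
    if (q$form == "visible") {
      v <- c(input1 = k[ep$mid, j2, ep$final] * k[ep$start, ep$input1, ep$mid],
             input2 = k[ep$mid, ep$input2, ep$final] * k[ep$start, j1, ep$mid])
    } else {
      v <- c(input1 = hidden_path(ep$start, ep$input1, j2, ep$final),
             input2 = hidden_path(ep$start, j1, ep$input2, ep$final))
    }
    v <- v[opts]
  }
  v <- as.numeric(v)
  names(v) <- opts
  v
}

scores_from_values <- function(q, v, answer_model, epsilon) {
  favored <- if (abs(v[1] - v[2]) < 1e-12) "TIE" else names(v)[which.max(v)]
  list(question_id = q$id, task = q$task, form = q$form,
       answer_model = answer_model,
       option_values = v, favored = unname(favored),
       R = unname(evidence_R(v[1], v[2], epsilon)))
}

#' Score a question under the normative (Bayesian) answer rule
#'
#' Computes the two options' quantities under the supplied probability model
#' (the true machine or a fitted mental model), the favored option, and the
#' evidence `R`. Prediction and control use next-state probabilities, with
#' hidden forms marginalizing over the unobserved intermediate state;
#' explanation compares the two counterfactual path products obtained by
#' flipping each input in turn (the cause is the input whose flip yields the
#' smaller product).
#'
#' @param question A one-row question data frame (see
#'   [generate_questions()]) or an equivalent list.
#' @param model An `"fsm"` or `"mental_model"` object.
#' @param epsilon Evidence regularizer, default 0.1.
#' @return A list: `question_id`, `task`, `form`, `answer_model`,
#'   `option_values` (named after the options), `favored` (an option or
#'   `"TIE"`), and `R`.
#' @export
normative_scores <- function(question, model, epsilon = 0.1) {
  q <- as_question(question)
  scores_from_values(q, option_quantities(q, model, heuristic = FALSE),
                     "normative", epsilon)
}

#' Score a question under the alternative-neglect heuristic
#'
#' For hidden forms, the sum over possible intermediate states is replaced by
#' the single most likely one (the greedy path); when several intermediate
#' states tie for most likely, the heuristic quantity is averaged over the
#' tied states. Visible forms involve no hidden state, so the heuristic
#' coincides with the normative rule and [normative_scores()] is returned
#' (with `answer_model = "alternative_neglect"`).
#'
#' @inheritParams normative_scores
#' @return As [normative_scores()].
#' @export
an_scores <- function(question, model, epsilon = 0.1) {
  q <- as_question(question)
  heur <- q$form == "hidden"
  scores_from_values(q, option_quantities(q, model, heuristic = heur),
                     "alternative_neglect", epsilon)
}

#' Oracle scoring by explicit path enumeration
#'
#' Independent implementation used as a test oracle: option quantities are
#' obtained by enumerating every assignment of the hidden intermediate state
#' one path at a time and summing the path probabilities with plain loops
#' (no marginalization shortcuts). Intended for small machines only.
#'
#' @inheritParams normative_scores
#' @return As [normative_scores()] (`answer_model = "brute_force"`).
#' @export
brute_force_scores <- function(question, model, epsilon = 0.1) {
  q <- as_question(question)
  k <- model_kernel(model)
  states <- model$states
  if (length(states) > 8) stop("brute-force oracle is limited to <= 8 states")
  ep <- parse_episode(q$episode, model)
  opts <- c(q$option1, q$option2)
  # total probability, over all intermediate paths, of the two-step episode
  # (start --u--> mid --w--> target); mid fixed when visible.
  path_sum <- function(s, u, w, target, mid = NULL) {
    mids <- if (is.null(mid)) states else mid
    total <- 0
    for (g in mids) total <- total + k[s, u, g] * k[g, w, target]
    total
  }
  v <- numeric(2)
  for (j in 1:2) {
    o <- opts[j]
    if (q$task == "prediction") {
      v[j] <- if (q$form == "visible")
        path_sum(ep$start, ep$input1, ep$input2, o, mid = ep$mid) /
          k[ep$start, ep$input1, ep$mid]
      else path_sum(ep$start, ep$input1, ep$input2, o)
    } else if (q$task == "control") {
      v[j] <- if (q$form == "visible")
        path_sum(ep$start, ep$input1, o, ep$final, mid = ep$mid) /
          k[ep$start, ep$input1, ep$mid]
      else path_sum(ep$start, substr(o, 1, 1), substr(o, 2, 2), ep$final)
    } else {
      j1 <- flip_input(model, ep$input1)
      j2 <- flip_input(model, ep$input2)
      mid <- if (q$form == "visible") ep$mid else NULL
      v[j] <- if (o == "input1") path_sum(ep$start, ep$input1, j2, ep$final, mid)
              else path_sum(ep$start, j1, ep$input2, ep$final, mid)
    }
  }
  names(v) <- opts
  out <- scores_from_values(q, v, "brute_force", epsilon)
  out
}

#' Score a whole question bank
#'
#' @param bank Question bank data frame.
#' @param model `"fsm"` or `"mental_model"`.
#' @param answer_model `"normative"` or `"alternative_neglect"`.
#' @param epsilon Evidence regularizer.
#' @return Data frame `question_id, task, form, answer_model, value_opt1,
#'   value_opt2, favored, R` (one row per question; values in display order
#'   of the options).
#' @export
score_questions <- function(bank, model,
                            answer_model = c("normative",
                                             "alternative_neglect"),
                            epsilon = 0.1) {
  answer_model <- match.arg(answer_model)
  scorer <- if (answer_model == "normative") normative_scores else an_scores
  rows <- lapply(seq_len(nrow(bank)), function(i) {
    s <- scorer(bank[i, ], model, epsilon)
    data.frame(question_id = s$question_id, task = s$task, form = s$form,
               answer_model = s$answer_model,
               value_opt1 = s$option_values[1], value_opt2 = s$option_values[2],
               favored = s$favored, R = s$R, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname score_questions
#' @param scores A [score_questions()] result.
#' @param path Output TSV path.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
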