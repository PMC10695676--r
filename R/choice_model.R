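#' Probability of choosing the favored option at evidence R
#'
#' The noisy translation from implicit evidence to an explicit choice:
#' `p_C = exp(beta * R) / (exp(beta * R) + exp(-beta * R))`, computed as the
#' logistic of `2 * beta * R` for numerical stability. `beta = 0` (or
#' `R = 0`) gives random choice at 0.5; large `beta` makes the favored
#' option near-certain. Note that as a logistic-regression coefficient on
#' predictor `R` without intercept, the fitted slope equals `2 * beta`.
#'
#' @param beta Sensitivity parameter (any sign).
#' @param R Evidence value(s), `R >= 0` for scored questions (any sign
#'   accepted; `p_C(beta, -R) = 1 - p_C(beta, R)`).
#' @return Choice probability in (0, 1), vectorized over `R`.
#' @export
choice_prob <- function(beta, R) {
  stats::plogis(2 * beta * R)
}

#' Build evidence records linking responses to an answer model
#'
#' For each response, scores the corresponding question with the given
#' probability model and answer rule, and records the evidence `R` together
#' with whether the response matched the favored option. Questions whose two
#' options tie under the model carry `R = 0` and `correct = NA`; they are
#' retained (each contributes log 0.5 to any likelihood, keeping
#' log-likelihoods comparable across answer models on the same responses).
#'
#' @param responses Data frame with columns `question_id`, `choice` (and
#'   optionally `participant`).
#' @param bank Question bank containing every referenced question.
#' @param model `"fsm"` or `"mental_model"` used for scoring.
#' @param answer_model `"normative"` or `"alternative_neglect"`.
#' @param epsilon Evidence regularizer.
#' @return Data frame `participant (if present), question_id, task, form,
#'   answer_model, R, correct`.
#' @export
build_evidence_records <- function(responses, bank,
                                   model,
                                   answer_model = c("normative",
                                                    "alternative_neglect"),
                                   epsilon = 0.1) {
  answer_model <- match.arg(answer_model)
  if (!all(responses$question_id %in% bank$id))
    stop("responses reference question ids absent from the bank")
  scores <- score_questions(bank, model, answer_model, epsilon)
  m <- match(responses$question_id, scores$question_id)
  favored <- scores$favored[m]
  out <- data.frame(question_id = responses$question_id,
                    task = scores$task[m], form = scores$form[m],
                    answer_model = answer_model, R = scores$R[m],
                    correct = ifelse(favored == "TIE", NA_integer_,
                                     as.integer(responses$choice == favored)),
                    stringsAsFactors = FALSE)
  if (!is.null(responses$participant))
    out <- cbind(participant = responses$participant, out)
  out
}

beta_loglik <- function(beta, R, correct) {
  p <- choice_prob(beta, R)
  sum(ifelse(correct == 1, log(p), log1p(-p)))
}

#' Maximum-likelihood estimate of the sensitivity beta
#'
#' Fits the one-parameter choice model by maximizing
#' `sum(correct * log p_C + (1 - correct) * log(1 - p_C))` with
#' `p_C = logistic(2 * beta * R)` — equivalently, a logistic regression of
#' `correct` on `R` without intercept, whose coefficient is `2 * beta`. The
#' problem is concave in `beta`; Newton iterations are run to gradient
#' `< 1e-8`. Records with `R = 0` (including ties, `correct = NA`) are
#' retained as constant log(0.5) terms. Under complete separation (all
#' informative records correct, or all incorrect) the estimate diverges and
#' is capped at `|beta| = cap` with `separation = TRUE`.
#'
#' @param records Evidence-record data frame with columns `R` and `correct`
#'   (see [build_evidence_records()]).
#' @param cap Bound on `|beta|` (default 20).
#' @param tol Gradient convergence tolerance.
#' @return A list of class `"beta_fit"`: `beta`, `beta_logistic` (`= 2 beta`),
#'   `se` (observed information), `loglik`, `n`, `n_informative`,
#'   `converged`, `separation`.
#' @export
fit_beta <- function(records, cap = 20, tol = 1e-8) {
  stopifnot(nrow(records) >= 1)
  R <- records$R; correct <- records$correct
  info <- which(R > 0 & !is.na(correct))
  n0 <- nrow(records) - length(info)
  if (length(info) == 0)
    stop("degenerate design: every record has R = 0; the likelihood is flat in beta")
  r <- R[info]; c <- correct[info]
  separation <- all(c == 1) || all(c == 0)
  beta <- 0; converged <- FALSE
  if (separation) {
    beta <- if (all(c == 1)) cap else -cap
  } else {
    for (iter in 1:200) {
      p <- choice_prob(beta, r)
      g <- sum(2 * r * (c - p))
      h <- -sum(4 * r^2 * p * (1 - p))
      if (abs(g) < tol) { converged <- TRUE; break }
      beta <- beta - g / h
      if (abs(beta) > cap) { beta <- sign(beta) * cap; separation <- TRUE; break }
    }
  }
  p <- choice_prob(beta, r)
  h <- -sum(4 * r^2 * p * (1 - p))
  ll <- beta_loglik(beta, r, c) + n0 * log(0.5)
  structure(list(beta = beta, beta_logistic = 2 * beta,
                 se = if (h < 0) sqrt(-1 / h) else NA_real_,
                 loglik = ll, n = nrow(records),
                 n_informative = length(info),
                 converged = converged || separation,
                 separation = separation),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("<beta_fit: beta = %.4f (se %.4f), loglik = %.3f, n = %d%s>\n",
              x$beta, x$se, x$loglik, x$n,
              if (x$separation) ", separated (capped)" else ""))
  invisible(x)
}

#' Likelihood-ratio comparison of the normative and alternative-neglect rules
#'
#' Builds evidence records for the same responses under both answer models,
#' fits the sensitivity `beta` for each, and reports the favored model (the
#' one with the larger maximized log-likelihood) together with
#' `delta_L = loglik(favored) - loglik(other) >= 0`. Two tail probabilities
#' against chi-square(1) are reported: one for the conventional deviance
#' `2 * delta_L`, and one treating `delta_L` itself as the statistic (the
#' convention matching published Delta-L/p pairings for this comparison).
#' The two answer rules are not nested, so both p-values are descriptive.
#'
#' @inheritParams build_evidence_records
#' @param model Probability model used for both scorings.
#' @return List of class `"model_comparison"`: `favored`, `delta_L`,
#'   `statistic` (`2 delta_L`), `p_chi2_2dL`, `p_chi2_dL`,
#'   `loglik_normative`, `loglik_an`, the two `"beta_fit"` objects, `n`.
#' @export
compare_answer_models <- function(responses, bank, model, epsilon = 0.1) {
  rec_norm <- build_evidence_records(responses, bank, model, "normative",
                                     epsilon)
  rec_an <- build_evidence_records(responses, bank, model,
                                   "alternative_neglect", epsilon)
  fit_norm <- fit_beta(rec_norm)
  fit_an <- fit_beta(rec_an)
  dl_signed <- fit_an$loglik - fit_norm$loglik
  favored <- if (dl_signed >= 0) "alternative_neglect" else "normative"
  delta_L <- abs(dl_signed)
  structure(list(favored = favored, delta_L = delta_L,
                 delta_L_signed = dl_signed,
                 statistic = 2 * delta_L,
                 p_chi2_2dL = stats::pchisq(2 * delta_L, df = 1,
                                            lower.tail = FALSE),
                 p_chi2_dL = stats::pchisq(delta_L, df = 1,
                                           lower.tail = FALSE),
                 loglik_normative = fit_norm$loglik,
                 loglik_an = fit_an$loglik,
                 fit_normative = fit_norm, fit_an = fit_an,
                 n = nrow(responses)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison: favored = %s, delta_L = %.3f (p[chi2, 2dL] = %.4g, p[chi2, dL] = %.4g), n = %d>\n",
              x$favored, x$delta_L, x$p_chi2_2dL, x$p_chi2_dL, x$n))
  invisible(x)
}

#' Recency bias in explanation responses
#'
#' Proportion of explanation responses choosing the most recent input
#' (`input2`), per participant, with a one-sample two-sided t test of the
#' group mean against 0.5.
#'
#' @param responses Data frame with `participant`, `question_id`, `choice`
#'   (`"input1"` / `"input2"`).
#' @param bank Question bank; all referenced questions must be explanation
#'   tasks.
#' @return List: `per_participant` (data frame `participant, prop_recent,
#'   n`), `mean`, `sd`, `t`, `df`, `p`.
#' @export
recency_rate <- function(responses, bank) {
  tasks <- bank$task[match(responses$question_id, bank$id)]
  if (any(is.na(tasks)) || any(tasks != "explanation"))
    stop("recency_rate applies to explanation-task responses only")
  pid <- if (is.null(responses$participant)) rep(1L, nrow(responses))
         else responses$participant
  recent <- as.integer(responses$choice == "input2")
  agg <- stats::aggregate(recent, by = list(participant = pid),
                          FUN = function(v) c(mean(v), length(v)))
  per <- data.frame(participant = agg$participant,
                    prop_recent = agg$x[, 1], n = agg$x[, 2])
  if (nrow(per) > 1 && stats::sd(per$prop_recent) > 0) {
    tt <- stats::t.test(per$prop_recent, mu = 0.5)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  } else {
    t_stat <- NA_real_; df <- NA_real_; p <- NA_real_
  }
  list(per_participant = per, mean = mean(per$prop_recent),
       sd = stats::sd(per$prop_recent), t = t_stat, df = df, p = p)
}

#' Accuracy against a participant's own mental model
#'
#' Fraction of a participant's responses that match the option favored by
#' their own fitted mental model under the chosen answer rule. Questions on
#' which the participant's model ties (favored `"TIE"`) are excluded from
#' the denominator.
#'
#' @param responses Data frame `question_id, choice`.
#' @param bank The participant's question bank.
#' @param model The participant's `"mental_model"`.
#' @param answer_model `"normative"` or `"alternative_neglect"`.
#' @param epsilon Evidence regularizer.
#' @return List: `accuracy` (NA if every question tied), `n_scored`,
#'   `n_tie`.
#' @export
mm_accuracy <- function(responses, bank, model,
                        answer_model = c("normative", "alternative_neglect"),
                        epsilon = 0.1) {
  answer_model <- match.arg(answer_model)
  rec <- build_evidence_records(responses, bank, model, answer_model, epsilon)
  scored <- rec$correct[!is.na(rec$correct)]
  list(accuracy = if (length(scored) > 0) mean(scored) else NA_real_,
       n_scored = length(scored), n_tie = sum(is.na(rec$correct)))
}

#' Write fitted betas / model comparisons as TSV
#'
#' @param fits Named list of `"beta_fit"` objects (names become the `group`
#'   column), or a list of `"model_comparison"` objects for
#'   [write_comparison_tsv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits_tsv <- function(fits, path) {
  rows <- lapply(names(fits), function(g) {
    f <- fits[[g]]
    data.frame(group = g, beta = f$beta, se = f$se, loglik = f$loglik,
               n = f$n, converged = f$converged, separation = f$separation)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fits_tsv
#' @export
write_comparison_tsv <- function(fits, path) {
  rows <- lapply(names(fits), function(g) {
    cmp <- fits[[g]]
    data.frame(group = g, favored = cmp$favored, delta_L = cmp$delta_L,
               statistic = cmp$statistic, p_chi2_2dL = cmp$p_chi2_2dL,
               p_chi2_dL = cmp$p_chi2_dL, n = cmp$n)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
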