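#' Fit a frequency-based mental model from an interaction log
#'
#' The estimated transition probability `P(i | j, k)` is the number of times
#' state `i` was observed to follow state `j` under input `k`, divided by the
#' number of times state `j` was seen under input `k`. A `(state, input)`
#' pair never observed in the log receives the uniform fallback: equal
#' probability over all of the machine's states. No smoothing is applied to
#' observed rows; the evidence regularizer enters only at the scoring stage.
#'
#' @param log Interaction log data frame (`trial, state, input, next_state`);
#'   an empty log yields an all-uniform model.
#' @param machine An `"fsm"` supplying the state/input alphabets (its
#'   probabilities are not used).
#' @param validate Check the log's chaining invariant (default `TRUE`). The
#'   estimator itself depends only on the multiset of
#'   `(state, input, next_state)` triples, not on trial order.
#' @return An object of class `c("mental_model", "fsm")`: `kernel` holds the
#'   estimated probabilities, `counts` the observation counts
#'   `[state, input, next_state]`, and `n_obs` the per-row totals. Usable
#'   anywhere an `"fsm"` is accepted by the scoring functions.
#' @export
fit_mental_model <- function(log, machine, validate = TRUE) {
  states <- machine$states; inputs <- machine$inputs
  counts <- array(0L, dim = c(length(states), length(inputs), length(states)),
                  dimnames = list(states, inputs, states))
  if (nrow(log) > 0) {
    if (validate) validate_interaction_log(log, machine)
    if (!all(c(log$state, log$next_state) %in% states) ||
        !all(log$input %in% inputs))
      stop("log contains symbols outside the machine's alphabets")
    tab <- table(factor(log$state, states), factor(log$input, inputs),
                 factor(log$next_state, states))
    counts[] <- as.integer(tab)
  }
  build_mental_model(counts, machine)
}

build_mental_model <- function(counts, machine) {
  states <- machine$states
  n_obs <- apply(counts, c(1, 2), sum)
  kernel <- counts / ifelse(
    array(n_obs > 0, dim = dim(counts)), array(n_obs, dim = dim(counts)), 1)
  unif <- 1 / length(states)
  for (s in states) for (u in machine$inputs) {
    if (n_obs[s, u] == 0) kernel[s, u, ] <- unif
  }
  structure(list(name = paste0("mm:", machine$name), states = states,
                 inputs = machine$inputs, kernel = kernel, counts = counts,
                 n_obs = n_obs),
            class = c("mental_model", "fsm"))
}

#' Add observed transitions to a fitted mental model
#'
#' @param model A `"mental_model"`.
#' @param triples Data frame with columns `state`, `input`, `next_state`
#'   (one row per additional observation).
#' @return The updated model (counts incremented, probabilities refit).
#' @export
update_mental_model <- function(model, triples) {
  counts <- model$counts
  for (i in seq_len(nrow(triples))) {
    s <- triples$state[i]; u <- triples$input[i]; nx <- triples$next_state[i]
    counts[s, u, nx] <- counts[s, u, nx] + 1L
  }
  build_mental_model(counts, model)
}

#' Maximum absolute deviation between a mental model and a machine
#'
#' Convergence diagnostic: the largest difference, over all
#' `(state, input, next_state)` cells, between the model's estimated
#' probability and the machine's true probability.
#'
#' @param model A `"mental_model"` (or any `"fsm"`).
#' @param machine The reference `"fsm"`.
#' @return A single nonnegative number.
#' @export
model_distance <- function(model, machine) {
  if (!identical(model$states, machine$states) ||
      !identical(model$inputs, machine$inputs))
    stop("model and machine must share the same state/input alphabets")
  max(abs(model$kernel - machine$kernel))
}

#' @export
print.mental_model <- function(x, ...) {
  cat(sprintf("<mental_model '%s': %d observations over %d/%d (state,input) rows>\n",
              x$name, sum(x$n_obs), sum(x$n_obs > 0), length(x$n_obs)))
  invisible(x)
}
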