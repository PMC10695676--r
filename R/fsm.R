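#' Construct a probabilistic finite-state machine
#'
#' A probabilistic finite-state machine (FSM) is defined by an ordered set of
#' state labels, an ordered set of input symbols, and a transition kernel
#' giving, for every (state, input) pair, a probability distribution over next
#' states: `P(i | j, k)` for next state `i`, current state `j`, input `k`.
#'
#' @param name Character label for the machine.
#' @param states Character vector of state labels (at least 2, unique).
#' @param inputs Character vector of input symbols (at least 2, unique).
#' @param kernel 3-dimensional numeric array with dimensions
#'   `[state, input, next_state]`; each `kernel[j, k, ]` row must be a
#'   probability distribution. Dimnames, if present, must match `states` and
#'   `inputs`; they are set from them otherwise.
#' @return An object of class `"fsm"`: a list with elements `name`, `states`,
#'   `inputs` and `kernel`.
#' @seealso [read_fsm()], [random_fsm()], [easy_machine()], [hard_machine()]
#' @examples
#' m <- fsm("cycle", c("A", "B"), c("a", "b"),
#'          kernel_from_rows(list(
#'            A = list(a = c(B = 1), b = c(B = 1)),
#'            B = list(a = c(A = 1), b = c(A = 1)))))
#' transition_census(m)
#' @export
fsm <- function(name, states, inputs, kernel) {
  states <- as.character(states)
  inputs <- as.character(inputs)
  dimnames(kernel) <- list(states, inputs, states)
  m <- structure(list(name = name, states = states, inputs = inputs,
                      kernel = kernel),
                 class = "fsm")
  validate_fsm(m)
  m
}

#' Build a transition kernel array from nested row lists
#'
#' Convenience constructor turning `list(state = list(input = c(next = p)))`
#' into the 3-d kernel array used by [fsm()]. Missing next states get
#' probability 0; missing (state, input) rows are an error.
#'
#' @param rows Nested list `state -> input -> named numeric vector`.
#' @param states,inputs Optional explicit alphabets; derived from `rows`
#'   otherwise (next-state names must then appear as states).
#' @return Numeric array `[state, input, next_state]`.
#' @export
kernel_from_rows <- function(rows, states = NULL, inputs = NULL) {
  if (is.null(states)) states <- names(rows)
  if (is.null(inputs)) inputs <- names(rows[[1]])
  k <- array(0, dim = c(length(states), length(inputs), length(states)),
             dimnames = list(states, inputs, states))
  for (s in states) {
    if (is.null(rows[[s]])) stop("missing transition rows for state '", s, "'")
    for (u in inputs) {
      row <- rows[[s]][[u]]
      if (is.null(row)) stop("missing transition row for (", s, ", ", u, ")")
      bad <- setdiff(names(row), states)
      if (length(bad) > 0)
        stop("unknown next state(s) in row (", s, ", ", u, "): ",
             paste(bad, collapse = ", "))
      k[s, u, names(row)] <- row
    }
  }
  k
}

#' Validate a finite-state machine object
#'
#' Checks the structural invariants: at least two states and two inputs, all
#' probabilities in `[0, 1]`, and every `(state, input)` row summing to 1
#' within `tol`.
#'
#' @param machine An `"fsm"` object.
#' @param tol Tolerance on row sums (default `1e-9`).
#' @return `machine`, invisibly; errors describe the offending row.
#' @export
validate_fsm <- function(machine, tol = 1e-9) {
  stopifnot(is.list(machine), !is.null(machine$kernel))
  states <- machine$states
  inputs <- machine$inputs
  if (length(states) < 2) stop("machine must have at least 2 states")
  if (length(inputs) < 2) stop("machine must have at least 2 inputs")
  if (anyDuplicated(states)) stop("duplicate state labels")
  if (anyDuplicated(inputs)) stop("duplicate input symbols")
  k <- machine$kernel
  if (!identical(dim(k), c(length(states), length(inputs), length(states))))
    stop("kernel dimensions do not match the state/input alphabets")
  if (any(k < -tol) || any(k > 1 + tol))
    stop("transition probabilities must lie in [0, 1]")
  sums <- apply(k, c(1, 2), sum)
  off <- which(abs(sums - 1) > tol, arr.ind = TRUE)
  if (nrow(off) > 0) {
    stop(sprintf("transition row (%s, %s) sums to %.12g, not 1",
                 states[off[1, 1]], inputs[off[1, 2]],
                 sums[off[1, 1], off[1, 2]]))
  }
  invisible(machine)
}

#' @export
print.fsm <- function(x, ...) {
  cen <- transition_census(x)
  cat(sprintf("<fsm '%s': %d states (%s), %d inputs (%s)>\n", x$name,
              length(x$states), paste(x$states, collapse = ","),
              length(x$inputs), paste(x$inputs, collapse = ",")))
  cat(sprintf("  %d probabilistic / %d deterministic rows; %d predetermined state(s)\n",
              cen$n_probabilistic, cen$n_deterministic, cen$n_predetermined))
  invisible(x)
}

#' Read a machine specification from JSON
#'
#' The document must contain `name`, `states`, `inputs`, and `transitions`
#' (a nested map `state -> input -> {next_state: probability}`). The result
#' is validated: every row must be present and sum to 1.
#'
#' @param path Path to a JSON machine spec.
#' @return A validated `"fsm"` object.
#' @export
read_fsm <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("name", "states", "inputs", "transitions")) {
    if (is.null(doc[[field]])) stop("machine spec is missing field '", field, "'")
  }
  states <- vapply(doc$states, as.character, "")
  inputs <- vapply(doc$inputs, as.character, "")
  rows <- lapply(states, function(s) {
    srow <- doc$transitions[[s]]
    if (is.null(srow)) stop("missing transition rows for state '", s, "'")
    out <- lapply(inputs, function(u) {
      urow <- srow[[u]]
      if (is.null(urow)) stop("missing transition row for (", s, ", ", u, ")")
      unlist(urow)
    })
    names(out) <- inputs
    out
  })
  names(rows) <- states
  fsm(doc$name, states, inputs, kernel_from_rows(rows, states, inputs))
}

#' Write a machine (or fitted mental model) to the JSON spec format
#'
#' @param machine An `"fsm"` object. Mental models are written with their
#'   estimated probabilities as `transitions` plus a `counts` block, so a
#'   fitted model round-trips into any place a machine is accepted.
#' @param path Output path.
#' @param digits Passed to the JSON writer (default `NA`: full precision).
#' @return `path`, invisibly.
#' @export
write_fsm <- function(machine, path, digits = NA) {
  doc <- list(name = machine$name, states = machine$states,
              inputs = machine$inputs,
              transitions = kernel_to_rows(machine$kernel, drop_zero = TRUE))
  if (inherits(machine, "mental_model")) {
    doc$counts <- kernel_to_rows(machine$counts, drop_zero = TRUE)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = digits)
  invisible(path)
}

kernel_to_rows <- function(k, drop_zero = FALSE) {
  states <- dimnames(k)[[1]]
  inputs <- dimnames(k)[[2]]
  out <- lapply(states, function(s) {
    row <- lapply(inputs, function(u) {
      v <- k[s, u, ]
      if (drop_zero) v <- v[v != 0]
      as.list(v)
    })
    names(row) <- inputs
    row
  })
  names(out) <- states
  out
}

#' Classify transition rows of a machine
#'
#' Each `(state, input)` row is *deterministic* if it is one-hot and
#' *probabilistic* otherwise. A state is *predetermined* if all of its input
#' rows share the same distribution (the next state does not depend on the
#' input).
#'
#' @param machine An `"fsm"` object.
#' @return A list with a per-row data frame `rows` (columns `state`, `input`,
#'   `type`) and the counts `n_probabilistic`, `n_deterministic`,
#'   `n_predetermined` (number of predetermined states).
#' @export
transition_census <- function(machine) {
  k <- machine$kernel
  grid <- expand.grid(state = machine$states, input = machine$inputs,
                      stringsAsFactors = FALSE)
  grid$type <- vapply(seq_len(nrow(grid)), function(r) {
    row <- k[grid$state[r], grid$input[r], ]
    if (any(abs(row - 1) < 1e-12)) "deterministic" else "probabilistic"
  }, "")
  predet <- vapply(machine$states, function(s) {
    rows <- k[s, , , drop = FALSE]
    all(apply(rows, 3, function(col) max(col) - min(col) < 1e-12))
  }, TRUE)
  list(rows = grid,
       n_probabilistic = sum(grid$type == "probabilistic"),
       n_deterministic = sum(grid$type == "deterministic"),
       n_predetermined = sum(predet),
       predetermined_states = machine$states[predet])
}

#' Draw next state(s) from a machine
#'
#' @param machine An `"fsm"` object.
#' @param state Current state label.
#' @param input Input symbol.
#' @param n Number of independent draws (default 1).
#' @return Character vector of `n` next-state labels, drawn from
#'   `P(. | state, input)` using the current RNG state.
#' @export
fsm_step <- function(machine, state, input, n = 1) {
  state <- as.character(state)
  input <- as.character(input)
  if (!state %in% machine$states) stop("unknown state '", state, "'")
  if (!input %in% machine$inputs) stop("unknown input '", input, "'")
  p <- machine$kernel[state, input, ]
  if (length(sup <- which(p > 0)) == 1L) return(rep(machine$states[sup], n))
  sample(machine$states, n, replace = TRUE, prob = p)
}

#' Simulate a free-interaction session
#'
#' The machine starts in a state drawn uniformly at random (unless `start` is
#' given); at each trial the policy chooses an input given the current state,
#' the machine transitions, and the `(trial, state, input, next_state)` record
#' is logged. This mirrors a free-exploration learning phase in which a
#' participant feeds inputs to the system and observes its responses.
#'
#' @param machine An `"fsm"` object.
#' @param n_trials Number of interaction trials (>= 1).
#' @param policy Function `(state, machine) -> input symbol`; the default
#'   chooses uniformly among the machine's inputs.
#' @param start Optional start state label; uniform over states if `NULL`.
#' @param seed Optional integer seed.
#' @return An interaction log: `data.frame(trial, state, input, next_state)`
#'   with attribute `"machine"` carrying the machine name.
#' @export
simulate_session <- function(machine, n_trials, policy = uniform_policy,
                             start = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_trials >= 1)
  s <- if (is.null(start)) sample(machine$states, 1) else as.character(start)
  if (!s %in% machine$states) stop("unknown start state '", s, "'")
  state <- character(n_trials); input <- character(n_trials)
  nxt <- character(n_trials)
  for (t in seq_len(n_trials)) {
    u <- policy(s, machine)
    s2 <- fsm_step(machine, s, u)
    state[t] <- s; input[t] <- u; nxt[t] <- s2
    s <- s2
  }
  log <- data.frame(trial = seq_len(n_trials), state = state, input = input,
                    next_state = nxt, stringsAsFactors = FALSE)
  attr(log, "machine") <- machine$name
  log
}

#' Uniform-random input policy
#'
#' @param state Current state (ignored).
#' @param machine The machine whose inputs are sampled.
#' @return One input symbol, uniformly at random.
#' @export
uniform_policy <- function(state, machine) {
  machine$inputs[sample.int(length(machine$inputs), 1)]
}

#' Read / write an interaction log as CSV
#'
#' CSV columns `trial,state,input,next_state`, header required. On read, the
#' chaining invariant (`next_state` of trial t equals `state` of trial t+1)
#' and, when a machine is supplied, alphabet membership are checked.
#'
#' @param path File path.
#' @param machine Optional `"fsm"` object to validate symbols against.
#' @return The log data frame (read), or `path` invisibly (write).
#' @export
read_interaction_log <- function(path, machine = NULL) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("integer", "character", "character",
                                        "character"))
  validate_interaction_log(log, machine)
  log
}

#' @rdname read_interaction_log
#' @param log An interaction log data frame.
#' @export
write_interaction_log <- function(log, path) {
  con <- file(path, open = "wb")  # binary mode forces LF line endings
  on.exit(close(con))
  utils::write.csv(log[, c("trial", "state", "input", "next_state")], con,
                   row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname read_interaction_log
#' @export
validate_interaction_log <- function(log, machine = NULL) {
  need <- c("trial", "state", "input", "next_state")
  if (!all(need %in% names(log))) stop("log must have columns ",
                                       paste(need, collapse = ", "))
  n <- nrow(log)
  if (n > 1 && !all(log$next_state[-n] == log$state[-1]))
    stop("log is not chained: next_state of trial t must equal state of trial t+1")
  if (!is.null(machine)) {
    if (!all(c(log$state, log$next_state) %in% machine$states))
      stop("log contains states outside the machine's alphabet")
    if (!all(log$input %in% machine$inputs))
      stop("log contains inputs outside the machine's alphabet")
  }
  invisible(log)
}

#' The two reference chatbot machines
#'
#' Four-state, two-input machines shipped as JSON fixtures. The *easy* machine
#' has two probabilistic and six deterministic transition rows (two
#' predetermined states); the *hard* machine has five probabilistic and three
#' deterministic rows (one predetermined state). From state 2 under input
#' `a`, both machines move to state 0 with probability 0.6 and to state 3
#' with probability 0.4. See the fixture JSON `comment` fields for which rows
#' are anchored by published values and which are synthetic reconstructions.
#'
#' @return A validated `"fsm"` object.
#' @export
easy_machine <- function() {
  read_fsm(system.file("extdata", "easy_machine.json", package = "fsmpec",
                       mustWork = TRUE))
}

#' @rdname easy_machine
#' @export
hard_machine <- function() {
  read_fsm(system.file("extdata", "hard_machine.json", package = "fsmpec",
                       mustWork = TRUE))
}

#' Generate a random strongly-connected machine
#'
#' Used for property tests. Rows designated probabilistic receive a Dirichlet
#' draw over a random support of at least two states; the rest are one-hot.
#' Machines are regenerated until every state is reachable from every state.
#'
#' @param n_states,n_inputs Alphabet sizes (>= 2).
#' @param n_probabilistic Number of non-one-hot rows
#'   (`0 <= n_probabilistic <= n_states * n_inputs`).
#' @param seed Optional integer seed.
#' @param max_tries Attempts before giving up on strong connectivity.
#' @return A validated `"fsm"` object with single-character state labels
#'   (`0,1,...`) and input symbols (`a,b,...`).
#' @export
random_fsm <- function(n_states, n_inputs, n_probabilistic, seed = NULL,
                       max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  if (n_states < 2 || n_inputs < 2) stop("need at least 2 states and 2 inputs")
  if (n_states > 10 || n_inputs > 26)
    stop("random_fsm supports at most 10 states and 26 inputs")
  if (n_probabilistic < 0 || n_probabilistic > n_states * n_inputs)
    stop("n_probabilistic must be between 0 and n_states * n_inputs")
  states <- as.character(seq_len(n_states) - 1L)
  inputs <- letters[seq_len(n_inputs)]
  for (try in seq_len(max_tries)) {
    k <- array(0, dim = c(n_states, n_inputs, n_states),
               dimnames = list(states, inputs, states))
    prob_rows <- sample.int(n_states * n_inputs, n_probabilistic)
    idx <- 0L
    for (s in seq_len(n_states)) for (u in seq_len(n_inputs)) {
      idx <- idx + 1L
      if (idx %in% prob_rows) {
        supp <- sample.int(n_states, sample(2:n_states, 1))
        w <- stats::rgamma(length(supp), 1)
        k[s, u, supp] <- w / sum(w)
      } else {
        k[s, u, sample.int(n_states, 1)] <- 1
      }
    }
    if (strongly_connected(k)) {
      return(fsm(sprintf("random-%ds%di", n_states, n_inputs),
                 states, inputs, k))
    }
  }
  stop("could not generate a strongly connected machine in ", max_tries,
       " tries")
}

strongly_connected <- function(kernel) {
  n <- dim(kernel)[1]
  adj <- apply(kernel > 0, c(1, 3), any)  # reachable in one step via any input
  reach <- adj | diag(n) > 0
  for (i in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  all(reach)
}
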