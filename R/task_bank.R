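#' @keywords internal
"_PACKAGE"

TASKS <- c("prediction", "explanation", "control")
FORMS <- c("visible", "hidden")

#' Render a test episode as its compact string form
#'
#' Episodes are two-input conversation snippets written as five single-character
#' tokens: start state, first input, intermediate state (`X` when hidden),
#' second input, and a final token that is a state (explanation, control goal)
#' or `?` (prediction query). Control queries replace the input slots with
#' `?`. Examples: `1a2b?` (visible prediction), `1aXb3` (hidden explanation),
#' `1a2?3` (visible control), `1?X?3` (hidden control).
#'
#' @param episode An episode list with fields `start`, `input1`, `mid`,
#'   `input2`, `final` (as produced by [parse_episode()]), or a one-row
#'   question data frame with an `episode` column (returned unchanged).
#' @return The episode string.
#' @export
render_episode <- function(episode) {
  if (is.data.frame(episode)) return(episode$episode[1])
  if (!is.null(episode$episode)) return(episode$episode)
  paste0(episode$start, episode$input1, episode$mid, episode$input2,
         episode$final)
}

#' Parse an episode string
#'
#' Inverse of [render_episode()]: `parse(render(e)) == e`. The task and form
#' are inferred from the marker positions; all labels are validated against
#' the machine's alphabets. Only machines whose state labels and input
#' symbols are single characters (and distinct from the markers `X` and `?`)
#' can be rendered in this grammar.
#'
#' @param text Episode string (5 characters).
#' @param machine An `"fsm"` object supplying the alphabets.
#' @return List with `start`, `input1`, `mid`, `input2`, `final`, `task`,
#'   `form`. Hidden slots hold `"X"`, query slots `"?"`.
#' @export
parse_episode <- function(text, machine) {
  check_grammar_alphabets(machine)
  if (!is.character(text) || length(text) != 1)
    stop("episode text must be a single string")
  if (nchar(text) != 5)
    stop("parse error at position ", nchar(text) + 1,
         ": episode must be 5 characters, got '", text, "'")
  ch <- strsplit(text, "")[[1]]
  states <- machine$states; inputs <- machine$inputs
  expect <- function(pos, allowed, what) {
    if (!ch[pos] %in% allowed)
      stop("parse error at position ", pos, ": '", ch[pos],
           "' is not a valid ", what, " in '", text, "'")
    ch[pos]
  }
  start <- expect(1, states, "state label")
  input1 <- expect(2, c(inputs, "?"), "input symbol (or '?')")
  mid <- expect(3, c(states, "X"), "state label (or 'X')")
  input2 <- expect(4, c(inputs, "?"), "input symbol (or '?')")
  final <- expect(5, c(states, "?"), "state label (or '?')")
  form <- if (mid == "X") "hidden" else "visible"
  if (input2 == "?") {          # control query on the second (or both) inputs
    task <- "control"
    if (final == "?")
      stop("parse error at position 5: control episodes must end in a goal state")
    if (form == "hidden" && input1 != "?")
      stop("parse error at position 2: hidden control episodes must query both inputs")
    if (form == "visible" && input1 == "?")
      stop("parse error at position 2: visible control episodes show the first input")
  } else if (input1 == "?") {
    stop("parse error at position 2: only control episodes may query the first input")
  } else if (final == "?") {
    task <- "prediction"
  } else {
    task <- "explanation"
  }
  list(start = start, input1 = input1, mid = mid, input2 = input2,
       final = final, task = task, form = form)
}

check_grammar_alphabets <- function(machine) {
  syms <- c(machine$states, machine$inputs)
  if (any(nchar(syms) != 1) || any(syms %in% c("X", "?")))
    stop("episode grammar requires single-character labels distinct from 'X' and '?'")
  if (any(machine$states %in% machine$inputs))
    stop("episode grammar requires disjoint state and input alphabets")
  invisible(machine)
}

flip_input <- function(machine, input) {
  if (length(machine$inputs) != 2)
    stop("explanation tasks require a 2-input machine (counterfactual input flip)")
  setdiff(machine$inputs, input)
}

# All ordered (first, second) input pairs as 2-character strings
input_pairs <- function(machine) {
  as.vector(t(outer(machine$inputs, machine$inputs, paste0)))
}

# Enumerate all admissible (episode, options) candidates for a task x form on
# the TRUE machine: realizable visible transitions, a unique normatively best
# option, and at least one strictly worse distractor exceeding min_gap.
enumerate_questions <- function(machine, task, form, min_gap = 0,
                                epsilon = 0.1) {
  check_grammar_alphabets(machine)
  task <- match.arg(task, TASKS)
  form <- match.arg(form, FORMS)
  k <- machine$kernel
  states <- machine$states
  inputs <- machine$inputs
  out <- list()
  add <- function(ep_string, best, distractors, an_fun) {
    out[[length(out) + 1L]] <<- list(episode = ep_string, best = best,
                                     distractors = distractors)
  }
  if (task == "prediction") {
    for (s1 in states) for (i1 in inputs) {
      mids <- if (form == "visible") states[k[s1, i1, ] > 0] else "X"
      for (m in mids) for (i2 in inputs) {
        v <- if (form == "visible") k[m, i2, ]
             else as.vector(k[s1, i1, ] %*% k[, i2, ])
        names(v) <- states
        cand <- pick_options(v, min_gap, epsilon)
        if (!is.null(cand))
          add(paste0(s1, i1, m, i2, "?"), cand$best, cand$distractors)
      }
    }
  } else if (task == "control") {
    if (form == "visible") {
      for (s1 in states) for (i1 in inputs) {
        for (m in states[k[s1, i1, ] > 0]) for (goal in states) {
          v <- k[m, , goal]
          names(v) <- inputs
          cand <- pick_options(v, min_gap, epsilon)
          if (!is.null(cand))
            add(paste0(s1, i1, m, "?", goal), cand$best, cand$distractors)
        }
      }
    } else {
      pairs <- input_pairs(machine)
      for (s1 in states) for (goal in states) {
        v <- vapply(pairs, function(pr) {
          u <- substr(pr, 1, 1); w <- substr(pr, 2, 2)
          sum(k[s1, u, ] * k[, w, goal])
        }, 0)
        cand <- pick_options(v, min_gap, epsilon)
        if (!is.null(cand))
          add(paste0(s1, "?", "X", "?", goal), cand$best, cand$distractors)
      }
    }
  } else { # explanation: options fixed at input1 vs input2
    for (s1 in states) for (i1 in inputs) for (i2 in inputs) {
      j1 <- flip_input(machine, i1); j2 <- flip_input(machine, i2)
      if (form == "visible") {
        for (m in states[k[s1, i1, ] > 0]) {
          for (s3 in states[k[m, i2, ] > 0]) {
            v <- c(input1 = k[m, j2, s3] * k[s1, i1, m],
                   input2 = k[m, i2, s3] * k[s1, j1, m])
            cand <- pick_options(v, min_gap, epsilon, fixed = TRUE)
            if (!is.null(cand))
              add(paste0(s1, i1, m, i2, s3), cand$best, cand$distractors)
          }
        }
      } else {
        for (s3 in states) {
          if (sum(k[s1, i1, ] * k[, i2, s3]) <= 0) next  # final unrealizable
          v <- c(input1 = sum(k[s1, i1, ] * k[, j2, s3]),
                 input2 = sum(k[s1, j1, ] * k[, i2, s3]))
          cand <- pick_options(v, min_gap, epsilon, fixed = TRUE)
          if (!is.null(cand))
            add(paste0(s1, i1, "X", i2, s3), cand$best, cand$distractors)
        }
      }
    }
  }
  out
}

# Given named option quantities, return the unique best option and the
# distractors that are strictly worse with evidence above min_gap.
pick_options <- function(v, min_gap, epsilon, fixed = FALSE) {
  top <- max(v)
  if (sum(v >= top - 1e-12) != 1L) return(NULL)        # tied best: no answer
  best <- names(v)[which.max(v)]
  lower <- names(v)[v < top - 1e-12]
  keep <- lower[vapply(lower, function(d)
    evidence_R(top, v[[d]], epsilon) > min_gap, TRUE)]
  if (length(keep) == 0) return(NULL)
  if (fixed && length(v) != 2) stop("fixed option sets must have 2 entries")
  list(best = best, distractors = keep)
}

#' Generate two-alternative forced-choice test questions
#'
#' Samples episodes uniformly over the admissible combinations for the given
#' task and form on the true machine. Admissibility requires (i) every
#' visible transition in the episode to have positive probability, and (ii)
#' the two answer options to differ in their normative quantity under the
#' true machine by more than `min_gap` on the evidence scale, so every
#' question has a normatively correct answer. The correct option is the
#' normatively best one; the distractor is drawn uniformly from the strictly
#' worse alternatives (for explanation the options are fixed at first vs
#' second input). Option order is randomized.
#'
#' @param machine The true `"fsm"`.
#' @param task One of `"prediction"`, `"explanation"`, `"control"`.
#' @param form `"visible"` or `"hidden"`.
#' @param n Number of questions.
#' @param min_gap Minimum evidence `R` between the options under the true
#'   machine (default 0: any strict difference).
#' @param epsilon Evidence regularizer used for the `min_gap` screen.
#' @param replace Sample episodes with replacement? Default `FALSE`; an
#'   exhaustion error reports the admissible count when fewer than `n` exist.
#' @param seed Optional integer seed.
#' @param id_start First question id.
#' @return A question bank: `data.frame(id, task, form, episode, option1,
#'   option2, truth_normative, truth_an)` with attribute `"machine"`. Truth
#'   labels are the options favored under the true machine's normative and
#'   alternative-neglect rules (`NA` for an AN tie).
#' @export
generate_questions <- function(machine, task, form, n, min_gap = 0,
                               epsilon = 0.1, replace = FALSE, seed = NULL,
                               id_start = 1L) {
  if (!is.null(seed)) set.seed(seed)
  cands <- enumerate_questions(machine, task, form, min_gap, epsilon)
  if (length(cands) == 0 || (!replace && length(cands) < n))
    stop(sprintf(paste0("question exhaustion: only %d admissible %s/%s ",
                        "episode(s) exist on machine '%s' (requested %d)"),
                 length(cands), task, form, machine$name, n))
  idx <- if (replace) sample.int(length(cands), n, replace = TRUE)
         else sample.int(length(cands), n)
  rows <- lapply(seq_along(idx), function(j) {
    cand <- cands[[idx[j]]]
    distractor <- if (length(cand$distractors) == 1) cand$distractors
                  else sample(cand$distractors, 1)
    opts <- sample(c(cand$best, distractor))      # randomize display order
    q <- data.frame(id = id_start + j - 1L, task = task, form = form,
                    episode = cand$episode, option1 = opts[1],
                    option2 = opts[2], truth_normative = cand$best,
                    truth_an = NA_character_, stringsAsFactors = FALSE)
    an <- an_scores(q, machine, epsilon)
    q$truth_an <- if (identical(an$favored, "TIE")) NA_character_ else an$favored
    q
  })
  bank <- do.call(rbind, rows)
  attr(bank, "machine") <- machine$name
  bank
}

#' Assemble a mixed visible/hidden test block
#'
#' @param machine True `"fsm"`.
#' @param task Task name.
#' @param n_visible,n_hidden Question counts per form.
#' @param order `"random"` interleaves forms at random (between-subject
#'   designs); `"visible_first"` presents all visible questions first
#'   (within-subject designs).
#' @param ... Passed to [generate_questions()] (`min_gap`, `epsilon`,
#'   `replace`).
#' @param id_start First question id.
#' @return A question bank data frame.
#' @export
generate_test_block <- function(machine, task, n_visible = 10, n_hidden = 10,
                                order = c("random", "visible_first"), ...,
                                id_start = 1L) {
  order <- match.arg(order)
  vis <- generate_questions(machine, task, "visible", n_visible, ...,
                            id_start = id_start)
  hid <- generate_questions(machine, task, "hidden", n_hidden, ...,
                            id_start = id_start + n_visible)
  bank <- rbind(vis, hid)
  if (order == "random") bank <- bank[sample.int(nrow(bank)), ]
  rownames(bank) <- NULL
  attr(bank, "machine") <- machine$name
  bank
}

#' Read / write a question bank as JSON lines
#'
#' One question per line:
#' `{"id":..,"task":..,"form":..,"episode":..,"options":[..,..],"truth":{"normative":..,"an":..}}`.
#'
#' @param bank Question bank data frame.
#' @param path File path.
#' @return The bank (read) or `path` invisibly (write).
#' @export
write_question_bank <- function(bank, path) {
  lines <- vapply(seq_len(nrow(bank)), function(i) {
    jsonlite::toJSON(list(
      id = bank$id[i], task = bank$task[i], form = bank$form[i],
      episode = bank$episode[i],
      options = c(bank$option1[i], bank$option2[i]),
      truth = list(normative = bank$truth_normative[i],
                   an = bank$truth_an[i])),
      auto_unbox = TRUE, null = "null")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_question_bank
#' @export
read_question_bank <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    d <- jsonlite::fromJSON(l)
    data.frame(id = as.integer(d$id), task = d$task, form = d$form,
               episode = d$episode, option1 = d$options[1],
               option2 = d$options[2], truth_normative = d$truth$normative,
               truth_an = if (is.null(d$truth$an)) NA_character_ else d$truth$an,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
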