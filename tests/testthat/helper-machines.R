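# Small machines built in code for the tests.

# two-state deterministic cycle: every input flips the state
cycle_machine <- function() {
  fsm("cycle", c("A", "B"), c("a", "b"),
      kernel_from_rows(list(
        A = list(a = c(B = 1), b = c(B = 1)),
        B = list(a = c(A = 1), b = c(A = 1)))))
}

# fully deterministic 4-state machine (digit labels so the episode grammar
# applies); a: +1 cycle, b: +2
det4_machine <- function() {
  s <- as.character(0:3)
  rows <- lapply(0:3, function(j) {
    list(a = stats::setNames(1, as.character((j + 1) %% 4)),
         b = stats::setNames(1, as.character((j + 2) %% 4)))
  })
  names(rows) <- s
  fsm("det4", s, c("a", "b"), kernel_from_rows(rows))
}

# 3-state machine on which the greedy heuristic and the full marginal favor
# different prediction options: from 0 under a the most likely intermediate
# is 1, whose continuation under b favors state 0, but the marginal over
# both intermediates favors state 2.
an_divergent_machine <- function() {
  fsm("an-div", c("0", "1", "2"), c("a", "b"),
      kernel_from_rows(list(
        "0" = list(a = c("1" = 0.6, "2" = 0.4), b = c("0" = 1)),
        "1" = list(a = c("2" = 1), b = c("0" = 0.55, "2" = 0.45)),
        "2" = list(a = c("0" = 1), b = c("2" = 1)))))
}

make_question <- function(episode, machine, option1, option2) {
  ep <- parse_episode(episode, machine)
  data.frame(id = 1L, task = ep$task, form = ep$form, episode = episode,
             option1 = option1, option2 = option2,
             truth_normative = NA_character_, truth_an = NA_character_,
             stringsAsFactors = FALSE)
}

# draw n evidence records at a given beta from a pool of R values
simulate_records <- function(R_pool, beta, n) {
  R <- sample(R_pool, n, replace = TRUE)
  p <- choice_prob(beta, R)
  data.frame(R = R, correct = stats::rbinom(n, 1, p))
}

# pool of positive evidence values from the fixture machines' banks
fixture_R_pool <- function(epsilon = 0.1) {
  pool <- c()
  for (m in list(easy_machine(), hard_machine())) {
    for (task in c("prediction", "explanation", "control")) {
      for (form in c("visible", "hidden")) {
        cands <- fsmpec:::enumerate_questions(m, task, form)
        for (cand in cands) {
          q <- make_question(cand$episode, m, cand$best, cand$distractors[1])
          pool <- c(pool, normative_scores(q, m, epsilon)$R)
        }
      }
    }
  }
  pool[pool > 0]
}
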