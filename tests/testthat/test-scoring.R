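test_that("evidence R has the cap, the zero point, and monotonicity", {
  expect_equal(evidence_R(1, 0, 0.1), log(1.1 / 0.1))
  expect_equal(round(evidence_R(1, 0, 0.1), 1), 2.4)
  expect_equal(evidence_R(0.3, 0.3), 0)
  expect_equal(evidence_R(0, 0), 0)        # finite at all-zero quantities
  expect_error(evidence_R(1, 0, 0), "epsilon")
  # strictly increasing in the larger quantity at fixed smaller one
  ps <- seq(0.31, 1, by = 0.01)
  expect_true(all(diff(evidence_R(ps, 0.3)) > 0))
  # symmetric in the argument order
  expect_equal(evidence_R(0.2, 0.9), evidence_R(0.9, 0.2))
})

test_that("the hidden worked example separates the Bayesian and greedy rules", {
  h <- hard_machine()
  q <- make_question("2aXa?", h, "0", "1")
  norm <- normative_scores(q, h)
  expect_equal(unname(norm$option_values["0"]), 0.16)
  an <- an_scores(q, h)
  expect_equal(unname(an$option_values["0"]), 0)
  # the greedy path quantity is one term of the normative sum
  k <- h$kernel
  terms <- k["2", "a", ] * k[, "a", "0"]
  g <- names(which.max(k["2", "a", ]))
  expect_equal(unname(an$option_values["0"]), unname(terms[g]))
  expect_true(all(unname(an$option_values) <= 1) &&
                all(unname(an$option_values) >= 0))
})

test_that("equal option quantities give R = 0 and a TIE", {
  m <- cycle_machine()
  # both inputs act identically, so control options always tie
  q <- data.frame(id = 1L, task = "control", form = "visible",
                  episode = "AaB?A", option1 = "a", option2 = "b",
                  truth_normative = NA, truth_an = NA,
                  stringsAsFactors = FALSE)
  s <- normative_scores(q, m)
  expect_equal(s$R, 0)
  expect_identical(s$favored, "TIE")
})

test_that("greedy and Bayesian rules diverge on a 3-state construction", {
  m <- an_divergent_machine()
  q <- make_question("0aXb?", m, "0", "2")
  norm <- normative_scores(q, m)
  an <- an_scores(q, m)
  expect_identical(norm$favored, "2")
  expect_identical(an$favored, "0")
})

test_that("visible forms are identical under both answer rules", {
  set.seed(201)
  for (m in list(easy_machine(), hard_machine())) {
    for (task in c("prediction", "explanation", "control")) {
      bank <- generate_questions(m, task, "visible", 5, replace = TRUE)
      for (i in seq_len(nrow(bank))) {
        n <- normative_scores(bank[i, ], m)
        a <- an_scores(bank[i, ], m)
        expect_equal(a$option_values, n$option_values, tolerance = 1e-12)
        expect_identical(a$favored, n$favored)
      }
    }
  }
})

test_that("a one-hot intermediate marginal collapses hidden onto visible", {
  m <- hard_machine()   # (0, a) is deterministic: always to state 2
  qh <- make_question("0aXa?", m, "0", "3")
  qv <- make_question("0a2a?", m, "0", "3")
  norm_h <- normative_scores(qh, m)
  an_h <- an_scores(qh, m)
  norm_v <- normative_scores(qv, m)
  expect_equal(norm_h$option_values, an_h$option_values, tolerance = 1e-12)
  expect_equal(unname(norm_h$option_values), unname(norm_v$option_values),
               tolerance = 1e-12)
})

test_that("greedy ties are averaged deterministically", {
  m <- fsm("tie", c("0", "1", "2"), c("a", "b"),
           kernel_from_rows(list(
             "0" = list(a = c("1" = 0.5, "2" = 0.5), b = c("0" = 1)),
             "1" = list(a = c("0" = 1), b = c("1" = 0.9, "2" = 0.1)),
             "2" = list(a = c("2" = 1), b = c("0" = 1)))))
  q <- make_question("0aXb?", m, "1", "0")
  an <- an_scores(q, m)
  # intermediates 1 and 2 tie at 0.5; the heuristic quantity is the average
  # of the two greedy paths
  expect_equal(unname(an$option_values["1"]), mean(c(0.5 * 0.9, 0.5 * 0)))
  expect_equal(unname(an$option_values["0"]), mean(c(0.5 * 0, 0.5 * 1)))
  expect_identical(an_scores(q, m)$option_values, an$option_values)
})

test_that("brute-force enumeration agrees with the closed-form scorer", {
  set.seed(202)
  for (m in list(easy_machine(), hard_machine())) {
    for (task in c("prediction", "explanation", "control")) {
      for (form in c("visible", "hidden")) {
        bank <- generate_questions(m, task, form, 4, replace = TRUE)
        for (i in seq_len(nrow(bank))) {
          n <- normative_scores(bank[i, ], m)
          b <- brute_force_scores(bank[i, ], m)
          expect_equal(b$option_values, n$option_values, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("scoring respects the marker/form contract", {
  m <- hard_machine()
  q <- make_question("2aXa?", m, "0", "1")
  q$form <- "visible"    # declared form contradicts the episode marker
  expect_error(normative_scores(q, m), "does not match")
})

test_that("score_questions emits one labeled row per question", {
  set.seed(203)
  bank <- generate_test_block(hard_machine(), "control", 3, 3, replace = TRUE)
  tab <- score_questions(bank, hard_machine(), "alternative_neglect")
  expect_equal(nrow(tab), 6)
  expect_identical(tab$question_id, bank$id)
  expect_true(all(tab$answer_model == "alternative_neglect"))
  expect_true(all(tab$favored %in% c(bank$option1, bank$option2, "TIE")))
  expect_true(all(tab$R >= 0))
})
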