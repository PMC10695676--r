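test_that("the choice rule has its fixed points and symmetry", {
  expect_equal(choice_prob(0, c(0, 0.5, 2.4)), rep(0.5, 3))
  expect_equal(choice_prob(3, 0), 0.5)
  expect_equal(choice_prob(1, 1), exp(1) / (exp(1) + exp(-1)))
  expect_equal(round(choice_prob(1, 1), 4), 0.8808)
  R <- seq(0, 3, by = 0.25)
  expect_equal(choice_prob(1.7, R), 1 - choice_prob(1.7, -R))
  # numerically stable far beyond any realistic evidence
  expect_equal(choice_prob(20, 350), 1)
  expect_false(is.nan(choice_prob(20, 350)))
})

test_that("beta is recovered from simulated records and matches glm", {
  set.seed(301)
  pool <- fixture_R_pool()
  rec <- simulate_records(pool, beta = 2, n = 10000)
  fit <- fit_beta(rec)
  expect_true(abs(fit$beta - 2) < 3 * fit$se)
  expect_true(fit$converged && !fit$separation)
  expect_lte(fit$loglik, 0)
  # independent route: no-intercept logistic regression slope = 2 * beta
  g <- stats::glm(correct ~ 0 + R, family = stats::binomial(), data = rec)
  expect_equal(fit$beta_logistic, unname(stats::coef(g)), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
})

test_that("coin-flip responders yield beta near zero", {
  set.seed(302)
  pool <- fixture_R_pool()
  rec <- data.frame(R = sample(pool, 5000, replace = TRUE),
                    correct = stats::rbinom(5000, 1, 0.5))
  fit <- fit_beta(rec)
  expect_lt(abs(fit$beta), 3 * fit$se)
})

test_that("degenerate and separated designs are flagged", {
  expect_error(fit_beta(data.frame(R = c(0, 0), correct = c(1, 0))),
               "degenerate")
  sep <- data.frame(R = runif(50, 0.5, 2), correct = 1L)
  fit <- fit_beta(sep)
  expect_equal(fit$beta, 20)
  expect_true(fit$separation)
  fit_neg <- fit_beta(transform(sep, correct = 0L))
  expect_equal(fit_neg$beta, -20)
  # records with R = 0 contribute a constant log(0.5) each
  rec <- data.frame(R = c(1, 1, 0, 0), correct = c(1, 0, NA, NA))
  expect_equal(fit_beta(rec)$loglik,
               fit_beta(rec[1:2, ])$loglik + 2 * log(0.5))
})

test_that("the fitted beta is a global optimum of a concave likelihood", {
  set.seed(303)
  rec <- simulate_records(fixture_R_pool(), beta = 1, n = 2000)
  fit <- fit_beta(rec)
  grid <- seq(-3, 5, by = 0.05)
  ll <- vapply(grid, function(b)
    sum(ifelse(rec$correct == 1, log(choice_prob(b, rec$R)),
               log(1 - choice_prob(b, rec$R)))), 0)
  expect_true(all(ll <= fit$loglik + 1e-8))
})

test_that("model comparison identifies the generating answer rule", {
  set.seed(304)
  h <- hard_machine()
  bank <- generate_questions(h, "prediction", "hidden", 12, replace = TRUE)
  gen_responses <- function(answer_model, beta, n) {
    sc <- score_questions(bank, h, answer_model)
    idx <- sample.int(nrow(bank), n, replace = TRUE)
    fav <- sc$favored[idx]
    other <- ifelse(bank$option1[idx] == fav, bank$option2[idx],
                    bank$option1[idx])
    take <- stats::rbinom(n, 1, choice_prob(beta, sc$R[idx])) == 1
    data.frame(question_id = bank$id[idx],
               choice = ifelse(fav == "TIE", other,
                               ifelse(take, fav, other)))
  }
  resp_an <- gen_responses("alternative_neglect", 3, 2000)
  cmp <- compare_answer_models(resp_an, bank, h)
  expect_identical(cmp$favored, "alternative_neglect")
  expect_gt(cmp$delta_L, 0)
  expect_equal(cmp$statistic, 2 * cmp$delta_L)
  expect_gt(cmp$p_chi2_dL, cmp$p_chi2_2dL)
  # antisymmetry: the signed difference flips with the generating model
  resp_norm <- gen_responses("normative", 3, 2000)
  cmp2 <- compare_answer_models(resp_norm, bank, h)
  expect_identical(cmp2$favored, "normative")
  expect_true(sign(cmp$delta_L_signed) != sign(cmp2$delta_L_signed))
})

test_that("comparison is an exact wash when the two rules agree everywhere", {
  set.seed(305)
  h <- hard_machine()
  bank <- generate_questions(h, "control", "visible", 10, replace = TRUE)
  ag <- agent_config("normative", beta = 1, model_source = "true_machine")
  resp <- do.call(rbind, lapply(1:10, function(i) {
    r <- data.frame(question_id = bank$id,
                    choice = vapply(seq_len(nrow(bank)), function(j)
                      answer_question(ag, bank[j, ], h), ""))
    r
  }))
  cmp <- compare_answer_models(resp, bank, h)
  expect_equal(cmp$delta_L, 0)
})

test_that("recency rates aggregate per participant with a t test", {
  set.seed(306)
  h <- hard_machine()
  bank <- generate_questions(h, "explanation", "hidden", 20, replace = TRUE)
  ag <- agent_config("recency", recency_strength = 0.58)
  resp <- do.call(rbind, lapply(1:121, function(p) {
    r <- answer_bank(ag, bank, model = NULL)
    data.frame(participant = p, r)
  }))
  rr <- recency_rate(resp, bank)
  expect_equal(nrow(rr$per_participant), 121)
  expect_lt(abs(rr$mean - 0.58), 0.02)
  expect_lt(rr$p, 0.001)
  all2 <- data.frame(participant = 1, question_id = bank$id[1:5],
                     choice = "input2")
  expect_equal(recency_rate(all2, bank)$mean, 1.0)
  pred_bank <- generate_questions(h, "prediction", "visible", 3,
                                  replace = TRUE)
  bad <- data.frame(participant = 1, question_id = pred_bank$id[1],
                    choice = "0")
  expect_error(recency_rate(bad, pred_bank), "explanation")
})

test_that("mental-model accuracy scores against the participant's own model", {
  set.seed(307)
  h <- hard_machine()
  learn <- simulate_learning(h, 45)
  bank <- generate_test_block(h, "prediction", 10, 10, replace = TRUE)
  # an agent that deterministically follows its own model is perfect
  ag <- agent_config("normative", beta = 20, model_source = "learned")
  resp <- answer_bank(ag, bank, learn$model)
  acc <- mm_accuracy(resp, bank, learn$model)
  expect_equal(acc$accuracy, 1.0)
  expect_equal(acc$n_scored + acc$n_tie, nrow(bank))
  # random responding sits near one half
  rnd <- agent_config("random")
  accs <- vapply(1:40, function(i)
    mm_accuracy(answer_bank(rnd, bank, NULL), bank, learn$model)$accuracy, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.06)
})

test_that("own-model accuracy increases with sensitivity", {
  set.seed(308)
  m <- easy_machine()
  learn <- simulate_learning(m, 45)
  bank <- generate_test_block(m, "prediction", 10, 10, replace = TRUE)
  acc_at <- vapply(c(0.5, 1, 4), function(b) {
    ag <- agent_config("normative", beta = b, model_source = "learned")
    mean(vapply(1:40, function(i)
      mm_accuracy(answer_bank(ag, bank, learn$model), bank,
                  learn$model)$accuracy, 0))
  }, 0)
  expect_gt(acc_at[3], acc_at[1])
  expect_gt(acc_at[2], 0.5)
  expect_lt(acc_at[2], 1)
})

test_that("fit and comparison tables serialize as TSV", {
  set.seed(309)
  rec <- simulate_records(fixture_R_pool(), beta = 1, n = 500)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fits_tsv(list(all = fit_beta(rec)), path)
  tab <- utils::read.delim(path)
  expect_identical(names(tab), c("group", "beta", "se", "loglik", "n",
                                 "converged", "separation"))
})
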