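test_that("designs carry the phase structure and validate their fields", {
  d1 <- design_exp1()
  expect_equal(d1$learning_trials, 45)
  expect_equal(c(d1$n_visible, d1$n_hidden), c(10, 10))
  expect_equal(design_exp2()$preview, c(10, 15, 18, 25, 30))
  d3 <- design_exp3()
  expect_true(d3$within)
  expect_equal(d3$learning_trials, 60)
  expect_equal(c(d3$n_visible, d3$n_hidden), c(5, 5))
  d4 <- design_exp4()
  expect_equal(c(d4$learning_trials, d4$block_size, d4$max_attempts),
               c(16, 15, 3))
  expect_equal(ceiling(d4$threshold * d4$block_size), 10)
  expect_error(design_exp4(threshold = 0.4), "threshold")
  expect_error(design_exp4(max_attempts = 0), "max_attempts")
})

test_that("between-subject harness recovers signal and noise regimes", {
  m <- easy_machine()
  # evidence-driven agents: positive beta in every visible condition
  res <- run_exp12(m, 30, agent_config("normative", beta = 3,
                                       model_source = "learned"),
                   seed = 501)
  vis <- res$fits[res$fits$form == "visible" &
                    res$fits$answer_model == "normative", ]
  expect_equal(nrow(vis), 3)
  expect_true(all(vis$beta > 0))
  # random agents: beta near zero, own-model accuracy near one half
  res0 <- run_exp12(m, 30, agent_config("random"), seed = 502)
  fit0 <- res0$fits[res0$fits$answer_model == "normative", ]
  expect_lt(max(abs(fit0$beta)), 3 * max(fit0$se))
  expect_lt(abs(mean(res0$accuracy$mm_accuracy, na.rm = TRUE) - 0.5), 0.07)
  expect_true(all(c("delta_L", "p_chi2_2dL", "p_chi2_dL") %in%
                    names(res0$comparisons)))
})

test_that("greedy responders on hidden questions pull the comparison to AN", {
  m <- hard_machine()
  res <- run_exp12(m, 40, agent_config("alternative_neglect", beta = 3,
                                       model_source = "learned"),
                   tasks = "prediction", seed = 503)
  cmp <- res$comparisons[res$comparisons$form == "hidden", ]
  expect_identical(cmp$favored, "alternative_neglect")
  expect_gt(cmp$delta_L, 0)
})

test_that("within-subject harness reports per-cell betas and correlations", {
  m <- easy_machine()
  res <- run_exp3(m, 24, agent_config("normative", beta = 2,
                                      model_source = "learned"),
                  seed = 504)
  expect_equal(nrow(res$betas), 24 * 6)
  expect_equal(nrow(res$correlations), 6)   # 3 task pairs x 2 forms
  expect_true(all(res$correlations$task1 != res$correlations$task2))
  expect_true(all(res$betas$order %in% 1:3))
})

test_that("cross-task correlations track the generative sharing of beta", {
  m <- easy_machine()
  set.seed(505)
  n <- 80
  shared <- runif(n, 0, 6)
  res_sh <- run_exp3(m, n, agent_config("normative", beta = 1,
                                        model_source = "true_machine"),
                     design = design_exp3(n_visible = 10, n_hidden = 10),
                     seed = 506, betas = shared)
  expect_gt(mean(res_sh$correlations$r, na.rm = TRUE), 0.2)
  indep <- matrix(runif(n * 3, 0, 6), n, 3)
  res_in <- run_exp3(m, n, agent_config("normative", beta = 1,
                                        model_source = "true_machine"),
                     design = design_exp3(n_visible = 10, n_hidden = 10),
                     seed = 507, betas = indep)
  expect_lt(abs(mean(res_in$correlations$r, na.rm = TRUE)), 0.15)
})

test_that("task orders are counterbalanced across a cohort", {
  m <- easy_machine()
  cohort <- simulate_cohort(m, design_exp3(learning_trials = 1,
                                           n_visible = 1, n_hidden = 1),
                            120, agent_config("random"), seed = 508)
  orders <- vapply(cohort, function(p) paste(p$tasks, collapse = "-"), "")
  tab <- table(orders)
  expect_equal(length(tab), 6)
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.001)
})

test_that("threshold training passes, excludes, and transfers as designed", {
  m <- easy_machine()
  # perfect responder: one attempt per part, never excluded
  perfect <- agent_config("fixed_accuracy", accuracy = 1)
  res <- run_exp4(m, 5, perfect, trained_task = "prediction", seed = 509)
  expect_true(all(res$participants$attempts_visible == 1))
  expect_true(all(res$participants$attempts_hidden == 1))
  expect_false(any(res$participants$excluded))
  expect_equal(sort(unique(res$transfer$task)),
               c("control", "explanation"))
  expect_equal(nrow(res$transfer), 5 * 2 * 2)
  # hopeless responder: all attempts used, everyone excluded, no transfer
  never <- agent_config("fixed_accuracy", accuracy = 0.05)
  res0 <- run_exp4(m, 4, never, trained_task = "prediction", seed = 510)
  expect_true(all(res0$participants$excluded))
  expect_true(all(res0$participants$attempts_visible == 3))
  expect_null(res0$transfer)
  # exclusion bookkeeping is exact
  expect_equal(res0$summary$n_excluded + res0$summary$n_analyzed,
               res0$summary$n)
})

test_that("feedback training raises sensitivity and updates the model", {
  m <- easy_machine()
  ag <- agent_config("normative", beta = 0.5, model_source = "learned",
                     beta_step = 0.5)
  res <- run_exp4(m, 4, ag, trained_task = "control", seed = 511)
  # at least one feedback block per part ran, so beta grew by >= 2 steps
  expect_true(all(res$participants$final_beta >= 0.5 + 2 * 0.5 - 1e-12))
  # the final model absorbed visible-block transitions beyond the 16 trials
  expect_true(all(vapply(res$cohort, function(p) sum(p$model$n_obs), 0) > 16))
})

test_that("the two-type mixture reproduces its closed-form correlation", {
  te <- thought_experiment(n_replicates = 400, seed = 512)
  expect_equal(te$closed_form, 0.01 / 0.056, tolerance = 1e-12)
  expect_lt(abs(te$mean_cor - te$closed_form), 0.03)
  expect_false(te$degenerate)
  expect_length(te$cors, 400)
  # equal accuracies: the mixture carries no signal
  flat <- thought_experiment(acc_with = 0.7, acc_without = 0.7,
                             n_replicates = 50, seed = 513)
  expect_true(flat$degenerate)
  expect_equal(flat$closed_form, 0)
  expect_lt(abs(flat$mean_cor), 0.05)
})

test_that("the beta-based mode of the thought experiment tracks the scores", {
  te_s <- thought_experiment(n_replicates = 300, seed = 514)
  te_b <- thought_experiment(n_replicates = 300, mode = "beta", seed = 514)
  expect_gt(te_b$mean_cor, 0)
  # the monotone score-to-beta map preserves the ordering of correlations
  expect_lt(abs(te_b$mean_cor - te_s$mean_cor), 0.1)
})

test_that("more questions and stronger models raise detectable correlation", {
  cf5 <- te_closed_form_cor(0.7, 0.5, 5)
  cf10 <- te_closed_form_cor(0.7, 0.5, 10)
  cf80 <- te_closed_form_cor(0.8, 0.5, 5)
  expect_gt(cf10, cf5)
  expect_gt(cf80, cf5)
})
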