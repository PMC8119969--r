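test_that("trial aggregation conserves totals and matches a hand tally", {
  tr <- simulate_experiment(design_experiment1(),
                            agent_profile(default_params()), seed = 8)
  tab <- aggregate_trials(tr)
  expect_equal(sum(tab$count), 1960)

  empty <- tr[0, ]
  tab0 <- aggregate_trials(empty, conditions = c("moral", "neutral"))
  expect_true(all(tab0$count == 0))

  fix <- data.frame(
    condition = c("m", "m", "m", "n", "n", "n"),
    partner_behavior = c("cooperate", "defect", "defect",
                         "cooperate", "cooperate", "defect"),
    participant_choice = c("cooperate", "cooperate", "defect",
                           "defect", "defect", "defect"),
    punishment_investment = c(0, 3, 0, 5, 0, 9),
    stringsAsFactors = FALSE)
  tab6 <- aggregate_trials(fix)
  get <- function(cond, tree, choice, pun) {
    tab6$count[tab6$condition == cond & tab6$tree == tree &
               tab6$choice == choice & tab6$punished == pun]
  }
  expect_equal(get("m", "partner_cooperates", "cooperate", FALSE), 1)
  expect_equal(get("m", "partner_defects", "cooperate", TRUE), 1)
  expect_equal(get("m", "partner_defects", "defect", FALSE), 1)
  expect_equal(get("n", "partner_cooperates", "defect", TRUE), 1)
  expect_equal(get("n", "partner_cooperates", "defect", FALSE), 1)
  expect_equal(get("n", "partner_defects", "defect", TRUE), 1)
  expect_equal(sum(tab6$count), 6)

  expect_error(aggregate_trials(fix, conditions = "m"), "unknown condition")
  expect_error(aggregate_trials(fix[, -1]), "condition")
})

test_that("fitting a table of exact expected counts recovers the parameters", {
  truth <- list(moral = mpt_parameters(0.45, 0.6, 0.3, 0.2, 0.12),
                neutral = mpt_parameters(0.38, 0.35, 0.25, 0.3, 0.08))
  tab <- table_from_params(truth, n_per_tree = 490)
  fit <- fit_mpt(tab, n_starts = 5)
  expect_true(fit$converged)
  expect_lt(fit$g2, 1e-9)
  for (cond in names(truth)) {
    expect_equal(unclass(fit$estimates[[cond]]),
                 unclass(truth[[cond]]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  expect_equal(fit$df, 2)
  expect_equal(fit$p_value, 1, tolerance = 1e-6)
})

test_that("equality constraints are honored exactly and never improve fit", {
  set.seed(55)
  tr <- simulate_experiment(design_experiment1(),
                            agent_profile(default_params()), seed = 17)
  tab <- aggregate_trials(tr)
  full <- fit_mpt(tab, n_starts = 3)
  for (par in c("C", "P_Moral", "b")) {
    res <- fit_mpt(tab, model_spec(c("moral", "neutral"), par), n_starts = 3)
    expect_identical(unclass(res$estimates$moral)[[par]],
                     unclass(res$estimates$neutral)[[par]])
    expect_gte(res$g2, full$g2 - 1e-6)
    expect_equal(res$df, 3)
  }
})

test_that("adding constraints never decreases minimized G-squared on random tables", {
  set.seed(77)
  for (i in 1:5) {
    counts <- lapply(list(moral = NULL, neutral = NULL), function(x) {
      as.numeric(c(stats::rmultinom(1, 300, stats::runif(4, 0.05, 1)),
                   stats::rmultinom(1, 300, stats::runif(4, 0.05, 1))))
    })
    tab <- category_table(counts)
    # arbitrary tables routinely put punishment parameters on the boundary;
    # the SE warning is expected there
    g_full <- suppressWarnings(fit_mpt(tab, n_starts = 3)$g2)
    par <- sample(c("C", "P_Moral", "P_Hypocritical", "P_Antisocial", "b"), 1)
    g_res <- suppressWarnings(
      fit_mpt(tab, model_spec(c("moral", "neutral"), par), n_starts = 3)$g2)
    expect_gte(g_res, g_full - 1e-6)
  }
})

test_that("standard errors are omitted with a warning at boundary solutions", {
  # zero counts in every punished cell force b-hat (and punishment
  # parameters) to the boundary
  tab <- category_table(list(moral = c(0, 200, 0, 300, 0, 180, 0, 320),
                             neutral = c(0, 210, 0, 290, 0, 190, 0, 310)))
  expect_warning(fit <- fit_mpt(tab, n_starts = 2), "boundary")
  expect_true(all(is.na(fit$standard_errors[fit$boundary])))
})

test_that("the unconstrained two-condition model is locally identified at interior points", {
  spec <- model_spec(c("moral", "neutral"))
  rep <- check_identifiability(spec, mpt_parameters(0.4, 0.5, 0.35, 0.3, 0.45))
  expect_equal(rep$expected_rank, 10)
  expect_equal(rep$jacobian_rank, 10)
  expect_length(rep$deficient_directions, 0)
})

test_that("C = 0 in one condition confounds that condition's moral-punishment parameter", {
  spec <- model_spec(c("moral", "neutral"))
  point <- list(moral = mpt_parameters(0, 0.5, 0.35, 0.3, 0.45),
                neutral = mpt_parameters(0.4, 0.5, 0.35, 0.3, 0.45))
  rep <- check_identifiability(spec, point)
  expect_lt(rep$jacobian_rank, 10)
  expect_true("P_Moral.moral" %in% rep$deficient_directions)
})

test_that("a fully constrained spec has expected rank five", {
  spec <- model_spec(c("moral", "neutral"),
                     c("C", "P_Moral", "P_Hypocritical", "P_Antisocial", "b"))
  rep <- check_identifiability(spec, mpt_parameters(0.4, 0.5, 0.35, 0.3, 0.45))
  expect_equal(rep$expected_rank, 5)
  expect_equal(rep$jacobian_rank, 5)
})
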