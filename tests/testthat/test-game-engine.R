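test_that("partner schedule enforces the exact cooperate/defect split", {
  set.seed(11)
  s <- partner_schedule(20, 0.5)
  expect_length(s, 20)
  expect_equal(sum(s == "cooperate"), 10)
  expect_equal(partner_schedule(4, 1.0), rep("cooperate", 4))
  expect_error(partner_schedule(20, 0.33), "integer")
})

test_that("partner schedule is a uniform permutation (per-position rate ~ 1/2)", {
  n_rep <- 1000
  hits <- numeric(20)
  for (seed in seq_len(n_rep)) {
    set.seed(seed)
    hits <- hits + (partner_schedule(20, 0.5) == "cooperate")
  }
  # positions are exchangeable; 3 binomial SE around 0.5
  se <- sqrt(0.5 * 0.5 / n_rep)
  expect_true(all(abs(hits / n_rep - 0.5) < 3 * se))
})

test_that("payoff matrix follows the Prisoner's Dilemma ordering", {
  expect_equal(apply_payoff("cooperate", "cooperate"),
               c(participant = 10, partner = 10))
  expect_equal(apply_payoff("cooperate", "defect"),
               c(participant = -10, partner = 20))
  expect_equal(apply_payoff("defect", "cooperate"),
               c(participant = 20, partner = -10))
  expect_equal(apply_payoff("defect", "defect"),
               c(participant = 0, partner = 0))
  expect_error(apply_payoff("cooperate", "fold"), "cooperate")
  expect_error(payoff_rule(temptation = 5), "temptation")
})

test_that("punishment branch probabilities fold the bias after the dedicated parameter", {
  p <- mpt_parameters(0.5, 0.4, 0.3, 0.2, 0.2)
  expect_equal(punish_branch_probability("mutual_cooperation", p), 0.2)
  expect_equal(punish_branch_probability("mutual_defection",
                 mpt_parameters(0.5, 0, 0.3, 0, 0.1)), 0.37)
  p1 <- mpt_parameters(0.5, 1, 0.3, 0.2, 0.2)
  expect_equal(punish_branch_probability("partner_unilateral_defection", p1), 1)
  expect_error(punish_branch_probability("nonsense", p), "unknown")
})

test_that("simulated experiment has the right shape, split, and determinism", {
  prof <- agent_profile(default_params())
  tr <- simulate_experiment(design_experiment1(), prof, seed = 3)
  expect_equal(nrow(tr), 98 * 20)
  expect_setequal(unique(tr$condition), c("moral", "neutral"))
  # alternating assignment
  expect_equal(unique(tr$condition[tr$participant_id == 1]), "moral")
  expect_equal(unique(tr$condition[tr$participant_id == 2]), "neutral")
  # exact partner split for every participant
  coop_per_part <- tapply(tr$partner_behavior == "cooperate",
                          tr$participant_id, sum)
  expect_true(all(coop_per_part == 10))
  # reproducibility and prefix stability under added participants
  tr2 <- simulate_experiment(design_experiment1(), prof, seed = 3)
  expect_identical(tr, tr2)
  tr3 <- simulate_experiment(design_experiment1(120), prof, seed = 3)
  expect_identical(tr, tr3[tr3$participant_id <= 98, ])
})

test_that("degenerate agent (certain cooperation, no punishment) never punishes", {
  prof <- agent_profile(mpt_parameters(1, 0, 0, 0, 0))
  tr <- simulate_experiment(experiment_design(6), prof, seed = 5)
  expect_true(all(tr$participant_choice == "cooperate"))
  expect_true(all(tr$punishment_investment == 0))
})

test_that("balances conserve payoffs, punishment costs, and received deductions", {
  d <- design_experiment2(8)
  tr <- simulate_experiment(d, agent_profile(default_params()), seed = 9)
  pay <- mapply(function(ch, pb) apply_payoff(ch, pb)[["participant"]],
                tr$participant_choice, tr$partner_behavior)
  delta <- unname(pay) - tr$punishment_investment -
    10 * tr$partner_punishment_cost
  for (id in unique(tr$participant_id)) {
    sub <- tr[tr$participant_id == id, ]
    expect_equal(sub$participant_balance_after,
                 400 + cumsum(delta[tr$participant_id == id]))
  }
})

test_that("partner moral punishment hits exactly the participant's unilateral defection", {
  prof <- agent_profile(mpt_parameters(0.5, 0.5, 0.5, 0.5, 0.1))
  tr1 <- simulate_experiment(design_experiment1(20), prof, seed = 13)
  expect_true(all(tr1$partner_punishment_cost == 0))
  tr2 <- simulate_experiment(design_experiment2(20), prof, seed = 13)
  hit <- tr2$participant_choice == "defect" &
    tr2$partner_behavior == "cooperate"
  expect_true(all(tr2$partner_punishment_cost[hit] %in% 1:9))
  expect_true(all(tr2$partner_punishment_cost[!hit] == 0))
})

test_that("empirical cell frequencies agree with the closed-form category probabilities", {
  prof <- agent_profile(default_params())
  tr <- simulate_experiment(experiment_design(2000), prof, seed = 21)
  tab <- aggregate_trials(tr)
  probs <- category_probabilities(default_params())
  for (cond in c("moral", "neutral")) {
    for (tree in c("partner_cooperates", "partner_defects")) {
      n <- tab$count[tab$condition == cond & tab$tree == tree]
      tot <- sum(n)
      e <- probs[cell_key(tree, c("cooperate", "cooperate", "defect",
                                  "defect"), c(TRUE, FALSE, TRUE, FALSE))]
      se <- sqrt(tot * e * (1 - e))
      expect_true(all(abs(n - tot * e) < 3 * se))
    }
  }
})

test_that("trial tables round-trip through CSV", {
  tr <- simulate_experiment(experiment_design(4), agent_profile(default_params()),
                            seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back, tr)
  expect_equal(aggregate_trials(back), aggregate_trials(tr))
})
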