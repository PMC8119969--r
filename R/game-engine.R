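#' Payoff rule of the one-shot Prisoner's Dilemma
#'
#' The four payoffs (in cents) of the simultaneous game, required to satisfy
#' the Prisoner's Dilemma ordering temptation > reward > punishment outcome
#' > sucker. Defaults match the experimental game: unilateral defection 20,
#' mutual cooperation 10, mutual defection 0, unilateral cooperation -10.
#'
#' @param temptation payoff for unilateral defection.
#' @param reward payoff for mutual cooperation.
#' @param punishment_outcome payoff for mutual defection.
#' @param sucker payoff for unilateral cooperation.
#' @return An object of class `"payoff_rule"`.
#' @export
payoff_rule <- function(temptation = 20, reward = 10,
                        punishment_outcome = 0, sucker = -10) {
  if (!(temptation > reward && reward > punishment_outcome &&
        punishment_outcome > sucker)) {
    stop("payoffs must satisfy temptation > reward > punishment_outcome ",
         "> sucker", call. = FALSE)
  }
  structure(list(temptation = temptation, reward = reward,
                 punishment_outcome = punishment_outcome, sucker = sucker),
            class = "payoff_rule")
}

#' Payoff deltas for one round
#'
#' Applies the symmetric payoff matrix: each player's delta depends on their
#' own and the other's choice.
#'
#' @param participant_choice,partner_behavior `"cooperate"` or `"defect"`.
#' @param rule a [payoff_rule()].
#' @return Named numeric vector `c(participant = ..., partner = ...)` in
#'   cents.
#' @examples
#' apply_payoff("cooperate", "defect")  # sucker vs temptation
#' @export
apply_payoff <- function(participant_choice, partner_behavior,
                         rule = payoff_rule()) {
  one <- function(own, other) {
    if (own == "cooperate") {
      if (other == "cooperate") rule$reward else rule$sucker
    } else {
      if (other == "cooperate") rule$temptation else rule$punishment_outcome
    }
  }
  ok <- c("cooperate", "defect")
  if (!participant_choice %in% ok || !partner_behavior %in% ok) {
    stop("choices must be 'cooperate' or 'defect'", call. = FALSE)
  }
  c(participant = one(participant_choice, partner_behavior),
    partner = one(partner_behavior, participant_choice))
}

#' Experiment design
#'
#' Describes one experiment: sample size, trials per participant, the exact
#' fraction of computer partners that cooperate, the starting endowment, the
#' punishment economy (1-9 cents invested remove 10-90 cents), and whether
#' partners morally punish the participant's unilateral defection (the
#' second experiment's symmetric-punishment variant).
#'
#' @param n_participants number of participants.
#' @param n_trials_per_participant trials (one-shot rounds) per participant.
#' @param frac_partner_cooperate fraction of partners that cooperate;
#'   `frac * n_trials` must be an integer (exact schedule).
#' @param endowment starting account balance in cents.
#' @param punishment_cost_range integer vector of admissible punishment
#'   investments in cents.
#' @param punishment_multiplier cents deducted from the punished party per
#'   cent invested.
#' @param partner_punishes_unilateral_defection if `TRUE`, a cooperating
#'   partner who is cheated punishes the participant (cost uniform on the
#'   cost range, deduction times the multiplier).
#' @param framing_arms condition labels; participants are assigned
#'   alternately by participant id.
#' @param payoffs a [payoff_rule()].
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(n_participants,
                              n_trials_per_participant = 20L,
                              frac_partner_cooperate = 0.5,
                              endowment = 400,
                              punishment_cost_range = 1:9,
                              punishment_multiplier = 10,
                              partner_punishes_unilateral_defection = FALSE,
                              framing_arms = c("moral", "neutral"),
                              payoffs = payoff_rule()) {
  stopifnot(n_participants >= 1, n_trials_per_participant >= 1)
  n_coop <- frac_partner_cooperate * n_trials_per_participant
  if (abs(n_coop - round(n_coop)) > 1e-9) {
    stop("frac_partner_cooperate * n_trials_per_participant must be an ",
         "integer", call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 n_trials_per_participant = as.integer(n_trials_per_participant),
                 frac_partner_cooperate = frac_partner_cooperate,
                 endowment = endowment,
                 punishment_cost_range = as.integer(punishment_cost_range),
                 punishment_multiplier = punishment_multiplier,
                 partner_punishes_unilateral_defection =
                   isTRUE(partner_punishes_unilateral_defection),
                 framing_arms = as.character(framing_arms),
                 payoffs = payoffs),
            class = "experiment_design")
}

#' Agent profile: generating parameters plus a punishment-amount rule
#'
#' The generative counterpart of the measurement model: an agent cooperates
#' with probability `C`, punishes with the branch probability of the
#' realized outcome cell, and, when punishing, invests an amount drawn from
#' `punishment_amount_rule` (default uniform over the design's cost range —
#' the amount is not modelled by the measurement model, so the rule is
#' pluggable).
#'
#' @param parameters an [mpt_parameters()] vector (the ground truth).
#' @param punishment_amount_rule function `(n)` returning `n` integer
#'   investments; default uniform on 1..9.
#' @return An object of class `"agent_profile"`.
#' @export
agent_profile <- function(parameters,
                          punishment_amount_rule = function(n)
                            sample(1:9, n, replace = TRUE)) {
  structure(list(parameters = validate_params(parameters),
                 punishment_amount_rule = punishment_amount_rule),
            class = "agent_profile")
}

#' Exact partner schedule
#'
#' Returns the partner behaviors for one participant: a uniformly random
#' permutation containing exactly `frac_cooperate * n_trials` cooperators
#' (the computer partners' choices are random subject to this exact split).
#'
#' @param n_trials number of rounds.
#' @param frac_cooperate fraction of cooperating partners; the product with
#'   `n_trials` must be an integer.
#' @return Character vector of `"cooperate"`/`"defect"` of length
#'   `n_trials`.
#' @export
partner_schedule <- function(n_trials, frac_cooperate) {
  n_coop <- frac_cooperate * n_trials
  if (abs(n_coop - round(n_coop)) > 1e-9) {
    stop("frac_cooperate * n_trials must be an integer", call. = FALSE)
  }
  n_coop <- as.integer(round(n_coop))
  sample(rep(c("cooperate", "defect"), c(n_coop, n_trials - n_coop)))
}

# Deterministic per-participant child seed from the root seed, so that
# adding participants never perturbs the streams of earlier ones.
child_seed <- function(root_seed, participant_id) {
  (as.integer(root_seed) %% 1000003L) * 2011L + participant_id * 7L
}

#' Simulate a full experiment
#'
#' Generates the trial table of one experiment: participants are assigned
#' alternately to the framing arms, each plays `n_trials` one-shot rounds
#' against computer partners with an exact cooperate/defect split, chooses
#' to cooperate with probability `C`, and punishes with the processing-tree
#' branch probability of the realized outcome. Account balances track the
#' payoff matrix, punishment investments, and received deductions. With
#' `partner_punishes_unilateral_defection`, a cheated cooperating partner
#' punishes back at a uniformly random cost. Fully reproducible: each
#' participant has a child random stream derived from `seed`.
#'
#' @param design an [experiment_design()].
#' @param profiles named list mapping each framing arm to an
#'   [agent_profile()]; a single profile is recycled to all arms.
#' @param seed integer root seed.
#' @return Data frame with one row per trial: `participant_id`, `condition`,
#'   `trial_index`, `partner_behavior`, `participant_choice`,
#'   `punishment_investment`, `partner_punishment_cost`,
#'   `participant_balance_after`, `partner_balance_after`.
#' @export
simulate_experiment <- function(design, profiles, seed) {
  stopifnot(inherits(design, "experiment_design"))
  if (inherits(profiles, "agent_profile")) {
    profiles <- stats::setNames(rep(list(profiles),
                                    length(design$framing_arms)),
                                design$framing_arms)
  }
  miss <- setdiff(design$framing_arms, names(profiles))
  if (length(miss)) {
    stop("no agent profile for arm(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (p in profiles) {
    if (!inherits(p, "agent_profile")) stop("invalid agent profile",
                                            call. = FALSE)
  }
  nt <- design$n_trials_per_participant
  arms <- design$framing_arms
  rule <- design$payoffs
  np <- design$n_participants
  col <- function() vector("list", np)
  acc <- list(condition = col(), partner = col(), choice = col(),
              invest = col(), partner_cost = col(), balance = col(),
              partner_balance = col())
  for (id in seq_len(np)) {
    cond <- arms[((id - 1L) %% length(arms)) + 1L]
    prof <- profiles[[cond]]
    par <- prof$parameters
    set.seed(child_seed(seed, id))
    partner <- partner_schedule(nt, design$frac_partner_cooperate)
    choice <- ifelse(stats::runif(nt) < par[["C"]], "cooperate", "defect")
    cellname <- ifelse(choice == "cooperate",
                       ifelse(partner == "cooperate",
                              "mutual_cooperation",
                              "partner_unilateral_defection"),
                       ifelse(partner == "cooperate",
                              "participant_unilateral_defection",
                              "mutual_defection"))
    p_pun <- vapply(c(mutual_cooperation = "mutual_cooperation",
                      partner_unilateral_defection =
                        "partner_unilateral_defection",
                      participant_unilateral_defection =
                        "participant_unilateral_defection",
                      mutual_defection = "mutual_defection"),
                    punish_branch_probability, numeric(1), params = par)
    punished <- stats::runif(nt) < p_pun[cellname]
    invest <- integer(nt)
    if (any(punished)) invest[punished] <-
      as.integer(prof$punishment_amount_rule(sum(punished)))
    # partner moral punishment of the participant's unilateral defection
    partner_cost <- integer(nt)
    if (design$partner_punishes_unilateral_defection) {
      hit <- choice == "defect" & partner == "cooperate"
      if (any(hit)) partner_cost[hit] <-
        sample(design$punishment_cost_range, sum(hit), replace = TRUE)
    }
    own_pay <- ifelse(choice == "cooperate",
                      ifelse(partner == "cooperate", rule$reward,
                             rule$sucker),
                      ifelse(partner == "cooperate", rule$temptation,
                             rule$punishment_outcome))
    partner_pay <- ifelse(partner == "cooperate",
                          ifelse(choice == "cooperate", rule$reward,
                                 rule$sucker),
                          ifelse(choice == "cooperate", rule$temptation,
                                 rule$punishment_outcome))
    mult <- design$punishment_multiplier
    own_delta <- own_pay - invest - mult * partner_cost
    balance <- design$endowment + cumsum(own_delta)
    # each round's partner is new; their displayed balance starts within 10
    # cents of the participant's (cosmetic jitter, no behavioral role)
    jitter <- sample(-10:10, nt, replace = TRUE)
    partner_balance <- c(design$endowment, balance[-nt]) + jitter +
      partner_pay - mult * invest - partner_cost
    acc$condition[[id]] <- cond
    acc$partner[[id]] <- partner
    acc$choice[[id]] <- choice
    acc$invest[[id]] <- invest
    acc$partner_cost[[id]] <- partner_cost
    acc$balance[[id]] <- balance
    acc$partner_balance[[id]] <- partner_balance
  }
  data.frame(
    participant_id = rep(seq_len(np), each = nt),
    condition = rep(unlist(acc$condition), each = nt),
    trial_index = rep.int(seq_len(nt), np),
    partner_behavior = unlist(acc$partner),
    participant_choice = unlist(acc$choice),
    punishment_investment = unlist(acc$invest),
    partner_punishment_cost = unlist(acc$partner_cost),
    participant_balance_after = unlist(acc$balance),
    partner_balance_after = unlist(acc$partner_balance),
    stringsAsFactors = FALSE)
}

#' Read/write trial tables as CSV
#'
#' Plain UTF-8 CSV with a header and the [simulate_experiment()] columns;
#' punishment columns in integer cents. Real experimental data can be
#' supplied in the same schema (only `condition`, `partner_behavior`,
#' `participant_choice` and `punishment_investment` are needed for the
#' model-based analysis).
#'
#' @param trials trial data frame.
#' @param path file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` the data
#'   frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "partner_behavior", "participant_choice",
            "punishment_investment")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trial CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}
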