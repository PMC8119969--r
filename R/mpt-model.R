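# Canonical parameter and cell orderings used throughout the package.
# Cells within each tree: the participant's choice crossed with whether a
# punishment investment (> 0 cents) was made.
.mpt_param_names <- c("C", "P_Moral", "P_Hypocritical", "P_Antisocial", "b")
.mpt_trees <- c("partner_cooperates", "partner_defects")
.mpt_cells <- c("cooperate_punished", "cooperate_unpunished",
                "defect_punished", "defect_unpunished")

#' Latent parameters of the cooperation-and-punishment model
#'
#' Bundles the five latent probabilities of the multinomial processing tree
#' (MPT) model of cooperation and costly punishment: the probability of
#' cooperation `C` (shared across both trees because the game is
#' simultaneous), the conditional punishment probabilities `P_Moral`
#' (punishing a partner who defected against one's own cooperation),
#' `P_Hypocritical` (punishing a defecting partner after defecting oneself),
#' `P_Antisocial` (punishing a cooperating partner after defecting), and the
#' outcome-independent punishment bias `b`, the only punishment source after
#' mutual cooperation.
#'
#' @param C,P_Moral,P_Hypocritical,P_Antisocial,b probabilities in \[0, 1\].
#' @return A named numeric vector of class `"mpt_parameters"`.
#' @examples
#' mpt_parameters(C = 0.4, P_Moral = 0.6, P_Hypocritical = 0.3,
#'                P_Antisocial = 0.2, b = 0.1)
#' @export
mpt_parameters <- function(C, P_Moral, P_Hypocritical, P_Antisocial, b) {
  p <- c(C = C, P_Moral = P_Moral, P_Hypocritical = P_Hypocritical,
         P_Antisocial = P_Antisocial, b = b)
  validate_params(p)
}

#' Validate a set of MPT parameters
#'
#' Rejects values outside \[0, 1\] with an error naming the offending
#' parameter. Values exactly on the boundary are accepted but flagged
#' (attribute `"boundary"`), because observed-information standard errors
#' are not valid at boundary estimates.
#'
#' @param params named numeric vector with entries `C`, `P_Moral`,
#'   `P_Hypocritical`, `P_Antisocial`, `b` (any order; extra names are an
#'   error).
#' @return The parameters as an `"mpt_parameters"` vector in canonical order,
#'   with a logical `"boundary"` attribute per parameter.
#' @export
validate_params <- function(params) {
  params <- unlist(params)
  if (!all(.mpt_param_names %in% names(params))) {
    stop("parameters must be named ",
         paste(.mpt_param_names, collapse = ", "), call. = FALSE)
  }
  params <- params[.mpt_param_names]
  bad <- !is.finite(params) | params < 0 | params > 1
  if (any(bad)) {
    stop("parameter(s) out of [0, 1]: ",
         paste(names(params)[bad], collapse = ", "), call. = FALSE)
  }
  attr(params, "boundary") <- params == 0 | params == 1
  class(params) <- "mpt_parameters"
  params
}

#' Probability that a trial ends in punishment, by outcome cell
#'
#' Evaluates the punishment branch of the processing tree for one outcome of
#' the Prisoner's Dilemma. After mutual cooperation only the bias `b` can
#' produce punishment; in the other three outcomes the dedicated punishment
#' parameter acts first and, failing that, the bias still can:
#' `P + (1 - P) * b`.
#'
#' @param cell one of `"mutual_cooperation"`, `"partner_unilateral_defection"`
#'   (participant cooperated, partner defected), `"mutual_defection"`,
#'   `"participant_unilateral_defection"` (participant defected, partner
#'   cooperated).
#' @param params an [mpt_parameters()] vector.
#' @return Probability of a nonzero punishment investment in that cell.
#' @export
punish_branch_probability <- function(cell, params) {
  params <- validate_params(params)
  fold <- function(p, b) p + (1 - p) * b
  b <- params[["b"]]
  switch(cell,
    mutual_cooperation = b,
    partner_unilateral_defection = fold(params[["P_Moral"]], b),
    mutual_defection = fold(params[["P_Hypocritical"]], b),
    participant_unilateral_defection = fold(params[["P_Antisocial"]], b),
    stop("unknown outcome cell: ", cell, call. = FALSE)
  )
}

#' Category probabilities of the cooperation-and-punishment model
#'
#' Maps the five latent parameters to the eight observable category
#' probabilities: two trees (partner cooperates / partner defects), each with
#' four cells (own choice crossed with punished / not punished). Each tree
#' sums to 1.
#'
#' Partner-cooperates tree: `C*b`, `C*(1-b)`,
#' `(1-C)*(P_Antisocial + (1-P_Antisocial)*b)`,
#' `(1-C)*(1-P_Antisocial)*(1-b)`. Partner-defects tree:
#' `C*(P_Moral + (1-P_Moral)*b)`, `C*(1-P_Moral)*(1-b)`,
#' `(1-C)*(P_Hypocritical + (1-P_Hypocritical)*b)`,
#' `(1-C)*(1-P_Hypocritical)*(1-b)`.
#'
#' @param params an [mpt_parameters()] vector.
#' @return Named numeric vector of length 8 in the fixed cell order
#'   `<tree>.<choice>_<punished>`; each tree's four entries sum to 1.
#' @export
category_probabilities <- function(params) {
  params <- validate_params(params)
  C <- params[["C"]]; b <- params[["b"]]
  pm <- params[["P_Moral"]]; ph <- params[["P_Hypocritical"]]
  pa <- params[["P_Antisocial"]]
  coop_tree <- c(C * b,
                 C * (1 - b),
                 (1 - C) * (pa + (1 - pa) * b),
                 (1 - C) * (1 - pa) * (1 - b))
  defect_tree <- c(C * (pm + (1 - pm) * b),
                   C * (1 - pm) * (1 - b),
                   (1 - C) * (ph + (1 - ph) * b),
                   (1 - C) * (1 - ph) * (1 - b))
  out <- c(coop_tree, defect_tree)
  names(out) <- paste(rep(.mpt_trees, each = 4L), rep(.mpt_cells, 2L),
                      sep = ".")
  out
}

#' Likelihood-ratio goodness-of-fit statistic G-squared
#'
#' Computes `G^2 = 2 * sum(n * log(n / e))` over the eight cells per
#' condition, with expected counts `e` equal to the tree total times the
#' model category probability. Zero observed counts contribute zero
#' (`0 * log(0) = 0`). A structurally impossible cell (expected 0, observed
#' positive) yields `+Inf` with a boundary-degeneracy warning.
#'
#' @param observed a [category_table()] (any number of conditions).
#' @param params either a single [mpt_parameters()] vector applied to every
#'   condition, a named list of such vectors (one per condition), or a
#'   numeric vector of expected counts in table row order.
#' @return The G-squared statistic (nonnegative; 0 iff observed equals
#'   expected in every nonzero cell).
#' @export
g_squared <- function(observed, params) {
  stopifnot(inherits(observed, "category_table"))
  n <- observed$count
  e <- expected_counts(observed, params)
  if (any(e == 0 & n > 0)) {
    warning("observed count in a cell with expected count 0; ",
            "G-squared is infinite (boundary degeneracy)", call. = FALSE)
    return(Inf)
  }
  pos <- n > 0
  2 * sum(n[pos] * log(n[pos] / e[pos]))
}

# Expected counts for a category table under given parameters (or passed
# through when already counts). Tree totals are taken from the table.
expected_counts <- function(observed, params) {
  if (is.numeric(params) && is.null(attr(params, "class")) &&
      length(params) == nrow(observed)) {
    return(as.numeric(params))
  }
  conds <- unique(observed$condition)
  if (inherits(params, "mpt_parameters")) {
    params <- stats::setNames(rep(list(params), length(conds)), conds)
  }
  if (!all(conds %in% names(params))) {
    stop("parameters missing for condition(s): ",
         paste(setdiff(conds, names(params)), collapse = ", "), call. = FALSE)
  }
  e <- numeric(nrow(observed))
  for (cond in conds) {
    probs <- category_probabilities(params[[cond]])
    for (tree in .mpt_trees) {
      sel <- observed$condition == cond & observed$tree == tree
      total <- sum(observed$count[sel])
      key <- paste(tree, paste(observed$choice[sel],
                               ifelse(observed$punished[sel],
                                      "punished", "unpunished"), sep = "_"),
                   sep = ".")
      e[sel] <- total * probs[key]
    }
  }
  e
}

#' Model specification: conditions and cross-condition equality constraints
#'
#' Describes which framing conditions are modelled and which parameters are
#' constrained to be equal across all conditions. The free-parameter count
#' and residual degrees of freedom follow: with `k` conditions, each tree
#' pair contributes `6` free cells per condition (8 cells minus 2 tree-sum
#' constraints), and the model has `5k - (k - 1) * n_constraints` free
#' parameters.
#'
#' @param conditions ordered character vector of condition labels (default
#'   `c("moral", "neutral")`).
#' @param constraints character vector of parameter names (subset of
#'   `C, P_Moral, P_Hypocritical, P_Antisocial, b`) forced equal across
#'   conditions.
#' @return An object of class `"mpt_model_spec"` with elements `conditions`,
#'   `constraints`, `n_free_parameters`, `df`.
#' @export
model_spec <- function(conditions = c("moral", "neutral"),
                       constraints = character()) {
  conditions <- as.character(conditions)
  if (length(conditions) < 1L || anyDuplicated(conditions)) {
    stop("conditions must be distinct labels", call. = FALSE)
  }
  constraints <- as.character(constraints)
  bad <- setdiff(constraints, .mpt_param_names)
  if (length(bad)) {
    stop("unknown parameter(s) in constraints: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  k <- length(conditions)
  n_free <- 5L * k - (k - 1L) * length(constraints)
  df <- 6L * k - n_free
  structure(list(conditions = conditions, constraints = constraints,
                 n_free_parameters = n_free, df = df),
            class = "mpt_model_spec")
}

#' @export
print.mpt_model_spec <- function(x, ...) {
  cat("MPT model spec: conditions", paste(x$conditions, collapse = ", "),
      "\n  constraints:",
      if (length(x$constraints)) paste(x$constraints, collapse = ", ")
      else "(none)",
      "\n  free parameters:", x$n_free_parameters, " df:", x$df, "\n")
  invisible(x)
}

# Layout of the free-parameter vector for a spec: constrained parameters get
# one slot shared by all conditions, unconstrained ones a slot per condition.
# Returns a data.frame mapping (condition, parameter) -> free index.
free_parameter_layout <- function(spec) {
  map <- expand.grid(parameter = .mpt_param_names,
                     condition = spec$conditions,
                     stringsAsFactors = FALSE)[, c("condition", "parameter")]
  labels <- ifelse(map$parameter %in% spec$constraints,
                   map$parameter,
                   paste(map$parameter, map$condition, sep = "."))
  uniq <- unique(labels)
  map$index <- match(labels, uniq)
  attr(map, "labels") <- uniq
  map
}

# Expand a free-parameter vector into per-condition mpt_parameters.
expand_free_parameters <- function(theta, spec) {
  map <- free_parameter_layout(spec)
  out <- lapply(spec$conditions, function(cond) {
    rows <- map[map$condition == cond, ]
    validate_params(stats::setNames(theta[rows$index], rows$parameter))
  })
  stats::setNames(out, spec$conditions)
}
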