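# Internal: category probabilities from a raw numeric 5-vector in canonical
# order (C, P_Moral, P_Hypocritical, P_Antisocial, b), no validation — the
# optimizer's hot path.
.cat_probs_raw <- function(p) {
  C <- p[1L]; pm <- p[2L]; ph <- p[3L]; pa <- p[4L]; b <- p[5L]
  c(C * b, C * (1 - b),
    (1 - C) * (pa + (1 - pa) * b), (1 - C) * (1 - pa) * (1 - b),
    C * (pm + (1 - pm) * b), C * (1 - pm) * (1 - b),
    (1 - C) * (ph + (1 - ph) * b), (1 - C) * (1 - ph) * (1 - b))
}

.logistic <- function(x) 1 / (1 + exp(-x))
.logit <- function(p) log(p / (1 - p))

# Internal fitting context: counts and tree totals per condition plus the
# free-parameter index map, so the G2 objective is pure vector arithmetic.
.fit_context <- function(table, spec) {
  map <- free_parameter_layout(spec)
  idx <- matrix(map$index, nrow = 5L,
                dimnames = list(.mpt_param_names, spec$conditions))
  counts <- lapply(spec$conditions, function(cond) {
    n <- table$count[table$condition == cond]
    totals <- rep(c(sum(n[1:4]), sum(n[5:8])), each = 4L)
    list(n = n, totals = totals, pos = n > 0)
  })
  list(idx = idx, counts = counts, labels = attr(map, "labels"),
       conditions = spec$conditions)
}

.g2_from_theta <- function(theta, ctx) {
  p <- .logistic(theta)
  g2 <- 0
  for (j in seq_along(ctx$conditions)) {
    probs <- .cat_probs_raw(p[ctx$idx[, j]])
    cc <- ctx$counts[[j]]
    e <- cc$totals * probs
    k <- cc$pos
    g2 <- g2 + 2 * sum(cc$n[k] * log(cc$n[k] / e[k]))
  }
  g2
}

# Moment-based starting values per condition: cell proportions inverted
# through the tree, clamped away from the boundary.
.moment_start <- function(table, spec) {
  clamp <- function(x) pmin(pmax(x, 0.02), 0.98)
  map <- free_parameter_layout(spec)
  theta <- numeric(length(attr(map, "labels")))
  for (cond in spec$conditions) {
    n <- table$count[table$condition == cond]
    tc <- sum(n[1:4]); td <- sum(n[5:8])
    C <- clamp((n[1] + n[2] + n[5] + n[6]) / max(tc + td, 1))
    b <- clamp(if (n[1] + n[2] > 0) n[1] / (n[1] + n[2]) else 0.1)
    inv <- function(num, den) {
      q <- if (den > 0) num / den else b
      clamp((q - b) / (1 - b))
    }
    vals <- c(C = C,
              P_Moral = inv(n[5], n[5] + n[6]),
              P_Hypocritical = inv(n[7], n[7] + n[8]),
              P_Antisocial = inv(n[3], n[3] + n[4]),
              b = b)
    rows <- map[map$condition == cond, ]
    theta[rows$index] <- .logit(vals[rows$parameter])
  }
  theta
}

#' Fit the cooperation-and-punishment model by maximum likelihood
#'
#' Estimates the latent parameters by minimizing the G-squared statistic
#' (equivalently, maximizing the multinomial likelihood) over the free
#' parameters, with optional equality constraints across conditions
#' implemented by parameter sharing. Optimization runs on the log-odds scale
#' (no box constraints to collide with), from a moment-based start plus
#' `n_starts - 1` deterministic random starts; the best optimum is kept,
#' ties broken by the lexicographically smallest parameter vector. Standard
#' errors come from the inverse observed information of the multinomial
#' log-likelihood at the optimum and are omitted (with a warning) when an
#' estimate lies on the boundary.
#'
#' @param table a [category_table()] covering the spec's conditions.
#' @param spec an [model_spec()]; default: unconstrained model over the
#'   table's conditions.
#' @param n_starts number of optimizer starts (first is moment-based).
#' @param start_seed seed for the random starts (deterministic fits).
#' @param reltol relative convergence tolerance on G-squared.
#' @param boundary_tol estimates closer than this to 0 or 1 are treated as
#'   boundary solutions.
#' @return An object of class `"mpt_fit"`: `estimates` (per-condition
#'   [mpt_parameters()]), `free_estimates`, `standard_errors` (per free
#'   parameter), `g2`, `df`, `p_value`, `converged`, `n_total`, `model`,
#'   and `optimizer_trace`.
#' @export
fit_mpt <- function(table, spec = NULL, n_starts = 20L, start_seed = 1L,
                    reltol = 1e-12, boundary_tol = 1e-6) {
  stopifnot(inherits(table, "category_table"))
  if (is.null(spec)) spec <- model_spec(unique(table$condition))
  miss <- setdiff(spec$conditions, unique(table$condition))
  if (length(miss)) {
    stop("table lacks condition(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (cond in spec$conditions) {
    n <- table$count[table$condition == cond]
    if (sum(n[1:4]) <= 0 || sum(n[5:8]) <= 0) {
      stop("tree totals must be positive in condition ", cond,
           call. = FALSE)
    }
  }
  ctx <- .fit_context(table, spec)
  k <- length(ctx$labels)

  starts <- list(.moment_start(table, spec))
  if (n_starts > 1L) {
    set.seed(start_seed)
    for (i in seq_len(n_starts - 1L)) {
      starts[[i + 1L]] <- stats::runif(k, -2, 2)
    }
  }

  best <- NULL
  trace <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    res <- tryCatch(
      stats::optim(starts[[i]], .g2_from_theta, ctx = ctx, method = "BFGS",
                   control = list(reltol = reltol, maxit = 1000L)),
      error = function(e) NULL)
    if (is.null(res)) {
      trace[[i]] <- list(start = i, converged = FALSE, g2 = NA_real_)
      next
    }
    trace[[i]] <- list(start = i, converged = res$convergence == 0L,
                       g2 = res$value)
    if (is.null(best) || res$value < best$value ||
        (res$value == best$value &&
         .lex_less(.logistic(res$par), .logistic(best$par)))) {
      best <- res
    }
  }
  if (is.null(best)) stop("optimization failed in all starts", call. = FALSE)

  theta <- best$par
  est_free <- .logistic(theta)
  names(est_free) <- ctx$labels
  boundary <- est_free < boundary_tol | est_free > 1 - boundary_tol
  estimates <- expand_free_parameters(est_free, spec)
  g2 <- .g2_from_theta(theta, ctx)
  df <- spec$df
  n_total <- sum(table$count)

  se <- rep(NA_real_, k)
  names(se) <- ctx$labels
  if (any(boundary)) {
    warning("estimate(s) at the boundary (",
            paste(ctx$labels[boundary], collapse = ", "),
            "); standard errors omitted", call. = FALSE)
  } else {
    negll <- function(p) {
      ll <- 0
      for (j in seq_along(ctx$conditions)) {
        probs <- .cat_probs_raw(p[ctx$idx[, j]])
        cc <- ctx$counts[[j]]
        kpos <- cc$pos
        ll <- ll + sum(cc$n[kpos] * log(probs[kpos]))
      }
      -ll
    }
    H <- tryCatch(pracma::hessian(negll, est_free), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        d <- diag(V)
        se[d > 0] <- sqrt(d[d > 0])
      }
    }
    if (anyNA(se)) {
      warning("observed information not invertible; some standard errors ",
              "missing", call. = FALSE)
    }
  }

  structure(list(model = spec,
                 estimates = estimates,
                 free_estimates = est_free,
                 standard_errors = se,
                 boundary = boundary,
                 g2 = g2,
                 df = df,
                 p_value = stats::pchisq(g2, df, lower.tail = FALSE),
                 converged = any(vapply(trace, `[[`, logical(1),
                                        "converged")),
                 n_total = n_total,
                 optimizer_trace = trace),
            class = "mpt_fit")
}

.lex_less <- function(a, b) {
  d <- a - b
  i <- which(abs(d) > 1e-12)
  length(i) > 0 && d[i[1]] < 0
}

#' @export
print.mpt_fit <- function(x, ...) {
  cat("Cooperation-and-punishment MPT fit\n")
  cat(sprintf("  G2(%d) = %.2f, p = %.3f%s\n", x$df, x$g2,
              x$p_value, if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$model$constraints)) {
    cat("  constraints:", paste(x$model$constraints, collapse = ", "), "\n")
  }
  for (cond in names(x$estimates)) {
    est <- x$estimates[[cond]]
    cat("  ", cond, ": ",
        paste(sprintf("%s = %.3f", names(unclass(est)), unclass(est)),
              collapse = ", "), "\n", sep = "")
  }
  se <- x$standard_errors
  if (!all(is.na(se))) {
    cat("  SE: ", paste(sprintf("%s = %.3f", names(se), se),
                        collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Local identifiability check via the Jacobian rank
#'
#' Computes the numerical Jacobian of the free category probabilities (three
#' per tree after the sum-to-one constraint) with respect to the free
#' parameters at a given point, and reports its rank against the number of
#' free parameters. Rank deficiency means some parameter directions leave
#' the category probabilities unchanged — those parameters are confounded at
#' that point (for example, with `C = 0` no trial mass reaches the
#' cooperate cells, so `P_Moral` is unidentifiable).
#'
#' @param spec an [model_spec()].
#' @param point a single [mpt_parameters()] (recycled) or named list per
#'   condition: the evaluation point.
#' @param tol singular values below `tol` times the largest count as rank 0.
#' @return An object of class `"identifiability_report"`: `jacobian_rank`,
#'   `expected_rank`, `deficient_directions` (labels of confounded free
#'   parameters), `evaluation_point`.
#' @export
check_identifiability <- function(spec, point, tol = 1e-7) {
  if (inherits(point, "mpt_parameters")) {
    point <- stats::setNames(rep(list(point), length(spec$conditions)),
                             spec$conditions)
  }
  map <- free_parameter_layout(spec)
  labels <- attr(map, "labels")
  theta0 <- numeric(length(labels))
  for (cond in spec$conditions) {
    rows <- map[map$condition == cond, ]
    theta0[rows$index] <- unclass(point[[cond]])[rows$parameter]
  }
  idx <- matrix(map$index, nrow = 5L,
                dimnames = list(.mpt_param_names, spec$conditions))
  freeprobs <- function(p) {
    unlist(lapply(seq_along(spec$conditions), function(j) {
      pr <- .cat_probs_raw(p[idx[, j]])
      pr[c(1:3, 5:7)]  # drop one cell per tree (sum-to-one)
    }))
  }
  J <- pracma::jacobian(freeprobs, theta0)
  sv <- svd(J)
  thresh <- max(dim(J)) * max(sv$d) * 1e-9 + tol
  rank <- sum(sv$d > thresh)
  deficient <- character()
  if (rank < length(labels)) {
    null_vecs <- sv$v[, (rank + 1L):ncol(sv$v), drop = FALSE]
    load <- sqrt(rowSums(null_vecs^2))
    deficient <- labels[load > 0.3]
  }
  structure(list(jacobian_rank = rank,
                 expected_rank = length(labels),
                 deficient_directions = deficient,
                 evaluation_point = point),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat("Identifiability: rank", x$jacobian_rank, "of", x$expected_rank, "\n")
  if (length(x$deficient_directions)) {
    cat("  confounded:", paste(x$deficient_directions, collapse = ", "),
        "\n")
  }
  invisible(x)
}
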