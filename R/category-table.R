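#' Construct a category table of response frequencies
#'
#' The sufficient statistic of the cooperation-and-punishment model: per
#' framing condition, the eight response frequencies formed by crossing the
#' partner's behavior (the two trees), the participant's choice, and whether
#' a punishment investment was made. Rows are in the fixed canonical order:
#' conditions in the given order, within condition the partner-cooperates
#' tree then the partner-defects tree, within tree the cells
#' (cooperate, punished), (cooperate, unpunished), (defect, punished),
#' (defect, unpunished).
#'
#' @param counts named list: one numeric vector of 8 counts per condition,
#'   in the canonical cell order above.
#' @return A data frame of class `"category_table"` with columns
#'   `condition`, `tree`, `choice`, `punished`, `count`.
#' @examples
#' category_table(list(moral = c(5, 95, 10, 90, 30, 70, 25, 75)))
#' @export
category_table <- function(counts) {
  stopifnot(is.list(counts), length(names(counts)) == length(counts))
  rows <- lapply(names(counts), function(cond) {
    x <- counts[[cond]]
    if (length(x) != 8L || any(x < 0) || any(!is.finite(x))) {
      stop("each condition needs 8 nonnegative counts", call. = FALSE)
    }
    data.frame(condition = cond,
               tree = rep(.mpt_trees, each = 4L),
               choice = rep(c("cooperate", "cooperate",
                              "defect", "defect"), 2L),
               punished = rep(c(TRUE, FALSE, TRUE, FALSE), 2L),
               count = as.numeric(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("category_table", "data.frame")
  out
}

#' Aggregate trial records into a category table
#'
#' Reduces a trial-level table (one row per participant and trial) to the
#' model's per-condition eight-cell frequencies. A trial counts as punished
#' when the participant's punishment investment is positive.
#'
#' @param trials data frame with columns `condition`, `partner_behavior`
#'   (`"cooperate"`/`"defect"`), `participant_choice` (same levels) and
#'   `punishment_investment` (cents, 0 = no punishment), as produced by
#'   [simulate_experiment()] or read with [read_trials()].
#' @param conditions optional ordered condition labels; defaults to the
#'   order of first appearance.
#' @return A [category_table()]; total counts equal `nrow(trials)`.
#' @export
aggregate_trials <- function(trials, conditions = NULL) {
  need <- c("condition", "partner_behavior", "participant_choice",
            "punishment_investment")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ok <- c("cooperate", "defect")
  if (nrow(trials) &&
      (!all(trials$partner_behavior %in% ok) ||
       !all(trials$participant_choice %in% ok))) {
    stop("behavior columns must be 'cooperate' or 'defect'", call. = FALSE)
  }
  if (is.null(conditions)) conditions <- unique(trials$condition)
  if (nrow(trials) && !all(trials$condition %in% conditions)) {
    stop("unknown condition label(s): ",
         paste(setdiff(unique(trials$condition), conditions), collapse = ", "),
         call. = FALSE)
  }
  counts <- lapply(conditions, function(cond) {
    sub <- trials[trials$condition == cond, , drop = FALSE]
    out <- numeric(8L)
    i <- 0L
    for (pb in ok) {       # partner cooperates tree first
      for (ch in c("cooperate", "defect")) {
        for (pun in c(TRUE, FALSE)) {
          i <- i + 1L
          out[i] <- sum(sub$partner_behavior == pb &
                        sub$participant_choice == ch &
                        (sub$punishment_investment > 0) == pun)
        }
      }
    }
    out
  })
  category_table(stats::setNames(counts, conditions))
}

#' Read/write a category table as CSV
#'
#' The on-disk format is one row per cell with columns
#' `condition,tree,choice,punished,count`, in the canonical row order.
#'
#' @param table a [category_table()].
#' @param path file path.
#' @return `write_category_table` returns `path` invisibly;
#'   `read_category_table` returns a [category_table()].
#' @export
write_category_table <- function(table, path) {
  stopifnot(inherits(table, "category_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_category_table
#' @export
read_category_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  counts <- lapply(unique(df$condition), function(cond) {
    sub <- df[df$condition == cond, ]
    key <- paste(sub$tree, sub$choice, sub$punished)
    want <- paste(rep(.mpt_trees, each = 4L),
                  rep(c("cooperate", "cooperate", "defect", "defect"), 2L),
                  rep(c(TRUE, FALSE, TRUE, FALSE), 2L))
    sub$count[match(want, key)]
  })
  category_table(stats::setNames(counts, unique(df$condition)))
}

#' @export
print.category_table <- function(x, ...) {
  cat("Category table (", length(unique(x$condition)), " condition(s), ",
      sum(x$count), " observations)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
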