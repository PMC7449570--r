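#' Per-sample cost model for sequencing and array genotyping
#'
#' Defaults: $1,000 per whole genome sequenced and current list prices per
#' array-genotyped sample (Illumina Infinium Core $49, OmniExpress $94,
#' Omni2.5 $172). Costs are held internally in integer cents so feasibility
#' boundaries are exact.
#'
#' @param seq_cost_per_sample Cost to sequence one participant.
#' @param array_cost_per_sample Named numeric vector of per-sample array
#'   costs.
#' @return Object of class `cost_model`.
#' @export
cost_model <- function(seq_cost_per_sample = 1000,
                       array_cost_per_sample = c(core = 49,
                                                 omniexpress = 94,
                                                 omni2.5 = 172)) {
  stopifnot(is.numeric(seq_cost_per_sample),
            length(seq_cost_per_sample) == 1L, seq_cost_per_sample > 0,
            is.numeric(array_cost_per_sample),
            length(array_cost_per_sample) >= 1L,
            !is.null(names(array_cost_per_sample)),
            all(array_cost_per_sample > 0))
  structure(
    list(seq_cents = as.integer(round(100 * seq_cost_per_sample)),
         array_cents = vapply(array_cost_per_sample,
                              function(x) as.integer(round(100 * x)),
                              integer(1))),
    class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf("Cost model: $%.2f per sequenced sample\n", x$seq_cents / 100))
  for (a in names(x$array_cents))
    cat(sprintf("  %s array: $%.2f per sample\n", a, x$array_cents[[a]] / 100))
  invisible(x)
}

.cost_cents <- function(n_seq, m_imp, array, costs) {
  ac <- unname(costs$array_cents[array])
  if (anyNA(ac))
    stop("unknown array label `",
         paste(array[is.na(ac)][1L]), "` in cost model (known: ",
         paste(names(costs$array_cents), collapse = ", "), ")")
  as.numeric(n_seq) * costs$seq_cents + as.numeric(m_imp) * ac
}

#' Total experimental cost of a design
#'
#' `cost = n_seq * seq_cost + m_imp * array_cost`: sequenced participants
#' incur only the sequencing cost, imputed participants only the array
#' cost. This accounting is what makes equal-cost designs fall on the line
#' `m = a - b*n` with `a = total/array_cost` and
#' `b = seq_cost/array_cost`.
#'
#' @param design A [study_design()].
#' @param costs A [cost_model()].
#' @return Cost in currency units.
#' @examples
#' total_cost(study_design(400, 11100, "core"), cost_model())
#' @export
total_cost <- function(design, costs = cost_model()) {
  stopifnot(inherits(design, "study_design"), inherits(costs, "cost_model"))
  .cost_cents(design$n_seq, design$m_imp, design$array, costs) / 100
}

#' Grid of candidate designs for the optimizer
#'
#' @param n_values Candidate numbers sequenced. Default `NULL` uses the
#'   panel sizes available in the quality tables (no interpolation).
#' @param m_max Largest number imputed to consider.
#' @param m_step Grid step for the number imputed.
#' @param m_min Smallest number imputed.
#' @param arrays Array labels to consider. Default `NULL` uses every array
#'   present in the tables.
#' @return Object of class `design_grid`.
#' @export
design_grid <- function(n_values = NULL, m_max = 20000, m_step = 50,
                        m_min = 0, arrays = NULL) {
  stopifnot(m_max >= m_min, m_step > 0, m_min >= 0)
  structure(list(n_values = n_values,
                 m_values = seq(m_min, m_max, by = m_step),
                 arrays = arrays),
            class = "design_grid")
}

# Evaluate power and cost over the whole (array, n, m) grid.
.evaluate_grid <- function(model, tables, costs, sig, grid, ...) {
  if (inherits(tables, "quality_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "quality_table")),
            inherits(grid, "design_grid"))
  arrays <- grid$arrays %||%
    unique(vapply(tables, `[[`, character(1), "array"))
  rows <- list()
  for (arr in arrays) {
    sub <- tables[vapply(tables, function(t) t$array == arr, logical(1))]
    if (!length(sub)) stop("no quality table for array `", arr, "`")
    ns <- grid$n_values %||% sort(vapply(sub, `[[`, numeric(1), "panel_n"))
    for (n in ns) {
      tab <- interpolate_panel_size(sub, n)
      for (m in grid$m_values) {
        if (n + m < 1) next
        est <- estimate_power(study_design(n, m, arr), tab, model, sig, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          array = arr, n_seq = n, m_imp = m,
          cost_cents = .cost_cents(n, m, arr, costs),
          power = est$power, p_imputable = est$p_imputable,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("empty design grid")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.opt_result <- function(frontier, objective, constraint, feasible_idx,
                        pick) {
  frontier$cost <- frontier$cost_cents / 100
  frontier$feasible <- FALSE
  frontier$feasible[feasible_idx] <- TRUE
  best <- if (length(pick)) frontier[pick, , drop = FALSE] else NULL
  structure(
    list(best = best,
         frontier = frontier[c("array", "n_seq", "m_imp", "cost", "power",
                               "p_imputable", "feasible")],
         objective = objective, constraint = constraint,
         feasible = length(pick) > 0L),
    class = "design_opt")
}

#' Cheapest design attaining a power target
#'
#' Exhaustively evaluates the design grid and returns the design of minimum
#' total cost with estimated power at or above `power_target`. Ties are
#' broken by lower cost, then fewer sequenced, then fewer imputed. If no
#' design on the grid is feasible, the result records infeasibility and the
#' maximum power found.
#'
#' @param power_target Required power in (0, 1), or 0 to ask only for the
#'   cheapest nonempty design.
#' @param model A [disease_model()].
#' @param tables [quality_table()] or list of them (multiple `panel_n`
#'   and/or arrays).
#' @param costs A [cost_model()].
#' @param sig A [sig_spec()].
#' @param grid A [design_grid()].
#' @param ... Passed to [estimate_power()].
#' @return Object of class `design_opt` with fields `best` (one-row data
#'   frame or `NULL`), `frontier` (the full evaluated grid), `objective`,
#'   `constraint`, `feasible`.
#' @export
min_cost_design <- function(power_target, model, tables,
                            costs = cost_model(), sig = sig_spec(),
                            grid = design_grid(), ...) {
  stopifnot(power_target >= 0, power_target < 1)
  fr <- .evaluate_grid(model, tables, costs, sig, grid, ...)
  feas <- which(fr$power >= power_target & (fr$n_seq + fr$m_imp) >= 1)
  pick <- if (length(feas)) {
    feas[order(fr$cost_cents[feas], fr$n_seq[feas], fr$m_imp[feas])[1L]]
  } else integer(0)
  res <- .opt_result(fr, "min_cost_at_power",
                     c(power_target = power_target), feas, pick)
  if (!res$feasible) res$max_power_found <- max(fr$power)
  res
}

#' Most powerful design within a budget
#'
#' Exhaustively evaluates the design grid and returns the design of maximum
#' estimated power among those with total cost at most `budget`
#' (inclusive). Ties are broken by lower cost, then fewer sequenced, then
#' fewer imputed.
#'
#' @param budget Budget in currency units (> 0).
#' @inheritParams min_cost_design
#' @return Object of class `design_opt` (see [min_cost_design()]).
#' @export
max_power_design <- function(budget, model, tables, costs = cost_model(),
                             sig = sig_spec(), grid = design_grid(), ...) {
  stopifnot(budget > 0)
  budget_cents <- round(100 * budget)
  fr <- .evaluate_grid(model, tables, costs, sig, grid, ...)
  feas <- which(fr$cost_cents <= budget_cents & (fr$n_seq + fr$m_imp) >= 1)
  pick <- if (length(feas)) {
    feas[order(-fr$power[feas], fr$cost_cents[feas], fr$n_seq[feas],
               fr$m_imp[feas])[1L]]
  } else integer(0)
  res <- .opt_result(fr, "max_power_at_budget", c(budget = budget), feas,
                     pick)
  if (!res$feasible) res$min_cost_found <- min(fr$cost_cents) / 100
  res
}

#' @export
print.design_opt <- function(x, ...) {
  cat("Design optimization (", x$objective, "), ",
      paste(names(x$constraint), x$constraint, sep = " = ",
            collapse = ", "), "\n", sep = "")
  if (x$feasible) {
    b <- x$best
    cat(sprintf(
      "  best: %g sequenced + %g imputed (%s), cost $%s, power %.4f\n",
      b$n_seq, b$m_imp, b$array,
      format(b$cost, big.mark = ",", scientific = FALSE), b$power))
  } else {
    cat("  no feasible design on the evaluated grid")
    if (!is.null(x$max_power_found))
      cat(sprintf(" (max power found: %.4f)", x$max_power_found))
    if (!is.null(x$min_cost_found))
      cat(sprintf(" (min cost found: $%s)",
                  format(x$min_cost_found, big.mark = ",")))
    cat("\n")
  }
  cat(sprintf("  frontier: %d designs evaluated, %d feasible\n",
              nrow(x$frontier), sum(x$frontier$feasible)))
  invisible(x)
}

#' @export
summary.design_opt <- function(object, ...) {
  print(object)
  fr <- object$frontier
  best_by_n <- do.call(rbind, lapply(split(fr, fr[c("array", "n_seq")]),
                                     function(d) d[which.max(d$power), ]))
  rownames(best_by_n) <- NULL
  cat("\nBest design per (array, n_seq):\n")
  print(best_by_n, row.names = FALSE)
  invisible(best_by_n)
}
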