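# Fixtures and an independent brute-force oracle for the design optimizer.

# small table set: imputation quality rises with panel size
opt_tables <- function() {
  mk <- function(panel_n, r2, mac) {
    make_table(maf_sample = c(0.004, 0.005, 0.006),
               mac_panel = mac, r2 = r2, panel_n = panel_n, N = 1000)
  }
  list(mk(0, c(0.5, NA, 0.4), c(10, 0, 8)),
       mk(100, c(0.7, 0.35, 0.6), c(12, 6, 10)),
       mk(200, c(0.8, 0.6, 0.7), c(15, 9, 12)))
}

# exhaustive enumeration with the same tie-break order, written without
# reference to the optimizer implementation
brute_force <- function(objective, threshold, model, tables, costs, sig,
                        grid) {
  ns <- sort(vapply(tables, `[[`, numeric(1), "panel_n"))
  cells <- expand.grid(n = ns, m = grid$m_values)
  cells <- cells[cells$n + cells$m >= 1, ]
  cells$power <- mapply(function(n, m) {
    estimate_power(study_design(n, m), tables, model, sig)$power
  }, cells$n, cells$m)
  cells$cost <- mapply(function(n, m) {
    total_cost(study_design(n, m, "core"), costs)
  }, cells$n, cells$m)
  if (objective == "min_cost") {
    feas <- cells[cells$power >= threshold, ]
    if (!nrow(feas)) return(NULL)
    feas[order(feas$cost, feas$n, feas$m), ][1, ]
  } else {
    feas <- cells[cells$cost <= threshold, ]
    if (!nrow(feas)) return(NULL)
    feas[order(-feas$power, feas$cost, feas$n, feas$m), ][1, ]
  }
}
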