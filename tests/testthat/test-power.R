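test_that("effective fraction weights the sequenced stratum", {
  expect_equal(effective_fraction(100, 0, 0.3), 1.0)
  expect_equal(effective_fraction(100, 900, 1), 0.1)
  expect_equal(effective_fraction(100, 900, 0.5), 100 / 550)
  expect_error(effective_fraction(0, 0, 0.5), "zero")
})

test_that("analytic power matches closed forms at anchor points", {
  sig <- sig_spec(5e-8)
  # null calibration: power equals alpha exactly
  expect_equal(analytic_power(0, 100, 900, 0.5, sig), 5e-8,
               tolerance = 1e-12)
  expect_equal(analytic_power(0, 0, 1000, 1, sig_spec(0.05)), 0.05,
               tolerance = 1e-12)

  # mean at the critical value: power = 0.5 + Phi(-2 z)
  neff <- 4000
  eta <- sig$z_crit / sqrt(neff)
  expect_equal(analytic_power(eta, 0, neff, 1, sig),
               0.5 + pnorm(-2 * sig$z_crit), tolerance = 1e-15)

  # frozen normal-CDF evaluation
  expect_equal(analytic_power(0.04, 10000, 0, 1, sig), 0.07334671805254299,
               tolerance = 1e-10)
  # same effective sample size through imputation
  expect_equal(analytic_power(0.04, 0, 20000, 0.5, sig),
               analytic_power(0.04, 10000, 0, 1, sig), tolerance = 1e-15)
})

test_that("analytic power agrees with numerical integration of the integrand", {
  sig <- sig_spec(1e-4)
  for (eta in c(0, 0.02, 0.08)) {
    for (neff in c(500, 5000)) {
      lam <- eta * sqrt(neff)
      acc <- integrate(function(u) dnorm(u - lam), -sig$z_crit, sig$z_crit,
                       rel.tol = 1e-12, abs.tol = 1e-13,
                       subdivisions = 1000L)
      expect_equal(analytic_power(eta, neff, 0, 1, sig), 1 - acc$value,
                   tolerance = 1e-8)
    }
  }
})

test_that("imputability requires panel MAC >= 5 and observed r2 >= 0.3", {
  expect_true(is_imputable(5, 0.30))
  expect_false(is_imputable(4, 0.9))
  expect_false(is_imputable(1000, NA_real_))
  expect_false(is_imputable(5, 0.2999))
  # strict-inequality variant excludes the boundary
  expect_false(is_imputable(5, 0.30, strict_r2 = TRUE))
  expect_true(is_imputable(5, 0.31, strict_r2 = TRUE))
  # data-frame interface
  df <- data.frame(mac_panel = c(5, 4), r2 = c(0.3, 0.9))
  expect_identical(is_imputable(df), c(TRUE, FALSE))
})

test_that("MAC weights divide model pmf by the empirical histogram", {
  dm <- disease_model(0.005, 1, 0.01)
  pmf <- sample_mac_pmf(dm, N = 1000)  # Poisson mean 10
  hist <- c("10" = 0.5, "20" = 0.5)
  w <- maf_weight(c(10, 20), pmf, hist)
  expect_equal(w, c(dpois(10, 10) / 0.5, dpois(20, 10) / 0.5))
  expect_error(maf_weight(15, pmf, hist), "absent")
  # far-tail MAC under a rare-variant model: weight essentially zero
  w_tail <- maf_weight(300, pmf, c("300" = 1))
  expect_lt(w_tail, 1e-12)

  # self-weighting: empirical distribution equal to the model pmf gives
  # constant unit weights
  tab <- make_table(maf_sample = pmf$mac[6:30] / 2000, mac_panel = 10,
                    r2 = 0.5, weight = pmf$prob[6:30], N = 1000)
  h <- empirical_maf_hist(tab)
  w <- maf_weight(as.integer(names(h)), pmf, h)
  expect_equal(w, rep(sum(tab$records$weight), length(w)), tolerance = 1e-9)
})

test_that("population-specificity weights follow the two-branch ratio", {
  expect_equal(ps_weight(c(TRUE, FALSE), 0.6, c(0.6, 0.6)), c(1, 1))
  expect_equal(ps_weight(TRUE, 0.6, 0.3), 2.0)
  expect_equal(ps_weight(FALSE, 0.6, 0.2), 0.5)
  # impossible variants (empirical fraction 0/1 with opposite flag) get
  # weight zero with a warning
  expect_warning(w <- ps_weight(c(TRUE, FALSE), 0.5, c(0, 1)),
                 "impossible")
  expect_equal(w, c(0, 0))
})

test_that("estimate_power reduces correctly on degenerate tables", {
  dm <- disease_model(0.005, 4, 0.01)
  sig <- sig_spec(5e-8)

  # nothing imputable: power and bound both zero
  tab <- make_table(maf_sample = rep(0.004, 3), mac_panel = c(0, 4, 10),
                    r2 = c(NA, 0.9, 0.1), N = 1000)
  est <- estimate_power(study_design(0, 5000), tab, dm, sig)
  expect_equal(est$power, 0)
  expect_equal(est$p_imputable, 0)

  # single imputable record: estimator reduces to the analytic power at
  # that record's r2
  tab1 <- make_table(maf_sample = 0.004, mac_panel = 50, r2 = 0.7, N = 1000)
  est1 <- estimate_power(study_design(0, 5000), tab1, dm, sig)
  eta <- effect_size(dm)$eta
  expect_equal(est1$power, analytic_power(eta, 0, 5000, 0.7, sig),
               tolerance = 1e-12)
  expect_equal(est1$p_imputable, 1)
  expect_equal(est1$n_effective, 0.7 * 5000)
})

test_that("estimate_power combines per-variant power by the weighted sum", {
  dm <- disease_model(0.005, 4, 0.01)
  sig <- sig_spec(5e-8)
  # identical MAF/flag so MAC and PS weights cancel; the weight column
  # carries relative weights 1:3; second variant absent from the panel
  tab <- make_table(maf_sample = c(0.004, 0.004), mac_panel = c(50, 0),
                    r2 = c(1.0, NA), weight = c(1, 3), N = 1000)
  est <- estimate_power(study_design(0, 4000), tab, dm, sig)
  p1 <- analytic_power(effect_size(dm)$eta, 0, 4000, 1.0, sig)
  expect_equal(est$power, p1 / 4, tolerance = 1e-12)
  expect_equal(est$p_imputable, 0.25, tolerance = 1e-12)
  expect_lte(est$power, est$p_imputable)
})

test_that("estimate_power rejects incompatible tables and models", {
  dm <- disease_model(0.005, 4, 0.01)
  # table MACs far above anything plausible at this MAF: zero total weight
  tab <- make_table(maf_sample = rep(0.45, 4), mac_panel = 50, r2 = 0.9,
                    N = 1000)
  expect_error(estimate_power(study_design(0, 1000), tab, dm),
               "incompatibility|zero")
  # panel size mismatch without a table list to interpolate
  tab2 <- make_table(maf_sample = 0.004, mac_panel = 50, r2 = 0.7,
                     panel_n = 500, N = 1000)
  expect_error(estimate_power(study_design(200, 1000), tab2, dm),
               "panel_n")
})

test_that("null model gives power alpha times the imputable probability", {
  dm0 <- disease_model(0.01, 1, 0.01)
  for (alpha in c(0.05, 5e-8)) {
    sig <- sig_spec(alpha)
    set.seed(41)
    for (i in 1:5) {
      tab <- random_table(nv = 25)
      est <- suppressWarnings(
        estimate_power(study_design(0, 3000), tab, dm0, sig))
      expect_equal(est$power, alpha * est$p_imputable, tolerance = 1e-10)
    }
  }
})

test_that("power is monotone in m, n, effect size, and r2", {
  sig <- sig_spec(5e-8)
  tab <- make_table(maf_sample = c(0.004, 0.006, 0.01),
                    mac_panel = c(50, 8, 0), r2 = c(0.9, 0.45, NA), N = 1000)
  dm <- disease_model(0.005, 2, 0.01)
  pw <- function(n, m, model = dm, t = tab)
    estimate_power(study_design(n, m), t, model, sig)$power

  m_grid <- seq(1000, 50000, by = 7000)
  expect_true(all(diff(vapply(m_grid, function(m) pw(0, m), numeric(1))) >= 0))

  # increasing rr increases power (single-record table keeps the variant
  # weights fixed while the effect size grows)
  tab1 <- make_table(maf_sample = 0.004, mac_panel = 50, r2 = 0.7, N = 1000)
  rrs <- c(1, 1.5, 2, 3, 4)
  expect_true(all(diff(vapply(rrs, function(g)
    pw(0, 20000, disease_model(0.005, g, 0.01), tab1), numeric(1))) >= 0))

  # record-wise r2 perturbation increases power
  tab_hi <- make_table(maf_sample = c(0.004, 0.006, 0.01),
                       mac_panel = c(50, 8, 0), r2 = c(0.95, 0.5, NA),
                       N = 1000)
  expect_gte(pw(0, 20000, t = tab_hi), pw(0, 20000))
})

test_that("power_curve sweeps designs and respects the imputable asymptote", {
  sig <- sig_spec(5e-8)
  dm <- disease_model(0.005, 4, 0.01)
  tabs <- generate_quality_tables(
    quality_gen_config(n_variants = 300, panel_sizes = c(0, 500, 2000),
                       arrays = c(core = 0.9)), seed = 9)

  # single design equals estimate_power
  one <- power_curve(list(study_design(0, 5000, "core")), tabs, dm, sig)
  est <- estimate_power(study_design(0, 5000, "core"), tabs[["core_n0"]],
                        dm, sig)
  expect_equal(one$power, est$power)
  expect_equal(nrow(one), 1L)

  designs <- expand.grid(n_seq = c(0, 500, 2000),
                         m_imp = c(2000, 10000, 50000, 1e7))
  designs$array <- "core"
  pc <- power_curve(designs, tabs, dm, sig)
  expect_true(all(pc$power <= pc$p_imputable + 1e-12))
  for (n in c(0, 500, 2000)) {
    sub <- pc[pc$n_seq == n, ]
    expect_true(all(diff(sub$power) >= 0))
    # power plateaus at the imputable-probability bound as m grows
    expect_equal(sub$power[sub$m_imp == 1e7],
                 sub$p_imputable[sub$m_imp == 1e7], tolerance = 1e-9)
  }
  # more sequenced individuals never hurt at fixed m here (richer panel)
  sub_m <- pc[pc$m_imp == 50000, ]
  expect_true(all(diff(sub_m$power[order(sub_m$n_seq)]) >= -1e-12))
})
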