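#' Specify a two-stage GWAS design
#'
#' @param n_seq Number of participants whole-genome sequenced (these also
#'   augment the imputation reference panel).
#' @param m_imp Number of participants array-genotyped and imputed.
#' @param array Genotyping array label (e.g. `"core"`, `"omniexpress"`,
#'   `"omni2.5"`).
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_seq, m_imp, array = "core") {
  stopifnot(is.numeric(n_seq), is.numeric(m_imp), length(n_seq) == 1L,
            length(m_imp) == 1L, n_seq >= 0, m_imp >= 0)
  if (n_seq + m_imp < 1)
    stop("a design must include at least one participant")
  structure(list(n_seq = n_seq, m_imp = m_imp, array = as.character(array)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Design: %g sequenced + %g imputed (%s array)\n",
              x$n_seq, x$m_imp, x$array))
  invisible(x)
}

#' Sequenced fraction of the effective sample size
#'
#' In the effective-sample-size weighted meta-analysis of the sequenced and
#' imputed subsamples, the sequenced stratum carries weight
#' `c = n / (n + r2 * m)`: imputed samples count in proportion to their
#' imputation r-squared.
#'
#' @param n Number sequenced.
#' @param m Number imputed.
#' @param r2 Imputation r-squared in `[0, 1]`.
#' @return `c` in `[0, 1]`.
#' @export
effective_fraction <- function(n, m, r2) {
  stopifnot(n >= 0, m >= 0, all(r2 >= 0 & r2 <= 1))
  if (n == 0 && m == 0) stop("n and m cannot both be zero")
  denom <- n + r2 * m
  if (any(denom <= 0))
    stop("effective sample size n + r2*m must be positive")
  n / denom
}

#' Analytic power of the combined sequencing + imputation test
#'
#' The combined statistic `Z = sqrt(c) Z_seq + sqrt(1-c) Z_imp` is
#' asymptotically normal with unit variance and mean
#' `lambda = eta * sqrt(n + r2 * m)`. Two-sided power at level `alpha` is
#' \deqn{1 - [\Phi(z_{1-\alpha/2} - \lambda) - \Phi(-z_{1-\alpha/2} - \lambda)]
#'   = \Phi(\lambda - z_{1-\alpha/2}) + \Phi(-\lambda - z_{1-\alpha/2}).}
#'
#' @param eta Effect size per sqrt(sample) (see [effect_size()]).
#' @param n,m Numbers sequenced and imputed.
#' @param r2 Imputation r-squared (vectorized).
#' @param sig A [sig_spec()].
#' @return Power in `[0, 1]`, same length as `r2`.
#' @examples
#' analytic_power(0.04, n = 0, m = 10000, r2 = 1, sig = sig_spec(5e-8))
#' @export
analytic_power <- function(eta, n, m, r2, sig = sig_spec()) {
  stopifnot(inherits(sig, "sig_spec"), n >= 0, m >= 0,
            all(r2 >= 0 & r2 <= 1))
  lambda <- eta * sqrt(n + r2 * m)
  stats::pnorm(lambda - sig$z_crit) + stats::pnorm(-lambda - sig$z_crit)
}

#' Is a variant imputable?
#'
#' A variant is imputable when its reference-panel minor allele count is at
#' least `mac_min` (default 5, the panel's own inclusion threshold) and its
#' imputation r-squared is present and at least `r2_min` (default 0.3).
#' Variants absent from the panel (missing r-squared) are never imputable.
#' Power for non-imputable variants is taken to be zero.
#'
#' @param x Either a data frame with columns `mac_panel` and `r2` (e.g.
#'   `quality_table$records`), or a numeric vector of panel MACs.
#' @param r2 Numeric vector of r-squared values (ignored when `x` is a data
#'   frame).
#' @param mac_min Panel MAC threshold (inclusive).
#' @param r2_min r-squared threshold.
#' @param strict_r2 If `TRUE`, require `r2 > r2_min` instead of `>=`. Ties
#'   at the threshold are measure-zero in real data; the default follows
#'   the indicator definition `I(MAC >= 5, r2 >= 0.3)`.
#' @return Logical vector.
#' @export
is_imputable <- function(x, r2 = NULL, mac_min = 5, r2_min = 0.3,
                         strict_r2 = FALSE) {
  if (is.data.frame(x)) {
    mac_panel <- x$mac_panel
    r2 <- x$r2
  } else {
    mac_panel <- x
    if (is.null(r2)) stop("supply `r2` when `x` is not a data frame")
  }
  ok_r2 <- if (strict_r2) !is.na(r2) & r2 > r2_min else !is.na(r2) & r2 >= r2_min
  mac_panel >= mac_min & ok_r2
}

#' MAC weight for a variant
#'
#' Ratio of the model-implied probability of the variant's sample minor
#' allele count (Poisson, [sample_mac_pmf()]) to its empirical proportion
#' among the table's variants ([empirical_maf_hist()]). Reweights the
#' empirical variant set to look like draws of a variant with the disease
#' model's population MAF and effect size.
#'
#' @param mac_sample Sample MAC(s) of the variant(s).
#' @param pmf A `mac_pmf` from [sample_mac_pmf()] (numerator).
#' @param hist Named proportions from [empirical_maf_hist()] (denominator).
#' @return Non-negative weight(s).
#' @export
maf_weight <- function(mac_sample, pmf, hist) {
  stopifnot(inherits(pmf, "mac_pmf"))
  emp <- hist[as.character(mac_sample)]
  if (anyNA(emp))
    stop("sample MAC ", mac_sample[which(is.na(emp))[1L]],
         " absent from the empirical MAC histogram (inconsistent table)")
  # beyond the pmf truncation point the Poisson mass is < 1e-12: zero weight
  num <- ifelse(mac_sample <= max(pmf$mac), pmf$prob[mac_sample + 1L], 0)
  as.numeric(num / emp)
}

#' Population-specificity weight for a variant
#'
#' Adjusts variant weights so that the share of population-specific
#' variants matches the probability that a variant with the disease model's
#' population MAF `p` is population-specific:
#' `P_PS(p)/P_PS(p_hat)` for population-specific variants and
#' `(1-P_PS(p))/(1-P_PS(p_hat))` otherwise, where `P_PS` is the empirical
#' fraction by MAF bin.
#'
#' If the empirical fraction at the variant's own MAF is 0 (or 1) while the
#' variant is (is not) population-specific, the ratio is undefined; such
#' variants are impossible under the empirical model and get weight 0, with
#' a warning.
#'
#' @param pop_specific Logical vector: is each variant population-specific?
#' @param ps_p Empirical PS fraction at the model's population MAF.
#' @param ps_phat Empirical PS fraction(s) at the variants' own sample MAF.
#' @return Non-negative weight(s).
#' @export
ps_weight <- function(pop_specific, ps_p, ps_phat) {
  stopifnot(is.logical(pop_specific), ps_p >= 0, ps_p <= 1,
            all(ps_phat >= 0 & ps_phat <= 1))
  num <- ifelse(pop_specific, ps_p, 1 - ps_p)
  den <- ifelse(pop_specific, ps_phat, 1 - ps_phat)
  w <- num / den
  bad <- den == 0
  if (any(bad)) {
    warning(sum(bad), " variant(s) impossible under the empirical ",
            "population-specificity model (division by zero); weight set to 0")
    w[bad] <- 0
  }
  w
}

#' Empirically weighted power estimate for a two-stage design
#'
#' Estimates power to detect a variant with the disease model's population
#' MAF and relative risk, in a design with `n_seq` participants sequenced
#' and `m_imp` imputed, by averaging per-variant analytic power over the
#' empirical imputation-quality table:
#' \deqn{\widehat{Power} = \frac{\sum_j w_j C_j \, P(\eta, n, m, r^2_j)}
#'   {\sum_j w_j},}
#' with weights `w_j` the product of the MAC weight ([maf_weight()]), the
#' population-specificity weight ([ps_weight()]) and any row multiplicity,
#' and `C_j` the imputability indicator ([is_imputable()]). Non-imputable
#' variants contribute zero power but keep their weight in the denominator,
#' so the weighted imputable probability
#' `p_imputable = sum(w_j C_j) / sum(w_j)` is an upper bound on power.
#'
#' @param design A [study_design()]; `design$n_seq` must equal the table's
#'   `panel_n` (supply a list of tables to interpolate, see
#'   [interpolate_panel_size()]).
#' @param table A [quality_table()], or a list of them at different
#'   `panel_n` (interpolated to `design$n_seq`).
#' @param model A [disease_model()].
#' @param sig A [sig_spec()].
#' @param gwas_N Sample size used for the Poisson numerator of the MAC
#'   weight. Default `"table"` uses the quality table's own evaluation `N`
#'   (numerator and denominator then refer to the same sample size);
#'   alternatively a number, e.g. the planned GWAS size `n_seq + m_imp`.
#' @param ps_bins MAF bins for the population-specificity fractions. If the
#'   bin containing the model's population MAF holds no table variants, the
#'   table-wide population-specific fraction is used instead.
#' @param strict_r2 Passed to [is_imputable()].
#' @return Object of class `power_estimate`: list with `power`,
#'   `p_imputable`, `n_effective` (`n + mean-imputable-r2 * m`),
#'   `n_variants_used`, and the echoed `design`, `model`, `alpha`.
#' @examples
#' tab <- quality_table(
#'   data.frame(variant_id = c("a", "b"), maf_sample = c(0.004, 0.005),
#'              mac_panel = c(20, 2), r2 = c(0.8, NA),
#'              pop_specific = c(FALSE, FALSE)),
#'   population = "pop", array = "core", panel_n = 0, N = 1000)
#' estimate_power(study_design(0, 5000, "core"), tab,
#'                disease_model(0.005, 4, 0.01))
#' @export
estimate_power <- function(design, table, model, sig = sig_spec(),
                           gwas_N = "table",
                           ps_bins = default_maf_bins(
                             c(0, 0.001, 0.0025, 0.005, 0.05, 0.5)),
                           strict_r2 = FALSE) {
  stopifnot(inherits(design, "study_design"), inherits(model, "disease_model"),
            inherits(sig, "sig_spec"))
  if (is.list(table) && !inherits(table, "quality_table"))
    table <- interpolate_panel_size(table, design$n_seq)
  stopifnot(inherits(table, "quality_table"))
  if (table$panel_n != design$n_seq)
    stop("quality table panel_n (", table$panel_n, ") does not match ",
         "design n_seq (", design$n_seq, "); supply a list of tables to ",
         "interpolate")
  rec <- table$records
  N_num <- if (identical(gwas_N, "table")) table$N else as.numeric(gwas_N)
  pmf <- sample_mac_pmf(model, N = N_num)
  hist <- empirical_maf_hist(table)
  w_maf <- maf_weight(rec$mac_sample, pmf, hist)
  ps <- empirical_ps_fraction(table, bins = ps_bins)
  ps_p <- .ps_lookup(ps, model$p)
  if (is.na(ps_p)) {
    # no table variant shares the model's MAF bin: fall back to the
    # table-wide population-specific fraction
    ps_p <- stats::weighted.mean(rec$pop_specific, rec$weight)
  }
  ps_phat <- vapply(rec$maf_sample, function(q) .ps_lookup(ps, q), numeric(1))
  if (anyNA(ps_phat))
    stop("some variants' sample MAF is not covered by the ",
         "population-specificity bins")
  w_ps <- ps_weight(rec$pop_specific, ps_p, ps_phat)
  w <- w_maf * w_ps * rec$weight
  wsum <- sum(w)
  if (wsum <= 0)
    stop("total variant weight is zero: no variant in the table is ",
         "plausible at population MAF ", model$p, " under this disease ",
         "model (MAF/model incompatibility)")
  C <- is_imputable(rec, strict_r2 = strict_r2)
  eta <- effect_size(model)$eta
  r2 <- ifelse(is.na(rec$r2), 0, rec$r2)
  pw <- analytic_power(eta, design$n_seq, design$m_imp, r2, sig)
  power <- sum(w * C * pw) / wsum
  p_imp <- sum(w * C) / wsum
  r2_bar <- if (any(C & w > 0)) sum(w * C * r2) / sum(w * C) else 0
  structure(
    list(power = power, p_imputable = p_imp,
         n_effective = design$n_seq + r2_bar * design$m_imp,
         n_variants_used = sum(w > 0),
         design = design, model = model, alpha = sig$alpha),
    class = "power_estimate"
  )
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf(
    "Estimated power: %.4f (imputable probability bound %.4f)\n",
    x$power, x$p_imputable))
  cat(sprintf("  design: n_seq = %g, m_imp = %g (%s); alpha = %g\n",
              x$design$n_seq, x$design$m_imp, x$design$array, x$alpha))
  cat(sprintf("  effective sample size n + mean(r2)*m = %.1f over %d variants\n",
              x$n_effective, x$n_variants_used))
  invisible(x)
}

#' Power across a set of designs
#'
#' Applies [estimate_power()] over a list of designs, returning a table
#' suitable for power-versus-sample-size curves. Designs whose `n_seq`
#' falls between available panel sizes are interpolated.
#'
#' @param designs List of [study_design()] objects, or a data frame with
#'   columns `n_seq`, `m_imp` and optionally `array`.
#' @param tables A [quality_table()] or list of them (several `panel_n`
#'   and/or arrays).
#' @param model A [disease_model()].
#' @param sig A [sig_spec()].
#' @param costs Optional [cost_model()]; adds a `cost` column.
#' @param ... Passed to [estimate_power()].
#' @return Data frame of class `power_curve` with columns `n_seq`, `m_imp`,
#'   `array`, `power`, `p_imputable` (and `cost`), sorted by `(n_seq,
#'   m_imp)`.
#' @export
power_curve <- function(designs, tables, model, sig = sig_spec(),
                        costs = NULL, ...) {
  if (is.data.frame(designs)) {
    arr <- designs$array %||% "core"
    designs <- mapply(study_design, designs$n_seq, designs$m_imp, arr,
                      SIMPLIFY = FALSE)
  }
  stopifnot(length(designs) >= 1L,
            all(vapply(designs, inherits, logical(1), "study_design")))
  if (inherits(tables, "quality_table")) tables <- list(tables)
  rows <- lapply(designs, function(d) {
    sub <- tables[vapply(tables, function(t) t$array == d$array, logical(1))]
    if (!length(sub))
      stop("no quality table for array `", d$array, "`")
    est <- estimate_power(d, sub, model, sig, ...)
    out <- data.frame(n_seq = d$n_seq, m_imp = d$m_imp, array = d$array,
                      power = est$power, p_imputable = est$p_imputable)
    if (!is.null(costs)) out$cost <- total_cost(d, costs)
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$n_seq, out$m_imp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Plot power as a function of the number imputed
#'
#' One line per number sequenced, with the imputable-probability upper
#' bound shown dashed; the asymptote of each power curve as the number
#' imputed grows.
#'
#' @param x A `power_curve`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.power_curve <- function(x, ...) {
  ns <- sort(unique(x$n_seq))
  ms <- sort(unique(x$m_imp))
  pw <- sapply(ns, function(n) {
    sub <- x[x$n_seq == n, ]
    sub$power[match(ms, sub$m_imp)]
  })
  graphics::matplot(ms, pw, type = "l", lty = 1, lwd = 2,
                    xlab = "participants imputed (m)",
                    ylab = "power", ylim = c(0, 1), ...)
  bound <- sapply(ns, function(n) {
    sub <- x[x$n_seq == n, ]
    sub$p_imputable[match(ms, sub$m_imp)]
  })
  graphics::matlines(ms, bound, lty = 2, lwd = 1)
  graphics::legend("bottomright", legend = paste("n_seq =", ns),
                   col = seq_along(ns), lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
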