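#' Specify a genetic disease model for a case-control GWAS
#'
#' Bundles the parameters of a single-variant multiplicative disease model:
#' population minor allele frequency, per-allele relative risk, disease
#' prevalence, and the case:control ratio of the planned study. All power
#' and weighting computations in the package start from this object.
#'
#' @param maf Population minor allele frequency `p` (conventionally in
#'   `[0, 0.5]`; any value in `[0, 1]` is accepted).
#' @param rr Per-allele relative risk `gamma` (> 0); `rr = 1` is the null.
#' @param prevalence Disease prevalence `K` in the population, in (0, 1).
#' @param case_control_ratio Cases per control `s` (> 0); `s = 1` means a
#'   balanced study.
#' @param model Association model tag; only `"multiplicative"` is supported.
#'
#' @return An object of class `disease_model`: a list with elements
#'   `p`, `gamma`, `K`, `s`, `model`.
#'
#' @details Under the multiplicative model with Hardy-Weinberg genotypes,
#' disease risk given `g` copies of the risk allele is proportional to
#' `gamma^g`. Case and control allele frequencies follow in closed form;
#' see [case_control_freqs()].
#'
#' @examples
#' dm <- disease_model(maf = 0.005, rr = 4, prevalence = 0.01)
#' case_control_freqs(dm)
#' effect_size(dm)
#' @export
disease_model <- function(maf, rr, prevalence, case_control_ratio = 1,
                          model = "multiplicative") {
  stopifnot(is.numeric(maf), length(maf) == 1L, is.finite(maf),
            is.numeric(rr), length(rr) == 1L, is.finite(rr),
            is.numeric(prevalence), length(prevalence) == 1L,
            is.numeric(case_control_ratio), length(case_control_ratio) == 1L)
  if (maf < 0 || maf > 1)
    stop("`maf` must be in [0, 1], got ", maf)
  if (rr <= 0)
    stop("`rr` (relative risk) must be > 0, got ", rr)
  if (prevalence <= 0 || prevalence >= 1)
    stop("`prevalence` must be in (0, 1), got ", prevalence)
  if (case_control_ratio <= 0)
    stop("`case_control_ratio` must be > 0, got ", case_control_ratio)
  model <- match.arg(model, "multiplicative")
  structure(
    list(p = maf, gamma = rr, K = prevalence, s = case_control_ratio,
         model = model),
    class = "disease_model"
  )
}

#' @export
print.disease_model <- function(x, ...) {
  cat("Disease model (", x$model, ")\n", sep = "")
  cat(sprintf("  population MAF      p = %g\n", x$p))
  cat(sprintf("  relative risk   gamma = %g\n", x$gamma))
  cat(sprintf("  prevalence          K = %g\n", x$K))
  cat(sprintf("  case:control ratio  s = %g\n", x$s))
  invisible(x)
}

#' Case and control allele frequencies under the disease model
#'
#' Computes the risk-allele frequency among cases,
#' `p_case = p*gamma / (1 + p*(gamma - 1))`, and among controls,
#' `p_control = (p - K*p_case) / (1 - K)`, so that the law of total
#' probability `K*p_case + (1 - K)*p_control = p` holds exactly.
#'
#' @param model A [disease_model()].
#' @return Named numeric vector `c(p_case = ..., p_control = ...)`.
#' @examples
#' case_control_freqs(disease_model(0.005, 4, 0.01))
#' @export
case_control_freqs <- function(model) {
  stopifnot(inherits(model, "disease_model"))
  p <- model$p; g <- model$gamma; K <- model$K
  p_case <- if (p == 0) 0 else p * g / (1 + p * (g - 1))
  p_control <- (p - K * p_case) / (1 - K)
  if (p_control < 0)
    stop("inconsistent disease model: implied control allele frequency is ",
         "negative (prevalence K = ", K, " too large for maf = ", p,
         ", rr = ", g, ")")
  c(p_case = p_case, p_control = p_control)
}

#' Genotype variances within cases and controls
#'
#' Additive-coded (0/1/2) genotype variance `2q(1-q)` within each disease
#' group, assuming Hardy-Weinberg proportions within the group at its own
#' allele frequency. Under the multiplicative model this holds exactly for
#' cases and controls.
#'
#' @param p_case Risk-allele frequency in cases.
#' @param p_control Risk-allele frequency in controls.
#' @return Named numeric vector `c(v_case = ..., v_control = ...)`.
#' @export
genotype_variances <- function(p_case, p_control) {
  stopifnot(p_case >= 0, p_case <= 1, p_control >= 0, p_control <= 1)
  c(v_case = 2 * p_case * (1 - p_case),
    v_control = 2 * p_control * (1 - p_control))
}

#' Standardized effect size for the two-stage association statistic
#'
#' Computes the per-sqrt(sample) effect size
#' \deqn{\eta = \frac{2(p_{case} - p_{control})}
#'   {\sqrt{(1+s)(v_{case} + v_{control}/s) + 4(p_{case}-p_{control})^2}}}
#' so that the allele-based association Z statistic (difference of mean
#' genotype between cases and controls, standardized by the pooled
#' combined-sample variance) has asymptotic mean `eta * sqrt(n_effective)`
#' in a study with effective sample size `n_effective` and case:control
#' ratio `s`. The squared value `eta^2` is the per-sample noncentrality of
#' the corresponding 1-df chi-squared test.
#'
#' @param model A [disease_model()].
#' @return An object of class `effect_size`: list with `p_case`,
#'   `p_control`, `v_case`, `v_control`, `eta`, `ncp_unit` (= `eta^2`).
#' @examples
#' effect_size(disease_model(0.005, 4, 0.01))
#' @export
effect_size <- function(model) {
  stopifnot(inherits(model, "disease_model"))
  fr <- case_control_freqs(model)
  v <- genotype_variances(fr[["p_case"]], fr[["p_control"]])
  s <- model$s
  d <- fr[["p_case"]] - fr[["p_control"]]
  denom2 <- (1 + s) * (v[["v_case"]] + v[["v_control"]] / s) + 4 * d^2
  eta <- if (denom2 <= 0) 0 else 2 * d / sqrt(denom2)
  structure(
    list(p_case = fr[["p_case"]], p_control = fr[["p_control"]],
         v_case = v[["v_case"]], v_control = v[["v_control"]],
         eta = eta, ncp_unit = eta^2),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  cat("Effect size (allele-based association)\n")
  cat(sprintf("  p_case = %.6g   p_control = %.6g\n", x$p_case, x$p_control))
  cat(sprintf("  v_case = %.6g   v_control = %.6g\n", x$v_case, x$v_control))
  cat(sprintf("  eta = %.6g   (per-sample NCP eta^2 = %.6g)\n",
              x$eta, x$ncp_unit))
  invisible(x)
}

#' Significance specification for a two-sided association test
#'
#' @param alpha Two-sided significance level in (0, 1). Default is the
#'   conventional genome-wide threshold 5e-8.
#' @return Object of class `sig_spec`: list with `alpha` and
#'   `z_crit = qnorm(1 - alpha/2)`.
#' @export
sig_spec <- function(alpha = 5e-8) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  # upper-tail form keeps full precision at genome-wide alpha levels
  structure(list(alpha = alpha,
                 z_crit = stats::qnorm(alpha / 2, lower.tail = FALSE)),
            class = "sig_spec")
}

#' @export
print.sig_spec <- function(x, ...) {
  cat(sprintf("Two-sided significance: alpha = %g, z_crit = %.5f\n",
              x$alpha, x$z_crit))
  invisible(x)
}

#' Distribution of the sample minor allele count under the disease model
#'
#' In a case-control GWAS of total size `N` with `s` cases per control, the
#' sample MAC (`2N` times the sample MAF) of a variant with population MAF
#' `p` is approximately Poisson with mean
#' `2N (s*p_case + p_control) / (s + 1)`. The returned pmf is truncated at
#' the point where the cumulative mass reaches `1 - 1e-12`, giving a finite
#' support for downstream weighting.
#'
#' @param model A [disease_model()].
#' @param N Total GWAS sample size (integer >= 1).
#' @return Object of class `mac_pmf`: list with `mean`, integer vector
#'   `mac` (support `0:kmax`), and `prob` of the same length.
#' @examples
#' pmf <- sample_mac_pmf(disease_model(0.005, 4, 0.01), N = 3412)
#' pmf$mean
#' @export
sample_mac_pmf <- function(model, N) {
  stopifnot(inherits(model, "disease_model"),
            is.numeric(N), length(N) == 1L, N >= 1, N == round(N))
  fr <- case_control_freqs(model)
  s <- model$s
  mu <- 2 * N * (s * fr[["p_case"]] + fr[["p_control"]]) / (s + 1)
  kmax <- stats::qpois(1 - 1e-12, mu)
  # qpois can undershoot the requested tail mass by a step; extend if needed
  while (stats::ppois(kmax, mu) < 1 - 1e-12) kmax <- kmax + 1L
  mac <- 0:kmax
  structure(list(mean = mu, mac = mac, prob = stats::dpois(mac, mu)),
            class = "mac_pmf")
}

#' @export
print.mac_pmf <- function(x, ...) {
  cat(sprintf("Sample-MAC pmf: Poisson(mean = %.4f), support 0..%d\n",
              x$mean, max(x$mac)))
  invisible(x)
}

# Exact sample-MAC distribution as a convolution of the case and control
# binomials (allele counts), minor-allele folded. Used as the oracle for
# the Poisson approximation; exported because tests and diagnostics use it.

#' Exact sample minor-allele-count distribution
#'
#' The exact distribution of the sample MAC in a case-control study: the
#' allele count is the sum of independent binomials
#' `Bin(2*n_case, p_case) + Bin(2*n_control, p_control)`, folded to the
#' minor allele. Serves as the reference against which the Poisson
#' approximation of [sample_mac_pmf()] is assessed.
#'
#' @inheritParams sample_mac_pmf
#' @return Object of class `mac_pmf` (exact, not Poisson); `mean` is the
#'   exact mean of the folded count.
#' @export
exact_mac_pmf <- function(model, N) {
  stopifnot(inherits(model, "disease_model"),
            is.numeric(N), length(N) == 1L, N >= 1, N == round(N))
  fr <- case_control_freqs(model)
  s <- model$s
  n_case <- round(N * s / (1 + s))
  n_control <- N - n_case
  a_case <- 0:(2 * n_case)
  pa <- stats::dbinom(a_case, 2 * n_case, fr[["p_case"]])
  a_ctrl <- 0:(2 * n_control)
  pb <- stats::dbinom(a_ctrl, 2 * n_control, fr[["p_control"]])
  # trim negligible tails before convolving
  keep_a <- pa > 1e-16; keep_b <- pb > 1e-16
  pa <- pa[keep_a]; a_case <- a_case[keep_a]
  pb <- pb[keep_b]; a_ctrl <- a_ctrl[keep_b]
  total <- outer(a_case, a_ctrl, `+`)
  prob <- outer(pa, pb)
  count <- pmin(total, 2 * N - total)  # fold to minor allele
  agg <- tapply(prob, count, sum)
  mac <- as.integer(names(agg))
  pr <- as.numeric(agg) / sum(prob)
  structure(list(mean = sum(mac * pr), mac = mac, prob = pr),
            class = "mac_pmf")
}
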