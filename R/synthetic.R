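# Run expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic imputation-quality generator
#'
#' Describes a synthetic population and imputation experiment whose quality
#' tables have the qualitative structure of real augmented-panel
#' experiments: per-variant imputation r-squared increases with the number
#' of population-matched sequenced individuals in the panel and with array
#' density, and decreases with MAF; population-specific variants get no
#' help from the external panel and are unimputable until enough matched
#' individuals are sequenced.
#'
#' @param n_variants Number of variants per table.
#' @param maf_range Range of population MAFs; drawn with density
#'   proportional to `1/p` (log-uniform), the usual neutral-spectrum shape.
#' @param panel_sizes Numbers of population-matched sequenced individuals
#'   at which tables are generated (ascending).
#' @param N Evaluation sample size (sample MAFs are binomial draws at this
#'   size, conditioned on being polymorphic).
#' @param external_panel_size Individuals in the external reference panel.
#' @param external_weight Effective fraction of the external panel that is
#'   genetically matched to the target population (haplotype-sharing
#'   discount); the effective matched panel for a shared variant is
#'   `panel_n + external_weight * external_panel_size`, while a
#'   population-specific variant sees only `panel_n`.
#' @param arrays Named numeric vector: asymptotic r-squared ceiling
#'   (`r2_max`) per genotyping array, higher for denser arrays.
#' @param n50_base,n50_rare Half-saturation constant of the r-squared
#'   curve, `n50(maf) = n50_base + n50_rare / maf` (matched individuals
#'   needed to reach half the ceiling; larger for rarer variants).
#' @param beta_conc Concentration of the Beta noise around the mean
#'   r-squared curve.
#' @param ps_max,ps_decay Probability a variant is population-specific:
#'   `ps_max * exp(-maf / ps_decay)`, decreasing in MAF.
#' @param population,external_panel Labels stamped on the tables.
#' @return Object of class `quality_gen_config`.
#' @export
quality_gen_config <- function(n_variants = 2000,
                               maf_range = c(1e-4, 0.5),
                               panel_sizes = c(0, 200, 500, 1000, 2000),
                               N = 3412,
                               external_panel_size = 30000,
                               external_weight = 0.05,
                               arrays = c(core = 0.90, omniexpress = 0.95,
                                          omni2.5 = 0.97),
                               n50_base = 100, n50_rare = 0.3,
                               beta_conc = 50,
                               ps_max = 0.5, ps_decay = 0.01,
                               population = "synthetic_pop",
                               external_panel = "synthetic_external") {
  stopifnot(n_variants >= 1, length(maf_range) == 2L,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] < maf_range[2],
            length(panel_sizes) >= 1L, all(panel_sizes >= 0),
            !is.unsorted(panel_sizes, strictly = TRUE),
            N >= 1, external_panel_size >= 0,
            external_weight >= 0, external_weight <= 1,
            length(arrays) >= 1L, !is.null(names(arrays)),
            all(arrays > 0 & arrays <= 1),
            n50_base > 0, n50_rare >= 0, beta_conc > 0,
            ps_max >= 0, ps_max <= 1, ps_decay > 0)
  structure(as.list(environment()), class = "quality_gen_config")
}

#' @export
print.quality_gen_config <- function(x, ...) {
  cat("Synthetic quality-table generator config\n")
  cat(sprintf("  %d variants, MAF in [%g, %g] (1/p density), N = %d\n",
              x$n_variants, x$maf_range[1], x$maf_range[2], x$N))
  cat(sprintf("  panel sizes: %s; external %d (weight %g)\n",
              paste(x$panel_sizes, collapse = ", "),
              x$external_panel_size, x$external_weight))
  cat(sprintf("  arrays (r2 ceiling): %s\n",
              paste(names(x$arrays), x$arrays, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Generate synthetic imputation-quality tables
#'
#' Produces one [quality_table()] per `panel_size x array`. The same
#' variant universe (MAF, population-specificity, sample MAC) underlies all
#' tables. Panel MACs are cumulative binomial draws as the matched panel
#' grows, so a variant's panel MAC is non-decreasing in `panel_n`.
#' Per-variant r-squared values are quantile-coupled Beta draws (one
#' uniform per variant shared across panel sizes and arrays) around the
#' saturation-curve mean, so each variant's r-squared is monotone in
#' `panel_n` and in array density by construction. Variants with panel MAC
#' zero are absent from the panel: missing r-squared, never imputable.
#'
#' @param config A [quality_gen_config()].
#' @param seed Integer seed; the output is a deterministic function of
#'   `(config, seed)`.
#' @return Named list of [quality_table()], names `"<array>_n<panel_n>"`.
#' @export
generate_quality_tables <- function(config = quality_gen_config(),
                                    seed = 1L) {
  stopifnot(inherits(config, "quality_gen_config"))
  .with_seed(seed, {
    nv <- config$n_variants
    lo <- log(config$maf_range[1]); hi <- log(config$maf_range[2])
    maf <- exp(stats::runif(nv, lo, hi))
    ps <- stats::runif(nv) < config$ps_max * exp(-maf / config$ps_decay)
    # sample MAC in the evaluation sample, conditioned polymorphic
    mac_sample <- stats::rbinom(nv, 2L * config$N, maf)
    while (any(mac_sample == 0L)) {
      z <- mac_sample == 0L
      mac_sample[z] <- stats::rbinom(sum(z), 2L * config$N, maf[z])
    }
    maf_sample <- mac_sample / (2 * config$N)
    u <- stats::runif(nv)   # shared Beta quantile across panel sizes/arrays
    ext_match <- ifelse(ps, 0,
                        config$external_weight * config$external_panel_size)
    n50 <- config$n50_base + config$n50_rare / maf
    # cumulative panel MAC as the matched panel grows
    sizes <- config$panel_sizes
    mac_panel <- matrix(0, nv, length(sizes))
    base <- stats::rbinom(nv, 2L * round(ext_match), maf) +
      stats::rbinom(nv, 2L * sizes[1], maf)
    mac_panel[, 1] <- base
    if (length(sizes) > 1L) {
      for (k in 2:length(sizes)) {
        inc <- stats::rbinom(nv, 2L * (sizes[k] - sizes[k - 1L]), maf)
        mac_panel[, k] <- mac_panel[, k - 1L] + inc
      }
    }
    out <- list()
    for (k in seq_along(sizes)) {
      x <- sizes[k] + ext_match
      for (arr in names(config$arrays)) {
        mu <- config$arrays[[arr]] * x / (x + n50)
        mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
        r2 <- stats::qbeta(u, mu * config$beta_conc,
                           (1 - mu) * config$beta_conc)
        r2[mac_panel[, k] == 0] <- NA_real_
        rec <- data.frame(
          variant_id = paste0("v", seq_len(nv)),
          maf_sample = maf_sample,
          mac_panel = mac_panel[, k],
          r2 = r2, pop_specific = ps,
          stringsAsFactors = FALSE)
        out[[paste0(arr, "_n", sizes[k])]] <-
          quality_table(rec, population = config$population, array = arr,
                        panel_n = sizes[k], N = config$N,
                        external_panel = config$external_panel)
      }
    }
    out
  })
}

#' Simulate imputed dosages at a target imputation r-squared
#'
#' Generates a dosage vector `D = G + e`, `e ~ N(0, s2)` with `s2` chosen
#' from the sample variance of `G` so that the squared correlation between
#' `G` and `D` converges to `r2_target` as the sample grows (the regression
#' slope of `D` on `G` is +1, so the correlation is always positive).
#' Dosages are not clipped to `[0, 2]`; clip on output if a file format
#' requires it.
#'
#' @param genotypes Numeric 0/1/2 vector with nonzero variance.
#' @param r2_target Target squared correlation in `(0, 1]`.
#' @param seed Optional integer seed (RNG state is restored).
#' @return Numeric dosage vector; exactly `genotypes` when
#'   `r2_target = 1`.
#' @export
simulate_imputed_dosage <- function(genotypes, r2_target, seed = NULL) {
  g <- as.numeric(genotypes)
  if (length(g) < 2L || stats::var(g) == 0)
    stop("genotype vector is monomorphic: dosage r2 is undefined")
  stopifnot(r2_target > 0, r2_target <= 1)
  if (r2_target == 1) return(g)
  s2 <- stats::var(g) * (1 - r2_target) / r2_target
  .with_seed(seed, g + stats::rnorm(length(g), 0, sqrt(s2)))
}

# ---- Monte Carlo two-stage GWAS ---------------------------------------------

# Sufficient statistics (sum, sum of squares of the analyzed dosage) for one
# disease group across `reps` replicates. Genotypes are HWE multinomial
# counts at allele frequency q; dosage noise (variance sigma2) enters
# through its exact conditional distribution given the genotypes: the iid
# Gaussian noise vector is decomposed along the constant direction, the
# centered-genotype direction, and the orthogonal complement, so the joint
# law of (sum e, sum G*e, sum e^2) matches individual-level simulation
# exactly.
.group_stats <- function(reps, ng, q, sigma2) {
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  M <- stats::rmultinom(reps, ng, hw)
  Sg <- M[2, ] + 2 * M[3, ]
  Sg2 <- M[2, ] + 4 * M[3, ]
  if (sigma2 <= 0) return(list(S = Sg, S2 = Sg2))
  if (ng < 3L)
    stop("each disease group needs at least 3 individuals to simulate ",
         "noisy dosages")
  sdev <- sqrt(sigma2)
  a1 <- stats::rnorm(reps, 0, sdev)
  a2 <- stats::rnorm(reps, 0, sdev)
  Qg <- pmax(Sg2 - Sg^2 / ng, 0)
  Se <- sqrt(ng) * a1
  SGe <- sqrt(Qg) * a2 + Sg / sqrt(ng) * a1
  Se2 <- a1^2 + a2^2 + sigma2 * stats::rchisq(reps, df = ng - 2)
  list(S = Sg + Se, S2 = Sg2 + 2 * SGe + Se2)
}

# Pooled-variance two-sample Z from group sufficient statistics.
.two_sample_z <- function(cs, ts, nc, nt) {
  n <- nc + nt
  V <- (cs$S2 + ts$S2 - (cs$S + ts$S)^2 / n) / (n - 1)
  z <- (cs$S / nc - ts$S / nt) / sqrt(V * (1 / nc + 1 / nt))
  z[!is.finite(z)] <- NA_real_
  z
}

.split_cases <- function(n, s) {
  nc <- round(n * s / (1 + s))
  c(cases = nc, controls = n - nc)
}

#' Monte Carlo power of a two-stage sequencing + imputation GWAS
#'
#' Simulates the two-stage design end to end: case and control genotypes
#' are drawn under Hardy-Weinberg at the disease model's case/control
#' allele frequencies; the sequenced subsample is analyzed on true
#' genotypes and the imputed subsample on dosages with squared correlation
#' `r2` to the truth; an allele-based Z statistic (difference in mean
#' dosage standardized by the pooled combined-sample variance) is computed
#' in each subsample and combined with the effective-sample-size weights
#' ([effective_fraction()]). A replicate rejects when `|Z| > z_crit`.
#'
#' Replicates are generated from sufficient statistics (genotype-class
#' counts and exact conditional noise sums), which is distributionally
#' identical to individual-level simulation; sequenced participants are
#' drawn independently of imputed ones, equivalent to random subsampling.
#'
#' @param model A [disease_model()].
#' @param design A [study_design()].
#' @param r2 Imputation r-squared of the imputed subsample, in `(0, 1]`.
#' @param reps Number of replicates.
#' @param sig A [sig_spec()].
#' @param seed Optional integer seed (RNG state restored).
#' @param details If `TRUE`, also return the per-replicate statistics.
#' @return Object of class `sim_power`: `power` (rejection fraction), `se`
#'   (binomial standard error), `mean_z`, `reps`, `n_undefined` (replicates
#'   with undefined statistic, counted as non-rejections), `alpha`, `r2`,
#'   and with `details = TRUE` a data frame `replicates` with columns
#'   `z_seq`, `z_imp`, `z_combined`, `rejected`.
#' @examples
#' sp <- simulate_power(disease_model(0.05, 1.3, 0.01),
#'                      study_design(100, 900), r2 = 0.8, reps = 2000,
#'                      sig = sig_spec(0.05), seed = 1)
#' sp$power
#' @export
simulate_power <- function(model, design, r2, reps = 20000,
                           sig = sig_spec(), seed = NULL, details = FALSE) {
  stopifnot(inherits(model, "disease_model"),
            inherits(design, "study_design"), inherits(sig, "sig_spec"),
            reps >= 1, r2 > 0, r2 <= 1)
  n <- design$n_seq; m <- design$m_imp; s <- model$s
  fr <- case_control_freqs(model)
  pc <- fr[["p_case"]]; pt <- fr[["p_control"]]
  v <- genotype_variances(pc, pt)
  w1 <- s / (1 + s)
  v_mix <- w1 * v[["v_case"]] + (1 - w1) * v[["v_control"]] +
    w1 * (1 - w1) * (2 * (pc - pt))^2
  sigma2 <- if (r2 < 1) v_mix * (1 - r2) / r2 else 0
  .with_seed(seed, {
    z_seq <- z_imp <- rep(NA_real_, reps)
    if (n > 0) {
      gs <- .split_cases(n, s)
      if (any(gs < 2)) stop("sequenced subsample too small to test")
      z_seq <- .two_sample_z(.group_stats(reps, gs[["cases"]], pc, 0),
                             .group_stats(reps, gs[["controls"]], pt, 0),
                             gs[["cases"]], gs[["controls"]])
    }
    if (m > 0) {
      gs <- .split_cases(m, s)
      if (any(gs < if (sigma2 > 0) 3 else 2))
        stop("imputed subsample too small to test")
      z_imp <- .two_sample_z(.group_stats(reps, gs[["cases"]], pc, sigma2),
                             .group_stats(reps, gs[["controls"]], pt, sigma2),
                             gs[["cases"]], gs[["controls"]])
    }
    if (n > 0 && m > 0) {
      cc <- effective_fraction(n, m, r2)
      z <- sqrt(cc) * z_seq + sqrt(1 - cc) * z_imp
    } else if (n > 0) z <- z_seq else z <- z_imp
    rejected <- !is.na(z) & abs(z) > sig$z_crit
    pw <- mean(rejected)
    out <- structure(
      list(power = pw, se = sqrt(pw * (1 - pw) / reps),
           mean_z = mean(z, na.rm = TRUE), reps = reps,
           n_undefined = sum(is.na(z)), alpha = sig$alpha, r2 = r2,
           design = design, model = model),
      class = "sim_power")
    if (details)
      out$replicates <- data.frame(z_seq = z_seq, z_imp = z_imp,
                                   z_combined = z, rejected = rejected)
    out
  })
}

#' @export
print.sim_power <- function(x, ...) {
  cat(sprintf(
    "Simulated power: %.4f (SE %.4f, %d replicates, alpha = %g)\n",
    x$power, x$se, x$reps, x$alpha))
  cat(sprintf("  design: n_seq = %g, m_imp = %g, r2 = %g; mean Z = %.3f\n",
              x$design$n_seq, x$design$m_imp, x$r2, x$mean_z))
  if (x$n_undefined > 0)
    cat(sprintf("  %d replicate(s) with undefined statistic (monomorphic)\n",
                x$n_undefined))
  invisible(x)
}

#' Simulate association Z statistics under a disease model
#'
#' `simulate()` method: draws per-replicate combined Z statistics for a
#' given design, the replicate-level view of [simulate_power()].
#'
#' @param object A [disease_model()].
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param design A [study_design()].
#' @param r2 Imputation r-squared for the imputed subsample.
#' @param sig A [sig_spec()].
#' @param ... Unused.
#' @return Data frame with columns `z_seq`, `z_imp`, `z_combined`,
#'   `rejected`.
#' @export
simulate.disease_model <- function(object, nsim = 1000, seed = NULL,
                                   design = study_design(0, 1000),
                                   r2 = 1, sig = sig_spec(), ...) {
  simulate_power(object, design, r2 = r2, reps = nsim, sig = sig,
                 seed = seed, details = TRUE)$replicates
}
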