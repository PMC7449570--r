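#' Construct a per-variant imputation-quality table
#'
#' A quality table records, for one (population, genotyping array, study
#' panel size) configuration, the empirical imputation quality of each
#' variant in an evaluation sample of `N` individuals: its sample MAF,
#' reference-panel minor allele count, imputation r-squared (squared Pearson
#' correlation between masked true genotype and imputed dosage; `NA` when
#' the variant is absent from the panel), and whether it is specific to the
#' target population. These tables drive the empirically-weighted power
#' estimator.
#'
#' @param records Data frame with columns `variant_id` (character),
#'   `maf_sample` (fraction), `mac_panel` (integer >= 0), `r2` (in `[0,1]`
#'   or `NA`), `pop_specific` (logical or 0/1). Optional columns:
#'   `mac_sample` (defaults to `round(2*N*maf_sample)`), `weight` (row
#'   multiplicity for bin-aggregated tables, defaults to 1).
#' @param population,array Labels identifying the configuration.
#' @param panel_n Number of population-matched sequenced individuals in the
#'   augmented reference panel (>= 0).
#' @param N Evaluation sample size used to measure the quality data (>= 1).
#' @param external_panel Label of the external reference panel.
#'
#' @return Object of class `quality_table`: list with fields `population`,
#'   `array`, `panel_n`, `N`, `external_panel` and the validated, folded
#'   `records` data frame (gains logical column `folded`).
#'
#' @details Sample MAFs above 0.5 are folded to the minor allele
#'   (`1 - maf`), flagged in the `folded` column, and `mac_sample` is
#'   recomputed. Missing `r2` encodes a variant absent from the reference
#'   panel (or not imputed); such variants are never imputable.
#' @export
quality_table <- function(records, population, array, panel_n, N,
                          external_panel = "external") {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            length(population) == 1L, length(array) == 1L,
            is.numeric(panel_n), length(panel_n) == 1L, panel_n >= 0,
            is.numeric(N), length(N) == 1L, N >= 1)
  required <- c("variant_id", "maf_sample", "mac_panel", "r2", "pop_specific")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("quality table records lack column(s): ",
         paste(missing_cols, collapse = ", "))
  rec <- records
  rec$variant_id <- as.character(rec$variant_id)
  rec$maf_sample <- as.numeric(rec$maf_sample)
  rec$mac_panel <- as.numeric(rec$mac_panel)
  rec$r2 <- as.numeric(rec$r2)
  rec$pop_specific <- as.logical(rec$pop_specific)
  if (anyNA(rec$maf_sample) || any(rec$maf_sample < 0 | rec$maf_sample > 1))
    stop("`maf_sample` must be in [0, 1]")
  bad_r2 <- !is.na(rec$r2) & (rec$r2 < 0 | rec$r2 > 1)
  if (any(bad_r2))
    stop("`r2` outside [0, 1] at row(s): ",
         paste(utils::head(which(bad_r2), 5L), collapse = ", "))
  if (anyNA(rec$mac_panel) || any(rec$mac_panel < 0))
    stop("`mac_panel` must be >= 0")
  if (anyNA(rec$pop_specific))
    stop("`pop_specific` must be logical (or 0/1) without missing values")
  # minor-allele folding, flagged for provenance
  fold <- rec$maf_sample > 0.5
  rec$folded <- fold
  rec$maf_sample[fold] <- 1 - rec$maf_sample[fold]
  rec$mac_sample <- as.integer(round(2 * N * rec$maf_sample))
  if (is.null(records$weight)) {
    rec$weight <- 1
  } else {
    rec$weight <- as.numeric(records$weight)
    if (anyNA(rec$weight) || any(rec$weight < 0))
      stop("`weight` must be >= 0")
  }
  rownames(rec) <- NULL
  structure(
    list(population = as.character(population), array = as.character(array),
         panel_n = as.numeric(panel_n), N = as.integer(N),
         external_panel = as.character(external_panel),
         records = rec[c("variant_id", "maf_sample", "mac_sample",
                         "mac_panel", "r2", "pop_specific", "weight",
                         "folded")]),
    class = "quality_table"
  )
}

#' @export
print.quality_table <- function(x, ...) {
  cat(sprintf(
    "Imputation quality table: %s / %s array, panel_n = %g (+ %s), N = %d\n",
    x$population, x$array, x$panel_n, x$external_panel, x$N))
  cat(sprintf("  %d variant records (%d imputable, %.1f%% population-specific)\n",
              nrow(x$records), sum(is_imputable(x$records)),
              100 * stats::weighted.mean(x$records$pop_specific,
                                         x$records$weight)))
  invisible(x)
}

#' @export
summary.quality_table <- function(object, bins = default_maf_bins(), ...) {
  rec <- object$records
  idx <- lapply(bins, function(b) which(rec$maf_sample >= b$lo &
                                          rec$maf_sample < b$hi))
  out <- data.frame(
    maf_lo = vapply(bins, `[[`, numeric(1), "lo"),
    maf_hi = vapply(bins, `[[`, numeric(1), "hi"),
    n_variants = vapply(idx, function(i) sum(rec$weight[i]), numeric(1)),
    mean_r2 = vapply(idx, function(i) {
      if (!length(i)) return(NA_real_)
      r2 <- ifelse(is.na(rec$r2[i]), 0, rec$r2[i])
      stats::weighted.mean(r2, rec$weight[i])
    }, numeric(1)),
    coverage = vapply(idx, function(i) {
      if (!length(i)) return(NA_real_)
      stats::weighted.mean(is_imputable(rec[i, ]), rec$weight[i])
    }, numeric(1))
  )
  class(out) <- c("summary.quality_table", "data.frame")
  out
}

# ---- TSV input/output -------------------------------------------------------

.qt_columns <- c("population", "array", "panel_n", "N", "variant_id",
                 "maf_sample", "mac_sample", "mac_panel", "r2",
                 "pop_specific")

#' Read an imputation-quality table from TSV
#'
#' Expects a tab-separated file with header columns `population array
#' panel_n N variant_id maf_sample mac_sample mac_panel r2 pop_specific`
#' (optional extras: `weight` for bin-aggregated rows, `folded`,
#' `external_panel`). `r2` is the empty string when missing. Gzip-compressed
#' files are read transparently.
#'
#' @param path Path to the TSV (optionally `.gz`).
#' @return A [quality_table()].
#' @export
read_quality_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  missing_cols <- setdiff(.qt_columns, names(df))
  if (length(missing_cols))
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) < 1L) stop("quality table ", path, " has no data rows")
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !(df[[col]] %in% c("", "NA")))
    if (length(bad))
      stop("non-numeric value in column `", col, "` at data line ", bad[1L],
           " of ", path)
    x
  }
  for (key in c("population", "array", "panel_n", "N")) {
    if (length(unique(df[[key]])) != 1L)
      stop("column `", key, "` must be constant within one table file: ", path)
  }
  rec <- data.frame(
    variant_id = df$variant_id,
    maf_sample = num("maf_sample"),
    mac_panel = num("mac_panel"),
    r2 = num("r2"),
    pop_specific = num("pop_specific") != 0,
    stringsAsFactors = FALSE
  )
  if (!is.null(df$weight)) rec$weight <- num("weight")
  quality_table(
    rec,
    population = df$population[1L], array = df$array[1L],
    panel_n = as.numeric(df$panel_n[1L]), N = as.numeric(df$N[1L]),
    external_panel = if (!is.null(df$external_panel)) df$external_panel[1L]
                     else "external"
  )
}

#' Write an imputation-quality table to TSV
#'
#' Inverse of [read_quality_table()]; missing `r2` is written as the empty
#' string.
#'
#' @param table A [quality_table()].
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_quality_table <- function(table, path) {
  stopifnot(inherits(table, "quality_table"))
  rec <- table$records
  out <- data.frame(
    population = table$population, array = table$array,
    panel_n = table$panel_n, N = table$N,
    variant_id = rec$variant_id,
    maf_sample = rec$maf_sample, mac_sample = rec$mac_sample,
    mac_panel = rec$mac_panel,
    r2 = ifelse(is.na(rec$r2), "", format(rec$r2, digits = 15L,
                                          scientific = FALSE, trim = TRUE)),
    pop_specific = as.integer(rec$pop_specific),
    weight = rec$weight, folded = as.integer(rec$folded),
    external_panel = table$external_panel,
    stringsAsFactors = FALSE
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- MAF bins ---------------------------------------------------------------

#' Half-open minor-allele-frequency bin
#'
#' @param lo,hi Bounds (fractions) of the half-open interval `[lo, hi)`,
#'   with `0 <= lo < hi <= 0.5`.
#' @return Object of class `maf_bin`: list with `lo`, `hi`.
#' @export
maf_bin <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L,
            length(hi) == 1L)
  if (!(lo >= 0 && lo < hi && hi <= 0.5))
    stop("need 0 <= lo < hi <= 0.5, got [", lo, ", ", hi, ")")
  structure(list(lo = lo, hi = hi), class = "maf_bin")
}

#' @export
print.maf_bin <- function(x, ...) {
  cat(sprintf("MAF bin [%g, %g)\n", x$lo, x$hi)); invisible(x)
}

#' Default MAF bins
#'
#' Bins on the minor-allele-folded frequency with edges 0.1%, 0.25%, 0.5%,
#' 5%, 50%, matching the rare / low-frequency / common split conventional
#' in imputation-coverage reporting.
#'
#' @param edges Numeric vector of increasing bin edges in `[0, 0.5]`.
#' @return List of [maf_bin()] objects, half-open `[lo, hi)`.
#' @export
default_maf_bins <- function(edges = c(0.001, 0.0025, 0.005, 0.05, 0.5)) {
  stopifnot(length(edges) >= 2L, !is.unsorted(edges, strictly = TRUE))
  lapply(seq_len(length(edges) - 1L),
         function(i) maf_bin(edges[i], edges[i + 1L]))
}

# ---- derived summaries ------------------------------------------------------

#' Imputation coverage within a MAF bin
#'
#' The (weighted) proportion of a bin's variants that are imputable:
#' reference-panel MAC at least 5 and imputation r-squared at least 0.3
#' (see [is_imputable()]).
#'
#' @param table A [quality_table()].
#' @param bin A [maf_bin()]; variants with folded sample MAF in
#'   `[bin$lo, bin$hi)` are considered.
#' @return Fraction in `[0, 1]`.
#' @seealso [is_imputable()] for the imputability rule.
#' @export
coverage <- function(table, bin) {
  stopifnot(inherits(table, "quality_table"), inherits(bin, "maf_bin"))
  rec <- table$records
  sel <- rec$maf_sample >= bin$lo & rec$maf_sample < bin$hi
  if (!any(sel))
    stop("empty MAF bin [", bin$lo, ", ", bin$hi, "): no variants to assess")
  stats::weighted.mean(is_imputable(rec[sel, ]), rec$weight[sel])
}

#' Empirical distribution of sample minor allele counts
#'
#' The (weight-adjusted) proportion of a table's variants at each observed
#' sample MAC; the empirical counterpart of [sample_mac_pmf()] used as the
#' denominator of the MAC weight.
#'
#' @param table A [quality_table()].
#' @return Named numeric vector: names are MAC values, entries are
#'   proportions summing to 1.
#' @export
empirical_maf_hist <- function(table) {
  stopifnot(inherits(table, "quality_table"))
  rec <- table$records
  tab <- tapply(rec$weight, rec$mac_sample, sum)
  prop <- as.numeric(tab) / sum(rec$weight)
  names(prop) <- names(tab)
  prop
}

#' Fraction of population-specific variants by MAF bin
#'
#' For each bin, the (weight-adjusted) fraction of variants that are
#' specific to the target population (monomorphic elsewhere). Bins with no
#' variants are omitted.
#'
#' @param table A [quality_table()].
#' @param bins List of [maf_bin()]; the default prepends a `[0, 0.001)` bin
#'   to [default_maf_bins()] so the whole folded-MAF range is covered.
#' @return Data frame of class `ps_fraction` with columns `lo`, `hi`,
#'   `n_variants`, `frac`.
#' @export
empirical_ps_fraction <- function(table,
                                  bins = default_maf_bins(
                                    c(0, 0.001, 0.0025, 0.005, 0.05, 0.5))) {
  stopifnot(inherits(table, "quality_table"))
  rec <- table$records
  rows <- lapply(bins, function(b) {
    sel <- rec$maf_sample >= b$lo & rec$maf_sample < b$hi
    if (!any(sel)) return(NULL)
    data.frame(lo = b$lo, hi = b$hi, n_variants = sum(rec$weight[sel]),
               frac = stats::weighted.mean(rec$pop_specific[sel],
                                           rec$weight[sel]))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no variants fall in any of the supplied bins")
  class(out) <- c("ps_fraction", "data.frame")
  out
}

# look up the ps fraction for a folded MAF; NA when uncovered
.ps_lookup <- function(ps, maf) {
  hit <- which(maf >= ps$lo & maf < ps$hi)
  if (!length(hit)) return(NA_real_)
  ps$frac[hit[1L]]
}

# ---- panel-size interpolation -----------------------------------------------

#' Interpolate quality tables to an intermediate panel size
#'
#' Quality data are measured at discrete study-panel sizes; this produces a
#' table at an intermediate size by per-variant linear interpolation of
#' `r2` and `mac_panel` between the two bracketing tables (matched by
#' `variant_id`). No extrapolation: `n_requested` must lie within the range
#' of available sizes. If a variant's `r2` is missing at either bracketing
#' size, the interpolated `r2` is missing (its panel MAC still
#' interpolates, from 0 when absent).
#'
#' @param tables List of [quality_table()] for the same population/array at
#'   distinct `panel_n` values.
#' @param n_requested Desired panel size.
#' @return A [quality_table()] with `panel_n = n_requested`.
#' @export
interpolate_panel_size <- function(tables, n_requested) {
  if (inherits(tables, "quality_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "quality_table")))
  ns <- vapply(tables, `[[`, numeric(1), "panel_n")
  if (anyDuplicated(ns)) stop("duplicate panel_n among tables")
  ord <- order(ns)
  tables <- tables[ord]; ns <- ns[ord]
  if (length(unique(vapply(tables, `[[`, character(1), "array"))) != 1L ||
      length(unique(vapply(tables, `[[`, character(1), "population"))) != 1L)
    stop("tables must share one population and one array")
  exact <- which(ns == n_requested)
  if (length(exact)) return(tables[[exact[1L]]])
  if (n_requested < min(ns) || n_requested > max(ns))
    stop("n_requested = ", n_requested, " outside available panel sizes [",
         min(ns), ", ", max(ns), "]; extrapolation is not supported")
  hi_i <- which(ns > n_requested)[1L]
  lo_i <- hi_i - 1L
  lo <- tables[[lo_i]]; hi <- tables[[hi_i]]
  w <- (n_requested - ns[lo_i]) / (ns[hi_i] - ns[lo_i])
  a <- lo$records; b <- hi$records
  idx <- match(a$variant_id, b$variant_id)
  if (anyNA(idx))
    stop("tables at panel_n = ", ns[lo_i], " and ", ns[hi_i],
         " do not share the same variants")
  b <- b[idx, ]
  rec <- a
  rec$mac_panel <- (1 - w) * a$mac_panel + w * b$mac_panel
  rec$r2 <- (1 - w) * a$r2 + w * b$r2   # NA if missing at either end
  rec$mac_sample <- NULL; rec$folded <- NULL
  quality_table(rec, population = lo$population, array = lo$array,
                panel_n = n_requested, N = lo$N,
                external_panel = lo$external_panel)
}

# ---- quality from paired genotypes ------------------------------------------

#' Per-variant imputation quality from paired true and imputed genotypes
#'
#' Computes, for each variant, the imputation r-squared as the squared
#' Pearson correlation across samples between the true (masked) 0/1/2
#' genotype and the imputed dosage, together with the sample MAF. Variants
#' with zero variance on either side get a missing r-squared.
#'
#' @param true_genotypes Numeric matrix, variants x samples, entries 0/1/2.
#' @param dosages Numeric matrix of the same shape, entries in `[0, 2]`.
#' @param panel_macs Integer vector (one per variant): reference-panel
#'   minor allele count.
#' @param variant_ids Optional character vector of variant names; defaults
#'   to rownames or `v1, v2, ...`.
#' @param pop_specific Optional logical vector; defaults to `FALSE`.
#' @return Data frame with columns `variant_id`, `maf_sample`, `mac_panel`,
#'   `r2`, `pop_specific`, suitable as `records` for [quality_table()].
#' @examples
#' G <- rbind(v1 = c(0, 0, 1, 1, 2, 2))
#' D <- rbind(v1 = c(0.1, 0.0, 0.9, 1.2, 1.8, 2.0))
#' compute_quality_from_genotypes(G, D, panel_macs = 12)
#' @export
compute_quality_from_genotypes <- function(true_genotypes, dosages,
                                           panel_macs, variant_ids = NULL,
                                           pop_specific = NULL) {
  true_genotypes <- as.matrix(true_genotypes)
  dosages <- as.matrix(dosages)
  if (!identical(dim(true_genotypes), dim(dosages)))
    stop("true genotype and dosage matrices must have identical dimensions (",
         paste(dim(true_genotypes), collapse = "x"), " vs ",
         paste(dim(dosages), collapse = "x"), ")")
  nv <- nrow(true_genotypes)
  if (length(panel_macs) != nv)
    stop("`panel_macs` must have one entry per variant")
  if (is.null(variant_ids))
    variant_ids <- rownames(true_genotypes) %||% paste0("v", seq_len(nv))
  if (is.null(pop_specific)) pop_specific <- rep(FALSE, nv)
  r2 <- vapply(seq_len(nv), function(j) {
    g <- true_genotypes[j, ]; d <- dosages[j, ]
    if (stats::var(g) == 0 || stats::var(d) == 0) return(NA_real_)
    stats::cor(g, d)^2
  }, numeric(1))
  maf <- rowMeans(true_genotypes) / 2
  data.frame(variant_id = as.character(variant_ids),
             maf_sample = maf, mac_panel = as.numeric(panel_macs),
             r2 = r2, pop_specific = as.logical(pop_specific),
             stringsAsFactors = FALSE)
}

#' Read imputed dosages from a VCF with a DS FORMAT field
#'
#' Convenience reader for the imputed side of a paired truth/dosage
#' comparison. Requires the `vcfR` package.
#'
#' @param path VCF path (optionally bgzipped).
#' @return Numeric matrix, variants x samples, of dosages.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF dosages requires the `vcfR` package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (is.null(ds) || all(is.na(ds)))
    stop("no DS (dosage) FORMAT field found in ", path)
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a
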