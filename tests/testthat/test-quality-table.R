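test_that("quality table construction validates and folds", {
  tab <- make_table(maf_sample = c(0.01, 0.7, 0.2),
                    mac_panel = c(10, 5, 0),
                    r2 = c(0.9, 0.4, NA), N = 1000)
  expect_s3_class(tab, "quality_table")
  expect_equal(nrow(tab$records), 3L)
  # folding: 0.7 -> 0.3, flagged, MAC recomputed from the folded MAF
  expect_equal(tab$records$maf_sample[2], 0.3)
  expect_true(tab$records$folded[2])
  expect_equal(tab$records$mac_sample, as.integer(round(2 * 1000 * c(0.01, 0.3, 0.2))))

  expect_error(make_table(maf_sample = 0.1, mac_panel = 5, r2 = 1.2),
               "r2")
  expect_error(make_table(maf_sample = 0.1, mac_panel = -1, r2 = 0.5),
               "mac_panel")
  expect_error(quality_table(data.frame(variant_id = "v1"), "p", "a", 0, 10),
               "lack column")
})

test_that("quality tables round-trip through TSV, preserving missing r2", {
  set.seed(5)
  for (i in 1:5) {
    tab <- random_table(nv = 25)
    path <- tempfile(fileext = if (i %% 2) ".tsv" else ".tsv.gz")
    write_quality_table(tab, path)
    back <- read_quality_table(path)
    expect_equal(back$records$maf_sample, tab$records$maf_sample,
                 tolerance = 1e-12)
    expect_identical(back$records$mac_sample, tab$records$mac_sample)
    expect_equal(back$records$r2, tab$records$r2, tolerance = 1e-12)
    expect_identical(back$records$pop_specific, tab$records$pop_specific)
    expect_identical(back$records$variant_id, tab$records$variant_id)
    expect_equal(back$panel_n, tab$panel_n)
    expect_equal(back$N, tab$N)
    unlink(path)
  }
})

test_that("reading rejects malformed files with informative errors", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("population\tarray\tvariant_id", "x\ty\tv1"), path)
  expect_error(read_quality_table(path), "missing column")
  writeLines(c(paste(c("population", "array", "panel_n", "N", "variant_id",
                       "maf_sample", "mac_sample", "mac_panel", "r2",
                       "pop_specific"), collapse = "\t"),
               paste(c("p", "a", "0", "100", "v1", "abc", "1", "5", "0.5",
                       "0"), collapse = "\t")), path)
  expect_error(read_quality_table(path), "maf_sample")
  expect_error(read_quality_table(tempfile()), "no such file")
  unlink(path)
})

test_that("coverage counts imputable variants within a MAF bin", {
  tab <- make_table(maf_sample = rep(0.003, 4),
                    mac_panel = c(10, 10, 10, 3),
                    r2 = c(0.9, 0.5, 0.2, 0.4))
  expect_equal(coverage(tab, maf_bin(0.0025, 0.005)), 0.5)
  expect_error(coverage(tab, maf_bin(0.05, 0.5)), "empty")

  all_good <- make_table(maf_sample = rep(0.01, 3), mac_panel = 100, r2 = 1)
  expect_equal(coverage(all_good, maf_bin(0.005, 0.05)), 1)
  none <- make_table(maf_sample = rep(0.01, 3), mac_panel = 100,
                     r2 = NA_real_)
  expect_equal(coverage(none, maf_bin(0.005, 0.05)), 0)
})

test_that("empirical MAC histogram gives proportions summing to one", {
  tab <- make_table(maf_sample = c(5, 5) / 2000, mac_panel = 5, r2 = 0.5,
                    N = 1000)
  h <- empirical_maf_hist(tab)
  expect_equal(h, c("5" = 1.0))

  tab <- make_table(maf_sample = c(5, 5, 10, 20) / 2000, mac_panel = 5,
                    r2 = 0.5, N = 1000)
  h <- empirical_maf_hist(tab)
  expect_equal(h, c("5" = 0.5, "10" = 0.25, "20" = 0.25))
  expect_equal(sum(h), 1, tolerance = 1e-12)
})

test_that("population-specific fractions are computed per MAF bin", {
  tab <- make_table(maf_sample = c(rep(0.002, 4), rep(0.01, 2)),
                    mac_panel = 5, r2 = 0.5,
                    pop_specific = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  ps <- empirical_ps_fraction(tab)
  expect_equal(ps$frac[ps$lo == 0.001], 0.5)
  expect_equal(ps$frac[ps$lo == 0.005], 0.0)
  # bins without variants are omitted
  expect_false(0.05 %in% ps$lo)

  all_ps <- make_table(maf_sample = rep(0.002, 3), mac_panel = 5, r2 = 0.5,
                       pop_specific = TRUE)
  expect_equal(empirical_ps_fraction(all_ps)$frac, 1.0)
})

test_that("panel-size interpolation is linear per variant, no extrapolation", {
  t0 <- make_table(maf_sample = c(0.01, 0.02), mac_panel = c(0, 4),
                   r2 = c(0.4, NA), panel_n = 0)
  t1 <- make_table(maf_sample = c(0.01, 0.02), mac_panel = c(10, 8),
                   r2 = c(0.8, 0.6), panel_n = 1000)

  # exact size returns the available table unchanged
  expect_identical(interpolate_panel_size(list(t1, t0), 1000), t1)

  mid <- interpolate_panel_size(list(t0, t1), 500)
  expect_equal(mid$panel_n, 500)
  expect_equal(mid$records$r2[1], 0.6)
  # r2 missing at one bracket stays missing
  expect_true(is.na(mid$records$r2[2]))

  q <- interpolate_panel_size(list(t0, t1), 250)
  expect_equal(q$records$mac_panel[1], 2.5)
  # interpolated MAC below 5 keeps the variant non-imputable
  expect_false(is_imputable(q$records)[1])

  expect_error(interpolate_panel_size(list(t0, t1), 2000), "extrapolation")
  expect_error(interpolate_panel_size(list(t0, t1), -5), "extrapolation")
})

test_that("quality from genotype/dosage pairs matches brute-force Pearson", {
  # dosages identical to genotypes: perfect imputation
  G <- rbind(v1 = c(0, 0, 1, 1, 2, 2))
  rec <- compute_quality_from_genotypes(G, G, panel_macs = 10)
  expect_equal(rec$r2, 1)
  expect_equal(rec$maf_sample, 1 / 2)

  # constant dosage: undefined correlation
  D0 <- rbind(v1 = rep(1, 6))
  expect_true(is.na(compute_quality_from_genotypes(G, D0, 10)$r2))
  # monomorphic truth likewise
  expect_true(is.na(compute_quality_from_genotypes(D0, G, 10)$r2))

  # frozen hand computation on six pairs
  D <- rbind(v1 = c(0.1, 0.0, 0.9, 1.2, 1.8, 2.0))
  expect_equal(compute_quality_from_genotypes(G, D, 10)$r2, 0.977857142857143,
               tolerance = 1e-12)

  expect_error(compute_quality_from_genotypes(G, D[, 1:3, drop = FALSE], 10),
               "identical dimensions")

  # property: agreement with a sum-formula Pearson implementation
  set.seed(31)
  for (i in 1:10) {
    ns <- sample(5:40, 1); nv <- sample(2:6, 1)
    Gm <- matrix(rbinom(nv * ns, 2, 0.3), nv, ns)
    Dm <- Gm + matrix(rnorm(nv * ns, 0, 0.5), nv, ns)
    rec <- compute_quality_from_genotypes(Gm, Dm, panel_macs = rep(5, nv))
    brute <- vapply(seq_len(nv), function(j) {
      g <- Gm[j, ]; d <- Dm[j, ]; n <- length(g)
      num <- n * sum(g * d) - sum(g) * sum(d)
      den <- (n * sum(g^2) - sum(g)^2) * (n * sum(d^2) - sum(d)^2)
      if (den == 0) return(NA_real_)
      num^2 / den
    }, numeric(1))
    expect_equal(rec$r2, brute, tolerance = 1e-10)
  }
})

test_that("dosages can be read from a VCF DS FORMAT field", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "v1", "A", "G", ".", ".", ".", "GT:DS",
          "0/0:0.1", "0/1:1.2", "1/1:1.9", sep = "\t"),
    paste("1", "200", "v2", "A", "C", ".", ".", ".", "GT:DS",
          "0/0:0.0", "0/0:0.2", "0/1:0.8", sep = "\t")), path)
  ds <- read_dosage_vcf(path)
  expect_equal(dim(ds), c(2L, 3L))
  expect_equal(rownames(ds), c("v1", "v2"))
  expect_equal(unname(ds["v1", ]), c(0.1, 1.2, 1.9))
  # pairs with a truth matrix in the usual way
  G <- rbind(v1 = c(0, 1, 2), v2 = c(0, 0, 1))
  rec <- compute_quality_from_genotypes(G, ds, panel_macs = c(8, 3))
  expect_true(all(rec$r2 > 0.9))
  unlink(path)
})
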