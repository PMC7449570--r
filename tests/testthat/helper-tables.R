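# Builders for small in-code quality tables used across the tests.

make_records <- function(maf_sample, mac_panel, r2, pop_specific = FALSE,
                         weight = NULL) {
  k <- length(maf_sample)
  rec <- data.frame(
    variant_id = paste0("v", seq_len(k)),
    maf_sample = maf_sample,
    mac_panel = mac_panel,
    r2 = r2,
    pop_specific = rep_len(pop_specific, k),
    stringsAsFactors = FALSE)
  if (!is.null(weight)) rec$weight <- weight
  rec
}

make_table <- function(..., population = "testpop", array = "core",
                       panel_n = 0, N = 1000) {
  quality_table(make_records(...), population = population, array = array,
                panel_n = panel_n, N = N)
}

# a random but structurally valid quality table
random_table <- function(nv = 30, N = 2000, panel_n = 0) {
  maf <- exp(stats::runif(nv, log(5e-4), log(0.4)))
  mac <- pmax(1L, stats::rbinom(nv, 2L * N, maf))
  r2 <- stats::runif(nv)
  r2[stats::runif(nv) < 0.2] <- NA
  mac_panel <- stats::rpois(nv, 20) * stats::rbinom(nv, 1, 0.8)
  quality_table(
    data.frame(variant_id = paste0("v", seq_len(nv)),
               maf_sample = mac / (2 * N),
               mac_panel = mac_panel, r2 = r2,
               pop_specific = stats::runif(nv) < 0.3),
    population = "rand", array = "core", panel_n = panel_n, N = N)
}

# total-variation distance between two mac_pmf objects
tv_dist <- function(a, b) {
  sup <- 0:max(max(a$mac), max(b$mac))
  pa <- pb <- numeric(length(sup))
  pa[a$mac + 1L] <- a$prob
  pb[b$mac + 1L] <- b$prob
  0.5 * sum(abs(pa - pb))
}
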