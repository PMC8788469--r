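# Shared fixtures and independent oracles, built in code.

# Small annotated protein set with hand-checkable digestion products.
toy_proteins <- function() {
  annotate_proteins(tibble::tibble(
    accession = c("P1", "P2", "P3"),
    sequence = c(
      # 3 tryptic peptides of lengths 8, 8, 7 (all observable)
      "AAAAAAAKCCCCCCCRDDDDDDD",
      # peptides of lengths 9, 9, 11 -> 3 observable
      "AADDEEFFKGGHHIILLRMMNNPPQSSTT",
      # 2 observable peptides
      "VVVVVVVKWWWWWWW"
    ),
    role = "background"
  ))
}

make_evidence <- function(...) {
  rows <- tibble::tribble(...)
  stopifnot(all(c("sample_id", "peptide_seq", "proteins", "spectral_count",
                  "xic_area", "rt_sd_seconds") %in% names(rows)))
  rows
}

# Evidence fixture exercising the three filter rules: an RT outlier, a
# shared peptide, and a protein with a single distinct peptide.
filter_fixture <- function() {
  make_evidence(
    ~sample_id, ~peptide_seq, ~proteins, ~spectral_count, ~xic_area, ~rt_sd_seconds,
    "S1", "AAAAAAAK", "P1",    4L, 1000, 3,
    "S1", "CCCCCCCR", "P1",    2L, 2000, 25,    # RT outlier
    "S1", "DDDDDDD",  "P1",    1L, 1500, 4,
    "S1", "AADDEEFFK", "P2;P3", 3L, 800, 5,     # shared
    "S1", "GGHHIILLR", "P2",   2L, 600, 2,
    "S1", "MMNNPPQSS", "P2",   1L, 500, 6,
    "S1", "VVVVVVVK", "P3",    5L, 3000, 1      # P3's only unique peptide
  )
}

# Brute-force Cook's distance: refit leaving each point out and compare
# fitted values, D_i = sum_j (yhat_j - yhat_j(i))^2 / (p * s^2).
oracle_cooks_distance <- function(x, y) {
  fit <- lm(y ~ x)
  yhat <- fitted(fit)
  s2 <- sum(residuals(fit)^2) / (length(x) - 2)
  vapply(seq_along(x), function(i) {
    fit_i <- lm(y[-i] ~ x[-i])
    yhat_i <- coef(fit_i)[1] + coef(fit_i)[2] * x
    sum((yhat - yhat_i)^2) / (2 * s2)
  }, numeric(1))
}

oracle_cooks_outliers <- function(x, y, k = 3) {
  d <- oracle_cooks_distance(x, y)
  which(d > k * mean(d))
}

# Standards ladder lying exactly on a log-log line with 3 gross planted
# outliers, mirroring a 28-protein detected subset over five decades.
planted_outlier_standards <- function() {
  expected <- rep(c(5, 50, 500, 5000, 50000), times = c(6, 6, 6, 5, 5))
  observed <- expected * 1e-6
  outliers <- c(3L, 14L, 27L)
  observed[outliers] <- observed[outliers] * 10^c(-2, -2.5, 2)
  tibble::tibble(
    accession = sprintf("U%02d", seq_along(expected)),
    abundance = observed,
    expected_fmol = expected,
    planted_outlier = seq_along(expected) %in% outliers
  )
}
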