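# Independent oracles and small generators used across the test files.

# Brute-force tryptic digestion: enumerate every substring and keep the ones
# whose boundaries are valid cleavage points (after K/R, not before P) and
# whose internal missed-cleavage count is within the limit. Quadratic and
# deliberately different from the package's linear construction.
oracle_digest <- function(sequence, max_missed) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cut_after <- vapply(seq_len(n), function(i) {
    chars[i] %in% c("K", "R") && (i == n || chars[i + 1] != "P")
  }, TRUE)
  out <- list()
  for (s in seq_len(n)) {
    if (!(s == 1 || cut_after[s - 1])) next
    for (e in s:n) {
      if (!(e == n || cut_after[e])) next
      internal <- if (e > s) sum(cut_after[s:(e - 1)]) else 0L
      if (internal > max_missed) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = paste(chars[s:e], collapse = ""),
        start = s, end = e, missed = internal)
    }
  }
  do.call(rbind, out)
}

random_peptide <- function(min_len = 3, max_len = 20) {
  len <- sample(min_len:max_len, 1)
  paste(sample(names(amino_acid_masses()), len, replace = TRUE), collapse = "")
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "lensphos", mustWork = TRUE)
}

table1 <- function() load_catalog(fixture_path("table1_sites.tsv"))
table2 <- function() load_catalog(fixture_path("table2_differential.tsv"))

# Gaussian chromatographic peak sampled on a regular grid.
gaussian_trace <- function(amplitude = 1000, sigma = 0.1, center = 50,
                           interval = 0.01, span = 4) {
  tt <- seq(center - span * sigma, center + span * sigma, by = interval)
  tibble::tibble(rt = tt,
                 intensity = amplitude * exp(-(tt - center)^2 / (2 * sigma^2)))
}
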