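# Seeded synthetic LC-MS experiment generator with a ground-truth ledger.
#
# Emulates the study design being tested: tryptic phosphopeptides from a set
# of proteins, two conditions (control and case) with per-peptide true
# abundance ratios, run-to-run retention-time distortion (linear plus
# segment-wise bumps), Gaussian chromatographic peaks sampled on a regular
# grid, multiplicative intensity noise, identification dropout, and
# target/decoy PSM score populations. Everything is reproducible from the
# seed, and every emitted observation traces back to the ledger.

#' Simulation configuration
#'
#' Defaults emulate a 120-min gradient with a 400-1600 Th acquisition window
#' and data-directed identification. Intensity noise (`noise_cv`) is
#' multiplicative per sampled chromatographic point; `abundance_cv` adds an
#' optional per-peptide-per-run abundance jitter (off by default).
#'
#' @param seed Integer seed (mandatory).
#' @param n_proteins,protein_length Number and length range of the synthetic
#'   proteins.
#' @param n_peptides Target number of phosphopeptides to carry through the
#'   experiment.
#' @param phospho_prob Probability that each S/T/Y of a selected peptide is
#'   phosphorylated (at least one site is always placed).
#' @param charge_probs Named probabilities of the charge states.
#' @param gradient Gradient span (min).
#' @param mz_range Acquisition m/z window (Th); peptides outside are dropped.
#' @param peak_sigma Chromatographic peak SD (min).
#' @param sample_interval Sampling interval of the centroided trace (min).
#' @param log_intensity_mean,log_intensity_sd Natural-log mean and SD of the
#'   base peak amplitude.
#' @param ratio_log2_range True case/control log2-ratios are drawn uniformly
#'   from this range; use `c(0, 0)` for all-ratio-one data.
#' @param distortion_slope,distortion_intercept Ranges of the linear RT
#'   distortion applied to non-reference runs.
#' @param n_bumps,bump_max Number and maximum absolute offset (min) of
#'   segment-wise RT bumps.
#' @param noise_cv Coefficient of variation of per-point multiplicative noise.
#' @param abundance_cv CV of per-peptide-per-run abundance jitter.
#' @param dropout_prob Probability that a peptide is not identified in a run.
#' @param rt_jitter SD (min) of the identification elution-time error.
#' @param score_true_mean,score_true_sd,score_false_mean,score_false_sd
#'   Gaussian PSM score populations for true and false matches.
#' @param false_match_rate Expected false matches per run as a fraction of
#'   true identifications.
#' @param decoy_fraction Fraction of false matches hitting the decoy database.
#' @param n_runs_per_condition Replicate runs per condition.
#' @param conditions Named character vector `c(control = ..., case = ...)`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_proteins = 12, protein_length = c(150, 400),
                       n_peptides = 50, phospho_prob = 0.3,
                       charge_probs = c("2" = 0.6, "3" = 0.4),
                       gradient = c(0, 120), mz_range = c(400, 1600),
                       peak_sigma = 0.1, sample_interval = 0.01,
                       log_intensity_mean = log(1e5), log_intensity_sd = 0.5,
                       ratio_log2_range = c(-2, 2),
                       distortion_slope = c(0.95, 1.05),
                       distortion_intercept = c(-2, 2),
                       n_bumps = 3, bump_max = 0.6,
                       noise_cv = 0.1, abundance_cv = 0,
                       dropout_prob = 0.2, rt_jitter = 0.05,
                       score_true_mean = 60, score_true_sd = 10,
                       score_false_mean = 25, score_false_sd = 8,
                       false_match_rate = 0.3, decoy_fraction = 0.5,
                       n_runs_per_condition = 1,
                       conditions = c(control = "normal", case = "cataract")) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  probs <- c(phospho_prob, dropout_prob, decoy_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  stopifnot(gradient[1] < gradient[2], mz_range[1] < mz_range[2],
            peak_sigma > 0, sample_interval > 0, noise_cv >= 0,
            abundance_cv >= 0, n_runs_per_condition >= 1)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

.random_protein <- function(len) {
  paste(sample(names(amino_acid_masses()), len, replace = TRUE),
        collapse = "")
}

.lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog) # mean 1
}

.sim_distortion <- function(cfg, distort) {
  if (!distort) {
    return(list(slope = 1, intercept = 0,
                bumps = tibble::tibble(start = numeric(0), end = numeric(0),
                                       offset = numeric(0))))
  }
  nb <- if (cfg$n_bumps > 0) sample(0:cfg$n_bumps, 1) else 0L
  starts <- sort(stats::runif(nb, cfg$gradient[1], cfg$gradient[2] - 10))
  list(slope = stats::runif(1, cfg$distortion_slope[1], cfg$distortion_slope[2]),
       intercept = stats::runif(1, cfg$distortion_intercept[1],
                                cfg$distortion_intercept[2]),
       bumps = tibble::tibble(
         start = starts,
         end = pmin(starts + stats::runif(nb, 10, 30), cfg$gradient[2]),
         offset = stats::runif(nb, -cfg$bump_max, cfg$bump_max)))
}

.apply_distortion <- function(d, t) {
  out <- d$slope * t + d$intercept
  if (nrow(d$bumps) > 0) {
    for (i in seq_len(nrow(d$bumps))) {
      hit <- t >= d$bumps$start[i] & t < d$bumps$end[i]
      out[hit] <- out[hit] + d$bumps$offset[i]
    }
  }
  out
}

#' Simulate PSM scores with known labels
#'
#' True matches are target PSMs drawn from the true-score distribution; false
#' matches are split between targets and decoys according to the decoy
#' fraction and drawn from the false-score distribution. The `is_true_match`
#' column is the ground-truth label (the simulator's ledger).
#'
#' @param n_true,n_false Numbers of true and false matches.
#' @param config A [sim_config()] (score distribution and decoy-fraction
#'   fields are used).
#' @return Tibble with `peptide`, `score`, `is_decoy`, `run_id`,
#'   `is_true_match`.
#' @export
simulate_psm_scores <- function(n_true, n_false, config) {
  stopifnot(n_true >= 0, n_false >= 0)
  true_tab <- tibble::tibble(
    peptide = sprintf("TRUEPEP%05d", seq_len(n_true)),
    score = stats::rnorm(n_true, config$score_true_mean, config$score_true_sd),
    is_decoy = FALSE, run_id = "run1", is_true_match = TRUE)
  false_tab <- tibble::tibble(
    peptide = sprintf("FALSEPEP%05d", seq_len(n_false)),
    score = stats::rnorm(n_false, config$score_false_mean,
                         config$score_false_sd),
    is_decoy = stats::runif(n_false) < config$decoy_fraction,
    run_id = "run1", is_true_match = FALSE)
  dplyr::bind_rows(true_tab, false_tab)
}

#' Simulate a two-condition label-free LC-MS experiment
#'
#' Generates proteins, selects tryptic phosphopeptides (via the digestion and
#' mass machinery), assigns true abundance ratios and elution times, emits
#' Gaussian chromatographic peaks per run with per-point multiplicative noise,
#' produces identification lists with dropout, and draws target/decoy PSM
#' scores. All outputs are reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param proteins Optional named character vector of protein sequences; by
#'   default random proteins are generated.
#' @return List with `features` (tibble: `run_id`, `condition`, `mz`, `rt`,
#'   `intensity`), `identifications` (tibble: `run_id`, `peptide`, `mods`,
#'   `charge`, `rt`, `mz`, `score`), `psms` (target/decoy score table), and
#'   `ledger` (ground truth: per-peptide `peptides`, per-run `run_rt`,
#'   `distortions`, `psm_labels`).
#' @export
simulate_experiment <- function(config, proteins = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_experiment_impl(config, proteins))
}

.simulate_experiment_impl <- function(cfg, proteins) {
  if (is.null(proteins)) {
    lens <- sample(cfg$protein_length[1]:cfg$protein_length[2],
                   cfg$n_proteins, replace = TRUE)
    proteins <- stats::setNames(
      vapply(lens, .random_protein, ""),
      sprintf("SYNPROT%03d", seq_len(cfg$n_proteins)))
  }

  # candidate fully tryptic peptides with at least one S/T/Y
  cand <- purrr::imap(proteins, function(seq, acc) {
    frags <- tryptic_digest(seq, missed_cleavages = 0)
    frags$accession <- acc
    frags
  }) |> dplyr::bind_rows()
  cand <- cand[nchar(cand$peptide) >= 7 & nchar(cand$peptide) <= 25 &
                 stringr::str_detect(cand$peptide, "[STY]"), ]
  cand <- dplyr::distinct(cand, .data$peptide, .keep_all = TRUE)

  # build phosphopeptides until n_peptides fall inside the m/z window
  cand <- cand[sample(nrow(cand)), ]
  peps <- list()
  for (i in seq_len(nrow(cand))) {
    if (length(peps) >= cfg$n_peptides) break
    pep <- cand$peptide[i]
    sty <- which(strsplit(pep, "")[[1]] %in% c("S", "T", "Y"))
    chosen <- sty[stats::runif(length(sty)) < cfg$phospho_prob]
    if (length(chosen) == 0) chosen <- sty[sample(length(sty), 1)]
    charge <- as.integer(sample(names(cfg$charge_probs), 1,
                                prob = cfg$charge_probs))
    mods <- lapply(chosen, function(p) list(position = p, spec = mod_phospho()))
    mz <- mass_to_mz(peptide_mass(pep, mods), charge)
    if (mz < cfg$mz_range[1] || mz > cfg$mz_range[2]) next # outside window
    peps[[length(peps) + 1L]] <- tibble::tibble(
      accession = cand$accession[i], peptide = pep,
      mods = paste0("phospho@", paste(chosen, collapse = "+")),
      sites = list(chosen), charge = charge, mz = mz)
  }
  peptides <- dplyr::bind_rows(peps)
  if (nrow(peptides) == 0) {
    stop("configuration produced zero usable phosphopeptides", call. = FALSE)
  }

  margin <- 4 * cfg$peak_sigma + 1
  peptides$key <- paste(peptides$peptide, peptides$mods, peptides$charge,
                        sep = "/")
  peptides$base_rt <- stats::runif(nrow(peptides),
                                   cfg$gradient[1] + margin,
                                   cfg$gradient[2] - margin)
  peptides$base_intensity <- stats::rlnorm(nrow(peptides),
                                           cfg$log_intensity_mean,
                                           cfg$log_intensity_sd)
  peptides$true_ratio <- 2^stats::runif(nrow(peptides),
                                        cfg$ratio_log2_range[1],
                                        cfg$ratio_log2_range[2])

  runs <- tibble::tibble(
    run_id = c(sprintf("%s_%d", cfg$conditions[["control"]],
                       seq_len(cfg$n_runs_per_condition)),
               sprintf("%s_%d", cfg$conditions[["case"]],
                       seq_len(cfg$n_runs_per_condition))),
    condition = rep(unname(cfg$conditions), each = cfg$n_runs_per_condition))

  distortions <- lapply(stats::setNames(runs$run_id, runs$run_id), function(r) {
    .sim_distortion(cfg, distort = !identical(r, runs$run_id[1]))
  })

  features <- list()
  run_rt <- list()
  idents <- list()
  for (i in seq_len(nrow(runs))) {
    r <- runs$run_id[i]
    cond <- runs$condition[i]
    is_case <- cond == cfg$conditions[["case"]]
    d <- distortions[[r]]
    rt_run <- .apply_distortion(d, peptides$base_rt)
    amp <- peptides$base_intensity *
      (if (is_case) peptides$true_ratio else 1) *
      .lognormal_factor(nrow(peptides), cfg$abundance_cv)
    run_rt[[i]] <- tibble::tibble(key = peptides$key, run_id = r,
                                  true_rt = rt_run, true_amplitude = amp)
    pts <- purrr::map(seq_len(nrow(peptides)), function(j) {
      tt <- seq(rt_run[j] - 4 * cfg$peak_sigma, rt_run[j] + 4 * cfg$peak_sigma,
                by = cfg$sample_interval)
      tt <- tt[tt >= cfg$gradient[1] & tt <= cfg$gradient[2]]
      inten <- amp[j] * exp(-(tt - rt_run[j])^2 / (2 * cfg$peak_sigma^2)) *
        .lognormal_factor(length(tt), cfg$noise_cv)
      tibble::tibble(run_id = r, condition = cond, key = peptides$key[j],
                     mz = peptides$mz[j], rt = tt, intensity = inten)
    })
    features[[i]] <- dplyr::bind_rows(pts)
    identified <- stats::runif(nrow(peptides)) >= cfg$dropout_prob
    idents[[i]] <- tibble::tibble(
      run_id = r, peptide = peptides$peptide[identified],
      mods = peptides$mods[identified], charge = peptides$charge[identified],
      rt = rt_run[identified] +
        stats::rnorm(sum(identified), 0, cfg$rt_jitter),
      mz = peptides$mz[identified],
      score = stats::rnorm(sum(identified), cfg$score_true_mean,
                           cfg$score_true_sd))
  }
  features <- dplyr::bind_rows(features)
  identifications <- dplyr::bind_rows(idents)

  n_true <- nrow(identifications)
  n_false <- stats::rpois(1, cfg$false_match_rate * max(n_true, 1))
  psms <- simulate_psm_scores(n_true, n_false, cfg)
  psms$peptide[psms$is_true_match] <-
    paste(identifications$peptide, identifications$mods,
          identifications$charge, sep = "/")
  psms$run_id[psms$is_true_match] <- identifications$run_id
  psms$score[psms$is_true_match] <- identifications$score

  list(
    features = features,
    identifications = identifications,
    psms = psms[, c("peptide", "score", "is_decoy", "run_id")],
    ledger = list(
      peptides = peptides[, c("key", "accession", "peptide", "mods", "sites",
                              "charge", "mz", "base_rt", "base_intensity",
                              "true_ratio")],
      run_rt = dplyr::bind_rows(run_rt),
      distortions = distortions,
      psm_labels = psms[, c("peptide", "score", "is_decoy", "run_id",
                            "is_true_match")]
    ),
    runs = runs,
    config = cfg
  )
}
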