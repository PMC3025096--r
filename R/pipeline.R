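# Pipeline orchestration and the command-line entry point.
#
# Each subcommand is a thin wrapper over the module functions; the CLI script
# in inst/scripts/lensphos calls cli_main() and exits with its return value.
# Exit codes: 0 success, 2 usage error, 3 validation failure, 4 runtime data
# error.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.log_line <- function(...) message("[lensphos] ", sprintf(...))

.log_inputs <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) > 0) {
    sums <- tools::md5sum(paths)
    for (p in names(sums)) .log_line("input %s md5=%s", p, sums[[p]])
  }
}

#' Assemble a full catalog / differential / quantitation report
#'
#' Combines the catalog summary of the identification table, the differential
#' classification and novelty comparison of the two-condition table, and
#' (optionally) quantitation recovery metrics from a simulated experiment,
#' into one list ready for JSON serialization.
#'
#' @param catalog Tibble from [load_catalog()] (full site catalog).
#' @param differential Tibble from [load_catalog()] (two-condition catalog
#'   with ratios).
#' @param known_sites Known-site table or path (see [compare_novelty()]).
#' @param fold_threshold Fold threshold for [classify_differential()].
#' @param quant_metrics Optional list of quantitation recovery metrics to
#'   embed verbatim.
#' @return Nested list.
#' @export
pipeline_report <- function(catalog, differential, known_sites = NULL,
                            fold_threshold = 2, quant_metrics = NULL) {
  summ <- summarize_catalog(catalog)
  diff <- classify_differential(differential, fold_threshold)
  out <- list(
    catalog = list(
      n_sites = summ$n_sites, n_proteins = summ$n_proteins,
      n_crystallin = summ$n_crystallin,
      n_noncrystallin = summ$n_noncrystallin,
      residue_distribution = as.data.frame(summ$residues)
    ),
    differential = diff$counts
  )
  if (!is.null(known_sites)) {
    out$novelty <- compare_novelty(differential, known_sites)$counts
  }
  if (!is.null(quant_metrics)) out$quant_recovery <- quant_metrics
  out
}

.cli_spec <- list(
  simulate = "simulate --seed INT --out-dir DIR [--n-peptides INT] [--noise-cv X] [--dropout X]",
  `filter-fdr` = "filter-fdr --psms TSV --out JSON (--alpha X | --score-threshold X)",
  quantify = "quantify --features TSV --identifications TSV --out TSV [--mz-tol X] [--rt-halfwidth X]",
  `catalog-stats` = "catalog-stats --catalog TSV --out JSON",
  `catalog-validate` = "catalog-validate --catalog TSV [--fasta FA] --out TSV",
  `mz-check` = "mz-check --catalog TSV --out TSV",
  `diff-summary` = "diff-summary --catalog TSV [--known-sites TSV] [--fold-threshold X] --out JSON",
  report = "report --catalog TSV --differential TSV [--known-sites TSV] [--fold-threshold X] --out JSON"
)

.cli_usage <- function() {
  message("usage: lensphos <subcommand> [options]\nsubcommands:")
  for (s in .cli_spec) message("  ", s)
  2L
}

.cli_getopt <- function(args, flags) {
  # flags: named list default values; NA_character_ etc. mark value-taking
  out <- flags
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop("unexpected argument: ", a, call. = FALSE)
    }
    name <- substring(a, 3)
    if (!name %in% names(flags)) stop("unknown flag: ", a, call. = FALSE)
    if (i + 1L > length(args)) stop("flag ", a, " needs a value", call. = FALSE)
    out[[name]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`simulate`, `filter-fdr`, `quantify`,
#' `catalog-stats`, `catalog-validate`, `mz-check`, `diff-summary`,
#' `report`). Called by the Rscript wrapper in
#' `system.file("scripts", "lensphos", package = "lensphos")`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 success, 2 usage, 3 validation failure,
#'   4 runtime data error).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || !args[1] %in% names(.cli_spec)) {
    return(.cli_usage())
  }
  sub <- args[1]
  rest <- args[-1]
  .log_line("lensphos %s | subcommand: %s | args: %s",
            as.character(packageVersion("lensphos")), sub,
            paste(rest, collapse = " "))
  status <- tryCatch({
    switch(sub,
      simulate = .cli_simulate(rest),
      `filter-fdr` = .cli_filter_fdr(rest),
      quantify = .cli_quantify(rest),
      `catalog-stats` = .cli_catalog_stats(rest),
      `catalog-validate` = .cli_catalog_validate(rest),
      `mz-check` = .cli_mz_check(rest),
      `diff-summary` = .cli_diff_summary(rest),
      report = .cli_report(rest)
    )
  },
  lensphos_usage = function(e) { message("usage error: ", conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 4L })
  status
}

.usage_stop <- function(...) {
  stop(structure(class = c("lensphos_usage", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

.need <- function(opt, name) {
  if (is.na(opt[[name]]) || is.null(opt[[name]])) {
    .usage_stop("missing required flag --", name)
  }
  opt[[name]]
}

.cli_simulate <- function(args) {
  opt <- .cli_getopt(args, list(seed = NA, `out-dir` = NA,
                                `n-peptides` = "50", `noise-cv` = "0.1",
                                dropout = "0.2"))
  seed <- as.integer(.need(opt, "seed"))
  dir <- .need(opt, "out-dir")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(seed = seed,
                    n_peptides = as.integer(opt$`n-peptides`),
                    noise_cv = as.numeric(opt$`noise-cv`),
                    dropout_prob = as.numeric(opt$dropout))
  sim <- simulate_experiment(cfg)
  readr::write_tsv(sim$features, file.path(dir, "features.tsv"))
  readr::write_tsv(sim$identifications, file.path(dir, "identifications.tsv"))
  readr::write_tsv(sim$psms, file.path(dir, "psms.tsv"))
  ledger <- sim$ledger$peptides
  ledger$sites <- vapply(ledger$sites, paste, "", collapse = "+")
  readr::write_tsv(ledger, file.path(dir, "ledger_peptides.tsv"))
  readr::write_tsv(sim$ledger$run_rt, file.path(dir, "ledger_run_rt.tsv"))
  .log_line("simulated %d peptides, %d feature points, %d PSMs -> %s",
            nrow(ledger), nrow(sim$features), nrow(sim$psms), dir)
  0L
}

.cli_filter_fdr <- function(args) {
  opt <- .cli_getopt(args, list(psms = NA, out = NA, alpha = NA,
                                `score-threshold` = NA))
  psms_path <- .need(opt, "psms"); out <- .need(opt, "out")
  has_alpha <- !is.na(opt$alpha); has_thr <- !is.na(opt$`score-threshold`)
  if (has_alpha == has_thr) {
    .usage_stop("exactly one of --alpha and --score-threshold must be given")
  }
  .log_inputs(psms_path)
  psms <- read_psms(psms_path)
  rep <- if (has_thr) {
    fdr_report(psms, as.numeric(opt$`score-threshold`))
  } else {
    thr <- threshold_for_fdr(psms, as.numeric(opt$alpha))
    fdr_report(psms, thr - 1e-9)
  }
  .write_json(rep, out)
  .log_line("FDR %.4f at threshold %.3f -> %s", rep$fdr, rep$threshold, out)
  0L
}

.cli_quantify <- function(args) {
  opt <- .cli_getopt(args, list(features = NA, identifications = NA, out = NA,
                                `mz-tol` = "0.05", `rt-halfwidth` = "1",
                                control = "normal", case = "cataract"))
  fpath <- .need(opt, "features"); ipath <- .need(opt, "identifications")
  out <- .need(opt, "out")
  .log_inputs(c(fpath, ipath))
  cfg <- quant_config(mz_tol = as.numeric(opt$`mz-tol`),
                      rt_halfwidth = as.numeric(opt$`rt-halfwidth`),
                      control = opt$control, case = opt$case)
  feats <- read_features(fpath, cfg$gradient)
  ids <- readr::read_tsv(ipath, show_col_types = FALSE)
  glist <- build_global_list(ids, mz_tol = cfg$mz_tol)
  res <- quantify(feats, glist, cfg)
  readr::write_tsv(dplyr::select(res, -"runs"), out)
  .log_line("quantified %d peptide keys -> %s", nrow(res), out)
  0L
}

.cli_catalog_stats <- function(args) {
  opt <- .cli_getopt(args, list(catalog = NA, out = NA))
  path <- .need(opt, "catalog"); out <- .need(opt, "out")
  .log_inputs(path)
  summ <- summarize_catalog(load_catalog(path))
  .write_json(list(
    n_sites = summ$n_sites, n_proteins = summ$n_proteins,
    n_crystallin = summ$n_crystallin,
    n_noncrystallin = summ$n_noncrystallin,
    residue_distribution = as.data.frame(summ$residues)
  ), out)
  .log_line("%d sites on %d proteins -> %s", summ$n_sites, summ$n_proteins, out)
  0L
}

.cli_catalog_validate <- function(args) {
  opt <- .cli_getopt(args, list(catalog = NA, fasta = NA, out = NA))
  path <- .need(opt, "catalog"); out <- .need(opt, "out")
  .log_inputs(path)
  proteins <- if (!is.na(opt$fasta)) read_fasta(opt$fasta) else NULL
  report <- validate_catalog(load_catalog(path), proteins)
  readr::write_tsv(report, out)
  n_warn <- sum(report$status == "warn")
  .log_line("%d checks, %d warnings -> %s", nrow(report), n_warn, out)
  if (n_warn > 0) 3L else 0L
}

.cli_mz_check <- function(args) {
  opt <- .cli_getopt(args, list(catalog = NA, out = NA))
  path <- .need(opt, "catalog"); out <- .need(opt, "out")
  .log_inputs(path)
  conc <- mz_concordance(load_catalog(path))
  readr::write_tsv(conc, out)
  s <- attr(conc, "summary")
  .log_line("median |dm/z| %.4f Th, max %.4f Th over %d rows -> %s",
            s$median_abs_delta, s$max_abs_delta, s$n, out)
  0L
}

.cli_diff_summary <- function(args) {
  opt <- .cli_getopt(args, list(catalog = NA, `known-sites` = NA, out = NA,
                                `fold-threshold` = "2"))
  path <- .need(opt, "catalog"); out <- .need(opt, "out")
  .log_inputs(path)
  cat <- load_catalog(path)
  diff <- classify_differential(cat, as.numeric(opt$`fold-threshold`))
  res <- list(differential = diff$counts)
  if (!is.na(opt$`known-sites`)) {
    res$novelty <- compare_novelty(cat, opt$`known-sites`)$counts
  }
  .write_json(res, out)
  .log_line("%d sites: %d up / %d down / %d unchanged -> %s",
            diff$counts$n_sites, diff$counts$increased, diff$counts$decreased,
            diff$counts$unchanged, out)
  0L
}

.cli_report <- function(args) {
  opt <- .cli_getopt(args, list(catalog = NA, differential = NA,
                                `known-sites` = NA, `fold-threshold` = "2",
                                out = NA))
  cpath <- .need(opt, "catalog"); dpath <- .need(opt, "differential")
  out <- .need(opt, "out")
  .log_inputs(c(cpath, dpath))
  known <- if (!is.na(opt$`known-sites`)) opt$`known-sites` else NULL
  rep <- pipeline_report(load_catalog(cpath), load_catalog(dpath),
                         known_sites = known,
                         fold_threshold = as.numeric(opt$`fold-threshold`))
  .write_json(rep, out)
  txt <- sub("\\.json$", ".txt", out)
  lines <- c(
    sprintf("Catalog: %d sites on %d proteins (%d crystallin, %d other)",
            rep$catalog$n_sites, rep$catalog$n_proteins,
            rep$catalog$n_crystallin, rep$catalog$n_noncrystallin),
    sprintf("Differential: %d sites on %d proteins; %d up / %d down / %d unchanged",
            rep$differential$n_sites, rep$differential$n_proteins,
            rep$differential$increased, rep$differential$decreased,
            rep$differential$unchanged))
  if (!is.null(rep$novelty)) {
    lines <- c(lines, sprintf("Novel sites: %d (of which %d on %d crystallins)",
                              rep$novelty$n_novel,
                              rep$novelty$n_novel_crystallin,
                              rep$novelty$n_crystallin_proteins_with_novel))
  }
  writeLines(lines, txt)
  .log_line("report -> %s, %s", out, txt)
  0L
}
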