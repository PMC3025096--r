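# Target-decoy false-discovery-rate estimation for PSM score tables, and
# decoy sequence generation.
#
# The estimator is D/T from a *separate* decoy search: the decoy database is
# searched with identical parameters, and the FDR at a score threshold t is
# the number of decoy PSMs scoring above t divided by the number of target
# PSMs scoring above t (strict inequality).

#' Generate decoy protein sequences
#'
#' One decoy per target sequence, preserving length and residue composition.
#' `"reverse"` reverses each sequence (deterministic); `"shuffle"` permutes
#' residues and requires a seed.
#'
#' @param sequences Named character vector of protein sequences.
#' @param mode `"reverse"` (default) or `"shuffle"`.
#' @param seed Integer seed, mandatory for `"shuffle"`.
#' @param tag Prefix added to each accession (default `"DECOY_"`).
#' @return Named character vector of decoy sequences.
#' @export
#' @examples
#' generate_decoys(c(P1 = "PEPTIDE")) # DECOY_P1 = "EDITPEP"
generate_decoys <- function(sequences, mode = c("reverse", "shuffle"),
                            seed = NULL, tag = "DECOY_") {
  mode <- match.arg(mode)
  if (length(sequences) == 0) stop("no input sequences", call. = FALSE)
  if (mode == "shuffle" && is.null(seed)) {
    stop("shuffle mode requires a seed", call. = FALSE)
  }
  flip <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  decoys <- if (mode == "reverse") {
    vapply(sequences, flip, "")
  } else {
    withr::with_seed(seed, vapply(sequences, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, ""))
  }
  names(decoys) <- paste0(tag, names(sequences))
  decoys
}

.check_psms <- function(psms) {
  if (!all(c("score", "is_decoy") %in% names(psms))) {
    stop("PSM table needs columns score and is_decoy", call. = FALSE)
  }
  if (!all(is.finite(psms$score))) stop("non-finite PSM score", call. = FALSE)
  if (!any(!psms$is_decoy)) stop("PSM table has no target records", call. = FALSE)
  psms
}

#' Read a PSM table from TSV
#'
#' Expected columns: `peptide`, `score`, `is_decoy`, `run_id` (extra columns
#' are kept).
#'
#' @param path Path to the TSV.
#' @return Tibble.
#' @export
read_psms <- function(path) {
  psms <- readr::read_tsv(path, show_col_types = FALSE)
  psms$is_decoy <- as.logical(psms$is_decoy)
  .check_psms(psms)
}

#' Target-decoy FDR at a score threshold
#'
#' `FDR = #(decoys with score > t) / #(targets with score > t)` (strict
#' inequality). If no target passes, the estimate is undefined and a classed
#' error (`lensphos_no_passing_targets`) is signaled.
#'
#' @param psms Tibble with `score` and `is_decoy`.
#' @param threshold Score threshold t.
#' @return FDR estimate in `[0, Inf)`, with attributes `n_targets` and
#'   `n_decoys` (passing counts).
#' @export
#' @examples
#' psms <- tibble::tibble(score = c(50, 40, 38, 20, 39, 10),
#'                        is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
#' fdr_at_threshold(psms, 36) # 1/3
fdr_at_threshold <- function(psms, threshold) {
  .check_psms(psms)
  t_pass <- sum(!psms$is_decoy & psms$score > threshold)
  d_pass <- sum(psms$is_decoy & psms$score > threshold)
  if (t_pass == 0) {
    stop(structure(
      class = c("lensphos_no_passing_targets", "error", "condition"),
      list(message = sprintf("no target PSM passes score > %s; FDR undefined",
                             format(threshold)),
           call = sys.call(-1))))
  }
  structure(d_pass / t_pass, n_targets = t_pass, n_decoys = d_pass)
}

#' Smallest score threshold achieving a target FDR
#'
#' Candidate thresholds are the observed target scores; the passing set for a
#' candidate t is every PSM with score >= t (i.e. "score > t'", t' just below
#' t). Returns the smallest candidate whose passing set achieves FDR <= alpha
#' (ties broken toward the smaller score, i.e. the larger passing set).
#'
#' @param psms Tibble with `score` and `is_decoy`.
#' @param alpha Target FDR in `[0, 1)`.
#' @return The threshold score, with attributes `fdr`, `n_targets`,
#'   `n_decoys` for its passing set.
#' @export
threshold_for_fdr <- function(psms, alpha) {
  .check_psms(psms)
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)", call. = FALSE)
  cand <- sort(unique(psms$score[!psms$is_decoy]))
  tscore <- psms$score[!psms$is_decoy]
  dscore <- psms$score[psms$is_decoy]
  for (t in cand) {
    T <- sum(tscore >= t)
    D <- sum(dscore >= t)
    if (D / T <= alpha) {
      return(structure(t, fdr = D / T, n_targets = T, n_decoys = D))
    }
  }
  stop("no score threshold achieves FDR <= ", alpha, call. = FALSE)
}

#' JSON-ready FDR report at a threshold
#'
#' @param psms Tibble with `score` and `is_decoy`.
#' @param threshold Score threshold.
#' @return List with `threshold`, `n_targets_passing`, `n_decoys_passing`,
#'   `fdr`.
#' @export
fdr_report <- function(psms, threshold) {
  est <- fdr_at_threshold(psms, threshold)
  list(threshold = threshold,
       n_targets_passing = attr(est, "n_targets"),
       n_decoys_passing = attr(est, "n_decoys"),
       fdr = as.numeric(est))
}
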