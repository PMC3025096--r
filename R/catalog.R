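# Phosphosite catalog: loading, validation, summary statistics, differential
# classification, novelty comparison and m/z concordance reporting.
#
# A catalog is a tibble with one row per phosphopeptide observation. A *site*
# is identified by (accession, designation); several observations (charge
# states, overlapping peptides) may cover the same site.

.CATALOG_MANDATORY <- c("accession", "protein_name", "peptide", "designation")
.CATALOG_OPTIONAL <- c("is_crystallin", "mz", "charge", "score", "pn_ratio",
                       "novel")

#' Load a phosphosite catalog from TSV
#'
#' Mandatory columns: `accession`, `protein_name`, `peptide`, `designation`,
#' plus fragment coordinates given either as integer columns
#' `frag_start`/`frag_end` or as a single `fragment` column such as `"12-22"`
#' (hyphen or en-dash). Optional columns: `is_crystallin`, `mz`, `charge`,
#' `score`, `pn_ratio`, `novel` (`yes`/`no`, blank = not novel). When
#' `is_crystallin` is absent it is derived from `protein_name` containing
#' "crystallin". Source row numbers are retained in column `row` for
#' diagnostics.
#'
#' @param path Path to a TSV file (UTF-8).
#' @return Tibble of phosphosite records.
#' @export
#' @examples
#' tab1 <- load_catalog(system.file("extdata", "table1_sites.tsv",
#'                                  package = "lensphos"))
#' nrow(tab1) # 73
load_catalog <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(.CATALOG_MANDATORY, names(raw))
  if (length(missing) > 0) {
    stop("catalog is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw$row <- seq_len(nrow(raw))

  if (all(c("frag_start", "frag_end") %in% names(raw))) {
    raw$frag_start <- as.integer(raw$frag_start)
    raw$frag_end <- as.integer(raw$frag_end)
  } else if ("fragment" %in% names(raw)) {
    m <- stringr::str_match(raw$fragment, "^\\s*(\\d+)\\s*[-–—]\\s*(\\d+)\\s*$")
    bad <- which(is.na(m[, 1]))
    if (length(bad) > 0) {
      stop("unparseable fragment range in row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    raw$frag_start <- as.integer(m[, 2])
    raw$frag_end <- as.integer(m[, 3])
  } else {
    stop("catalog is missing mandatory column(s): frag_start/frag_end ",
         "(or a combined 'fragment' column)", call. = FALSE)
  }
  inverted <- which(raw$frag_start > raw$frag_end)
  if (length(inverted) > 0) {
    stop("inverted fragment range (start > end) in row(s): ",
         paste(inverted, collapse = ", "), call. = FALSE)
  }

  out <- tibble::tibble(
    row = raw$row,
    accession = raw$accession,
    protein_name = raw$protein_name,
    is_crystallin = if ("is_crystallin" %in% names(raw)) {
      toupper(raw$is_crystallin) %in% c("TRUE", "T", "YES", "1")
    } else {
      stringr::str_detect(tolower(raw$protein_name), "crystallin")
    },
    frag_start = raw$frag_start,
    frag_end = raw$frag_end,
    peptide = raw$peptide,
    designation = raw$designation
  )
  if ("mz" %in% names(raw)) out$mz <- as.numeric(raw$mz)
  if ("charge" %in% names(raw)) out$charge <- as.integer(raw$charge)
  if ("score" %in% names(raw)) out$score <- as.numeric(raw$score)
  if ("pn_ratio" %in% names(raw)) {
    out$pn_ratio <- as.numeric(raw$pn_ratio)
    nonpos <- which(!is.na(out$pn_ratio) & out$pn_ratio <= 0)
    if (length(nonpos) > 0) {
      stop("nonpositive abundance ratio in row(s): ",
           paste(nonpos, collapse = ", "), call. = FALSE)
    }
  }
  if ("novel" %in% names(raw)) {
    out$novel <- !is.na(raw$novel) & tolower(raw$novel) %in% c("yes", "true", "1")
  }
  # fail early on malformed designations
  parse_designation(out$designation)
  out
}

#' Validate catalog records
#'
#' Per-record checks, reported (never silently dropped, never mutating):
#' * `designation_in_fragment` — the designated protein position lies within
#'   the fragment range;
#' * `designation_residue` — the peptide residue at the designated offset
#'   matches the residue named in the designation (only checked when the
#'   position is in range);
#' * `peptide_in_protein` — if `proteins` is given and contains the accession,
#'   the peptide equals the protein subsequence at the fragment coordinates.
#'
#' @param catalog Tibble from [load_catalog()].
#' @param proteins Optional named character vector of protein sequences (see
#'   [read_fasta()]).
#' @return Tibble with `row`, `accession`, `designation`, `check`, `status`
#'   (`"pass"`/`"warn"`), `detail`.
#' @export
validate_catalog <- function(catalog, proteins = NULL) {
  des <- parse_designation(catalog$designation)
  findings <- purrr::pmap(
    list(catalog$row, catalog$accession, catalog$designation,
         catalog$frag_start, catalog$frag_end, catalog$peptide,
         des$residue1, des$position),
    function(row, acc, desig, start, end, pep, res1, pos) {
      out <- list()
      in_range <- pos >= start && pos <= end
      out[[1]] <- tibble::tibble(
        row = row, accession = acc, designation = desig,
        check = "designation_in_fragment",
        status = if (in_range) "pass" else "warn",
        detail = if (in_range) "" else
          sprintf("position %d outside fragment %d-%d", pos, start, end)
      )
      if (in_range) {
        offset <- pos - start + 1L
        actual <- substr(pep, offset, offset)
        ok <- identical(actual, res1)
        out[[length(out) + 1L]] <- tibble::tibble(
          row = row, accession = acc, designation = desig,
          check = "designation_residue",
          status = if (ok) "pass" else "warn",
          detail = if (ok) "" else
            sprintf("peptide residue at offset %d is '%s', expected '%s'",
                    offset, actual, res1)
        )
      }
      if (!is.null(proteins) && acc %in% names(proteins)) {
        sub <- substr(proteins[[acc]], start, end)
        ok <- identical(sub, pep)
        out[[length(out) + 1L]] <- tibble::tibble(
          row = row, accession = acc, designation = desig,
          check = "peptide_in_protein",
          status = if (ok) "pass" else "warn",
          detail = if (ok) "" else
            sprintf("protein subsequence %d-%d is '%s'", start, end, sub)
        )
      }
      dplyr::bind_rows(out)
    }
  )
  dplyr::bind_rows(findings)
}

.unique_sites <- function(catalog) {
  dplyr::distinct(catalog, .data$accession, .data$designation, .keep_all = TRUE)
}

#' Summarize a phosphosite catalog
#'
#' Counts unique sites (keyed by accession + designation), proteins, the
#' crystallin / non-crystallin partition, and the Ser/Thr/Tyr site
#' distribution. Percentages are reported both at 0.1% precision and rounded
#' to the nearest integer.
#'
#' @param catalog Tibble from [load_catalog()].
#' @return Object of class `catalog_summary`: a list with `n_sites`,
#'   `n_proteins`, `n_crystallin`, `n_noncrystallin`, `residues` (tibble with
#'   `residue`, `n`, `pct`, `pct_int`), and `sites_by_protein`.
#' @export
summarize_catalog <- function(catalog) {
  if (nrow(catalog) == 0) stop("catalog is empty", call. = FALSE)
  sites <- .unique_sites(catalog)
  des <- parse_designation(sites$designation)
  sites$residue <- des$residue1
  prot <- dplyr::distinct(sites, .data$accession, .data$is_crystallin)
  residues <- sites |>
    dplyr::count(.data$residue) |>
    dplyr::right_join(tibble::tibble(residue = c("S", "T", "Y")),
                      by = "residue") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  pct = round(100 * .data$n / nrow(sites), 1),
                  pct_int = as.integer(round(100 * .data$n / nrow(sites))))
  structure(list(
    n_sites = nrow(sites),
    n_proteins = nrow(prot),
    n_crystallin = sum(prot$is_crystallin),
    n_noncrystallin = sum(!prot$is_crystallin),
    residues = residues,
    sites_by_protein = sites |>
      dplyr::group_by(.data$accession, .data$protein_name,
                      .data$is_crystallin) |>
      dplyr::summarise(n_sites = dplyr::n(),
                       sites = list(.data$designation), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$n_sites))
  ), class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("Phosphosite catalog: %d sites on %d proteins (%d crystallin, %d other)\n",
              x$n_sites, x$n_proteins, x$n_crystallin, x$n_noncrystallin))
  with(x$residues, cat(sprintf("  %s: %d sites (%.1f%%, ~%d%%)\n",
                               residue, n, pct, pct_int), sep = ""))
  invisible(x)
}

#' Classify sites as increased / decreased / unchanged
#'
#' Aggregates multiple observations of one site (e.g. two charge states) by the
#' median ratio, then classifies against a fold threshold: increased if
#' `ratio >= fold_threshold`, decreased if `ratio <= 1/fold_threshold`, else
#' unchanged.
#'
#' @param catalog Tibble with a `pn_ratio` on every row.
#' @param fold_threshold Fold-change threshold, > 1 (default 2).
#' @return Object of class `differential_summary`: list with `sites` (tibble
#'   with per-site `ratio` and `class`) and `counts`.
#' @export
classify_differential <- function(catalog, fold_threshold = 2) {
  if (!"pn_ratio" %in% names(catalog) || anyNA(catalog$pn_ratio)) {
    stop("every record needs a pn_ratio for differential classification",
         call. = FALSE)
  }
  if (any(catalog$pn_ratio <= 0)) {
    stop("nonpositive abundance ratio", call. = FALSE)
  }
  if (fold_threshold <= 1) stop("fold_threshold must be > 1", call. = FALSE)
  sites <- catalog |>
    dplyr::group_by(.data$accession, .data$protein_name, .data$is_crystallin,
                    .data$designation) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      ratio = stats::median(.data$pn_ratio),
      novel = if ("novel" %in% names(catalog)) any(.data$novel) else NA,
      .groups = "drop"
    ) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$ratio >= fold_threshold ~ "increased",
      .data$ratio <= 1 / fold_threshold ~ "decreased",
      TRUE ~ "unchanged"
    ))
  counts <- list(
    n_sites = nrow(sites),
    n_proteins = dplyr::n_distinct(sites$accession),
    increased = sum(sites$class == "increased"),
    decreased = sum(sites$class == "decreased"),
    unchanged = sum(sites$class == "unchanged")
  )
  structure(list(sites = sites, counts = counts, fold_threshold = fold_threshold),
            class = "differential_summary")
}

#' @export
print.differential_summary <- function(x, ...) {
  c <- x$counts
  cat(sprintf(
    "Differential phosphosites (fold threshold %.3g): %d sites on %d proteins\n",
    x$fold_threshold, c$n_sites, c$n_proteins))
  cat(sprintf("  increased: %d  decreased: %d  unchanged: %d\n",
              c$increased, c$decreased, c$unchanged))
  invisible(x)
}

#' Compare catalog sites against a known-site list
#'
#' A site is novel iff its (accession, designation) pair is absent from
#' `known_sites`. Counts are reported overall and split by the crystallin
#' flag.
#'
#' @param catalog Tibble from [load_catalog()].
#' @param known_sites Data frame with columns `accession` and `designation`
#'   (e.g. exported from a phosphosite database), or a path to such a TSV.
#' @return List with `records` (unique sites annotated with `novel`) and
#'   `counts` (`n_sites`, `n_novel`, `n_novel_crystallin`,
#'   `n_novel_noncrystallin`, `n_crystallin_proteins_with_novel`).
#' @export
compare_novelty <- function(catalog, known_sites) {
  if (is.character(known_sites) && length(known_sites) == 1L) {
    known_sites <- readr::read_tsv(known_sites, show_col_types = FALSE)
  }
  if (!all(c("accession", "designation") %in% names(known_sites))) {
    stop("known_sites needs columns accession and designation", call. = FALSE)
  }
  sites <- .unique_sites(catalog)
  key <- paste(sites$accession, sites$designation)
  known <- paste(known_sites$accession, known_sites$designation)
  sites$novel <- !(key %in% known)
  cry_novel <- sites[sites$novel & sites$is_crystallin, ]
  counts <- list(
    n_sites = nrow(sites),
    n_novel = sum(sites$novel),
    n_novel_crystallin = nrow(cry_novel),
    n_novel_noncrystallin = sum(sites$novel & !sites$is_crystallin),
    n_crystallin_proteins_with_novel = dplyr::n_distinct(cry_novel$accession)
  )
  list(records = sites, counts = counts)
}

#' Theoretical-vs-printed m/z concordance
#'
#' Recomputes the theoretical m/z of each catalog peptide (assuming
#' `n_phospho` phosphate groups; default one, as each row designates a single
#' site) and compares it to the recorded observed m/z. Because Met oxidation
#' was a variable search modification, peptides containing Met are tried with
#' 0..nMet oxidations and the best-matching state is reported
#' (`variable_oxidation = FALSE` disables this).
#'
#' @param catalog Tibble with `peptide`, `mz`, `charge` columns.
#' @param n_phospho Number of phosphate groups assumed per peptide.
#' @param variable_oxidation Consider variable Met oxidation when matching.
#' @return Tibble with `row`, `peptide`, `charge`, `mz_obs`, `mz_theo`,
#'   `n_oxidation`, `delta_th`, `delta_ppm`; records without a charge are
#'   skipped and listed in attribute `skipped`. Attribute `summary` holds the
#'   median and max absolute deviation.
#' @export
mz_concordance <- function(catalog, n_phospho = 1L, variable_oxidation = TRUE) {
  if (!all(c("mz", "charge") %in% names(catalog))) {
    stop("catalog needs mz and charge columns for concordance", call. = FALSE)
  }
  usable <- !is.na(catalog$mz) & !is.na(catalog$charge)
  skipped <- catalog$row[!usable]
  if (length(skipped) > 0) {
    message("skipping ", length(skipped), " record(s) without m/z or charge: row ",
            paste(skipped, collapse = ", "))
  }
  cat2 <- catalog[usable, ]
  phos_delta <- n_phospho * mod_phospho()$delta
  ox_delta <- mod_oxidation()$delta
  res <- purrr::pmap(
    list(cat2$row, cat2$peptide, cat2$mz, cat2$charge),
    function(row, pep, obs, z) {
      base <- peptide_mass(pep) + phos_delta
      n_met <- stringr::str_count(pep, "M")
      n_ox <- if (variable_oxidation) 0:n_met else 0L
      theo <- mass_to_mz(base + n_ox * ox_delta, z)
      best <- which.min(abs(theo - obs))
      tibble::tibble(row = row, peptide = pep, charge = z, mz_obs = obs,
                     mz_theo = theo[best], n_oxidation = n_ox[best],
                     delta_th = theo[best] - obs,
                     delta_ppm = 1e6 * (theo[best] - obs) / obs)
    }
  ) |> dplyr::bind_rows()
  attr(res, "summary") <- list(
    n = nrow(res),
    median_abs_delta = stats::median(abs(res$delta_th)),
    max_abs_delta = max(abs(res$delta_th))
  )
  attr(res, "skipped") <- skipped
  res
}
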