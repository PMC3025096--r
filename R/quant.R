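# Label-free quantitation: merge per-run identifications into a global peptide
# list, align elution times across runs (linear regression plus segment-wise
# offset correction), reconstruct XICs, integrate areas, and compute
# fold-changes between conditions.

#' Quantitation configuration
#'
#' Defaults are sized to a 120-min gradient on a Q-TOF class instrument:
#' m/z tolerance +/- 0.05 Th, RT half-window 1.0 min, 10-min alignment
#' segments.
#'
#' @param mz_tol m/z matching half-tolerance (Th).
#' @param rt_halfwidth XIC extraction half-window around the expected RT (min).
#' @param segment_width Width of the elution-time domains used for shift
#'   correction (min).
#' @param gradient Gradient span (min), default `c(0, 120)`.
#' @param reference_run Run id used as the alignment reference; default the
#'   first control run.
#' @param control,case Condition labels of the denominator and numerator of
#'   the fold-change.
#' @param tic_normalize Scale each run's intensities to a common total ion
#'   current before integration (off by default).
#' @return List of class `quant_config`.
#' @export
quant_config <- function(mz_tol = 0.05, rt_halfwidth = 1.0, segment_width = 10,
                         gradient = c(0, 120), reference_run = NULL,
                         control = "normal", case = "cataract",
                         tic_normalize = FALSE) {
  stopifnot(mz_tol > 0, rt_halfwidth > 0, segment_width > 0,
            length(gradient) == 2, gradient[1] < gradient[2])
  structure(list(mz_tol = mz_tol, rt_halfwidth = rt_halfwidth,
                 segment_width = segment_width, gradient = gradient,
                 reference_run = reference_run, control = control, case = case,
                 tic_normalize = tic_normalize),
            class = "quant_config")
}

#' Read a feature map from TSV
#'
#' Expected columns: `run_id`, `condition`, `mz`, `rt`, `intensity`. Points
#' are sorted by retention time; negative intensities are rejected.
#'
#' @param path Path to the TSV.
#' @param gradient Gradient span used to sanity-check retention times.
#' @return Tibble sorted by `run_id`, `rt`.
#' @export
read_features <- function(path, gradient = c(0, 120)) {
  feats <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("run_id", "condition", "mz", "rt", "intensity")
  missing <- setdiff(need, names(feats))
  if (length(missing) > 0) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(feats$intensity < 0)) stop("negative intensity", call. = FALSE)
  if (any(feats$rt < gradient[1] | feats$rt > gradient[2])) {
    stop("retention time outside gradient span ", gradient[1], "-",
         gradient[2], " min", call. = FALSE)
  }
  dplyr::arrange(feats, .data$run_id, .data$rt)
}

#' Merge per-run identifications into a global peptide list
#'
#' Entries are keyed by (sequence, modification string, charge); the consensus
#' m/z is the median over observations and the identified elution time is kept
#' per run (median if a run identified the peptide more than once). Keys whose
#' observed m/z spread exceeds `mz_tol` are flagged (`mz_conflict`).
#'
#' @param identifications Tibble with `run_id`, `peptide`, `mods`, `charge`,
#'   `rt`, `mz`.
#' @param mz_tol Flagging tolerance for conflicting m/z (Th).
#' @return Tibble with one row per key: `key`, `peptide`, `mods`, `charge`,
#'   `mz`, `mz_conflict`, `n_runs`, `rts` (list of per-run tibbles).
#' @export
build_global_list <- function(identifications, mz_tol = 0.05) {
  need <- c("run_id", "peptide", "mods", "charge", "rt", "mz")
  missing <- setdiff(need, names(identifications))
  if (length(missing) > 0) {
    stop("identification table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(identifications$mz <= 0)) stop("nonpositive m/z", call. = FALSE)
  identifications |>
    dplyr::mutate(mods = dplyr::coalesce(as.character(.data$mods), ""),
                  key = paste(.data$peptide, .data$mods, .data$charge,
                              sep = "/")) |>
    dplyr::group_by(.data$key, .data$peptide, .data$mods, .data$charge) |>
    dplyr::summarise(
      mz_conflict = diff(range(.data$mz)) > mz_tol,
      mz = stats::median(.data$mz),
      n_runs = dplyr::n_distinct(.data$run_id),
      rts = list(.per_run_median_rt(.data$run_id, .data$rt)),
      .groups = "drop"
    )
}

.per_run_median_rt <- function(run_id, rt) {
  tb <- tibble::tibble(run_id = run_id, rt = rt)
  dplyr::summarise(dplyr::group_by(tb, .data$run_id),
                   rt = stats::median(.data$rt), .groups = "drop")
}

.make_segments <- function(gradient, segment_width) {
  starts <- seq(gradient[1], gradient[2], by = segment_width)
  if (starts[length(starts)] >= gradient[2]) {
    starts <- starts[-length(starts)]
  }
  tibble::tibble(start = starts,
                 end = c(starts[-1], gradient[2]))
}

#' Fit a retention-time alignment model
#'
#' Least-squares linear regression of reference times on source times,
#' followed by an additive correction per elution-time segment: within each
#' segment of `segment_width` minutes over the reference gradient, the offset
#' is the median residual of the anchors falling in that segment (0 where a
#' segment has no anchors).
#'
#' @param source Anchor elution times in the run being aligned (min).
#' @param reference Matching elution times in the reference run (min).
#' @param segment_width Segment width (min).
#' @param gradient Gradient span (min).
#' @return Object of class `rt_alignment` with `slope`, `intercept`,
#'   `segments` (tibble `start`, `end`, `offset`, `n_anchors`) and
#'   post-correction `residuals`.
#' @export
fit_alignment <- function(source, reference, segment_width = 10,
                          gradient = c(0, 120)) {
  if (length(source) != length(reference)) {
    stop("source and reference anchor vectors differ in length", call. = FALSE)
  }
  if (length(source) < 2 || length(unique(source)) < 2) {
    stop("need at least 2 anchors with distinct source times", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, source), reference)
  intercept <- unname(fit$coefficients[1])
  slope <- unname(fit$coefficients[2])
  pred <- intercept + slope * source
  resid <- reference - pred
  segments <- .make_segments(gradient, segment_width)
  idx <- findInterval(pred, segments$start,
                      rightmost.closed = TRUE, all.inside = TRUE)
  agg <- tapply(resid, factor(idx, levels = seq_len(nrow(segments))),
                stats::median)
  cnt <- tapply(resid, factor(idx, levels = seq_len(nrow(segments))), length)
  segments$offset <- ifelse(is.na(agg), 0, as.numeric(agg))
  segments$n_anchors <- ifelse(is.na(cnt), 0L, as.integer(cnt))
  model <- structure(list(slope = slope, intercept = intercept,
                          segments = segments, gradient = gradient),
                     class = "rt_alignment")
  model$residuals <- reference - apply_alignment(model, source)
  model
}

#' Identity alignment model
#'
#' @param gradient Gradient span (min).
#' @param segment_width Segment width (min).
#' @return `rt_alignment` mapping every time to itself.
#' @export
identity_alignment <- function(gradient = c(0, 120), segment_width = 10) {
  segments <- .make_segments(gradient, segment_width)
  segments$offset <- 0
  segments$n_anchors <- 0L
  structure(list(slope = 1, intercept = 0, segments = segments,
                 gradient = gradient, residuals = numeric(0)),
            class = "rt_alignment")
}

#' @export
print.rt_alignment <- function(x, ...) {
  cat(sprintf("<rt alignment> ref = %.4f * src %+.4f; %d segments, %d with offsets\n",
              x$slope, x$intercept, nrow(x$segments),
              sum(x$segments$offset != 0)))
  invisible(x)
}

.segment_offset <- function(model, times) {
  seg <- model$segments
  idx <- findInterval(times, seg$start, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= nrow(seg) &
    times >= model$gradient[1] & times <= model$gradient[2]
  off <- rep(0, length(times))
  off[inside] <- seg$offset[idx[inside]]
  off
}

#' Map source-run times into the reference frame
#'
#' Applies the linear map, then the additive offset of the containing
#' elution-time segment; times mapping outside the gradient get the linear
#' part only.
#'
#' @param model An `rt_alignment` from [fit_alignment()].
#' @param times Times in the source run (min).
#' @return Times in the reference frame (min).
#' @export
apply_alignment <- function(model, times) {
  stopifnot(inherits(model, "rt_alignment"))
  lin <- model$intercept + model$slope * times
  lin + .segment_offset(model, lin)
}

#' Map reference-frame times back into the source run
#'
#' Approximate inverse of [apply_alignment()]: subtracts the offset of the
#' segment containing the reference time, then inverts the linear map.
#'
#' @param model An `rt_alignment`.
#' @param ref_times Times in the reference frame (min).
#' @return Times in the source run (min).
#' @export
invert_alignment <- function(model, ref_times) {
  stopifnot(inherits(model, "rt_alignment"))
  (ref_times - .segment_offset(model, ref_times) - model$intercept) /
    model$slope
}

#' Extract an ion chromatogram
#'
#' All points of one run with `|mz - mz_center| <= mz_tol` and retention time
#' inside `rt_window`, ordered by RT. An empty trace is allowed.
#'
#' @param features Tibble with `mz`, `rt`, `intensity` (one run).
#' @param mz_center Center m/z (Th).
#' @param mz_tol Half-tolerance (Th), > 0.
#' @param rt_window Numeric length-2, `c(start, end)` in minutes; must lie
#'   within the gradient span.
#' @param gradient Gradient span (min).
#' @return Tibble with `rt`, `intensity`.
#' @export
extract_xic <- function(features, mz_center, mz_tol = 0.05, rt_window,
                        gradient = c(0, 120)) {
  if (mz_tol <= 0) stop("mz_tol must be > 0", call. = FALSE)
  if (length(rt_window) != 2 || rt_window[1] >= rt_window[2]) {
    stop("rt_window must be c(start, end) with start < end", call. = FALSE)
  }
  if (rt_window[1] < gradient[1] || rt_window[2] > gradient[2]) {
    stop("rt_window outside gradient span", call. = FALSE)
  }
  trace <- features[abs(features$mz - mz_center) <= mz_tol &
                      features$rt >= rt_window[1] &
                      features$rt <= rt_window[2], c("rt", "intensity")]
  dplyr::arrange(tibble::as_tibble(trace), .data$rt)
}

#' Trapezoidal XIC area
#'
#' @param trace Tibble with `rt` and `intensity` (as from [extract_xic()]).
#' @return Area in intensity x minutes; 0 for an empty or single-point trace.
#' @export
xic_area <- function(trace) {
  if (nrow(trace) < 2) return(0)
  ord <- order(trace$rt)
  pracma::trapz(trace$rt[ord], trace$intensity[ord])
}

#' Label-free quantitation across runs
#'
#' For every entry of the global peptide list and every run: the expected
#' retention time is the run's own identified time when available, otherwise
#' it is cross-assigned by mapping the consensus reference-frame time through
#' that run's alignment model; an XIC is extracted around the expected time
#' and integrated. Condition abundance is the mean area over the condition's
#' runs; the fold-change is case abundance / control abundance (NA, flagged,
#' when a condition has no signal).
#'
#' @param features Tibble with `run_id`, `condition`, `mz`, `rt`, `intensity`
#'   covering all runs.
#' @param global_list Tibble from [build_global_list()].
#' @param config A [quant_config()].
#' @return Tibble with one row per peptide key: expected RTs, per-run areas
#'   (`runs` list-column), condition abundances, `ratio`, and flags
#'   (`cross_assigned`, `n_empty_runs`).
#' @export
quantify <- function(features, global_list, config = quant_config()) {
  stopifnot(inherits(config, "quant_config"))
  runs <- dplyr::distinct(features, .data$run_id, .data$condition)
  for (cond in c(config$control, config$case)) {
    if (!cond %in% runs$condition) {
      stop("no run with condition '", cond, "'", call. = FALSE)
    }
  }
  reference <- config$reference_run %||%
    runs$run_id[runs$condition == config$control][1]
  if (!reference %in% runs$run_id) {
    stop("reference run '", reference, "' not present", call. = FALSE)
  }

  if (config$tic_normalize) {
    tic <- features |>
      dplyr::group_by(.data$run_id) |>
      dplyr::summarise(tic = sum(.data$intensity), .groups = "drop")
    features <- features |>
      dplyr::left_join(tic, by = "run_id") |>
      dplyr::mutate(intensity = .data$intensity * mean(tic$tic) / .data$tic) |>
      dplyr::select(-"tic")
  }

  id_rts <- global_list |>
    dplyr::select("key", "rts") |>
    tidyr::unnest("rts")

  # alignment model per run (source run -> reference frame)
  ref_rts <- id_rts[id_rts$run_id == reference, c("key", "rt")]
  models <- lapply(stats::setNames(runs$run_id, runs$run_id), function(r) {
    if (identical(r, reference)) {
      return(identity_alignment(config$gradient, config$segment_width))
    }
    anchors <- dplyr::inner_join(id_rts[id_rts$run_id == r, ], ref_rts,
                                 by = "key", suffix = c("_src", "_ref"))
    if (nrow(anchors) < 2 || length(unique(anchors$rt_src)) < 2) {
      return(identity_alignment(config$gradient, config$segment_width))
    }
    fit_alignment(anchors$rt_src, anchors$rt_ref,
                  segment_width = config$segment_width,
                  gradient = config$gradient)
  })

  feats_by_run <- split(features, features$run_id)
  g <- config$gradient

  quant_one <- function(key, mz, rts) {
    # consensus reference-frame RT over the runs that identified the peptide
    mapped <- vapply(seq_len(nrow(rts)), function(i) {
      apply_alignment(models[[rts$run_id[i]]], rts$rt[i])
    }, 0)
    ref_rt <- stats::median(mapped)
    per_run <- purrr::pmap(runs, function(run_id, condition) {
      own <- rts$rt[rts$run_id == run_id]
      cross <- length(own) == 0
      expected <- if (cross) invert_alignment(models[[run_id]], ref_rt)
                  else own[1]
      lo <- max(g[1], expected - config$rt_halfwidth)
      hi <- min(g[2], expected + config$rt_halfwidth)
      area <- if (lo >= hi) 0 else {
        xic_area(extract_xic(feats_by_run[[run_id]], mz,
                             mz_tol = config$mz_tol, rt_window = c(lo, hi),
                             gradient = g))
      }
      tibble::tibble(run_id = run_id, condition = condition,
                     expected_rt = expected, cross_assigned = cross,
                     area = area)
    }) |> dplyr::bind_rows()
    control_ab <- mean(per_run$area[per_run$condition == config$control])
    case_ab <- mean(per_run$area[per_run$condition == config$case])
    tibble::tibble(
      key = key, mz = mz, ref_rt = ref_rt, runs = list(per_run),
      control_abundance = control_ab, case_abundance = case_ab,
      ratio = if (control_ab > 0 && case_ab > 0) case_ab / control_ab
              else NA_real_,
      cross_assigned = any(per_run$cross_assigned),
      n_empty_runs = sum(per_run$area == 0)
    )
  }

  res <- purrr::pmap(
    list(global_list$key, global_list$mz, global_list$rts), quant_one
  ) |> dplyr::bind_rows()
  dplyr::left_join(
    dplyr::select(global_list, "key", "peptide", "mods", "charge"),
    res, by = "key"
  )
}
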