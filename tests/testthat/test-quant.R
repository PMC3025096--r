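# Label-free quantitation: global list, alignment, XIC, ratios.

make_ids <- function(...) {
  tibble::tibble(...)
}

test_that("global list merges identifications by (sequence, mods, charge)", {
  ids <- make_ids(
    run_id = c("n1", "c1", "n1", "n1"),
    peptide = c("GSKAAR", "GSKAAR", "GSKAAR", "AYLLTK"),
    mods = c("phospho@2", "phospho@2", "phospho@2", "phospho@2"),
    charge = c(2L, 2L, 3L, 2L),
    rt = c(30, 31, 30.2, 50),
    mz = c(400.1, 400.1, 267.1, 420.5))
  gl <- build_global_list(ids)
  expect_equal(nrow(gl), 3) # two charge states are distinct entries
  two_run <- gl[gl$charge == 2 & gl$peptide == "GSKAAR", ]
  expect_equal(two_run$n_runs, 1 + 1)
  expect_equal(nrow(two_run$rts[[1]]), 2)

  withr::local_seed(108)
  rand <- make_ids(run_id = "n1",
                   peptide = replicate(100, random_peptide(6, 15)),
                   mods = paste0("phospho@", 1:100 %% 5 + 1),
                   charge = 2L, rt = runif(100, 5, 115),
                   mz = runif(100, 400, 1600))
  expect_equal(nrow(build_global_list(rand)), 100)

  conflict <- make_ids(run_id = c("n1", "c1"), peptide = "GSKAAR",
                       mods = "phospho@2", charge = 2L,
                       rt = c(30, 31), mz = c(400.1, 400.4))
  expect_true(build_global_list(conflict)$mz_conflict)
  expect_error(build_global_list(dplyr::mutate(conflict, mz = -1)),
               "nonpositive")
})

test_that("alignment recovers a noiseless line and a segment bump", {
  src <- seq(5, 110, length.out = 50)
  m <- fit_alignment(src, 1.05 * src + 2.0)
  expect_equal(m$slope, 1.05, tolerance = 1e-9)
  expect_equal(m$intercept, 2.0, tolerance = 1e-9)
  expect_true(all(abs(m$segments$offset) < 1e-9))
  expect_equal(apply_alignment(m, 50), 1.05 * 50 + 2, tolerance = 1e-9)

  ref <- 1.05 * src + 2.0
  bumped <- ref + ifelse(ref >= 40 & ref < 60, 0.5, 0)
  mb <- fit_alignment(src, bumped)
  hit <- mb$segments$start %in% c(40, 50)
  expect_true(all(mb$segments$offset[hit] > 0.3))
  expect_lt(median(abs(mb$residuals)), 0.1)
  src45 <- (45 - mb$intercept) / mb$slope # maps into the [40, 50) segment
  expect_equal(apply_alignment(mb, src45) - 45,
               unname(mb$segments$offset[mb$segments$start == 40]),
               tolerance = 1e-9)

  # two anchors give the exact interpolating line
  m2 <- fit_alignment(c(10, 100), c(12, 104))
  expect_equal(apply_alignment(m2, c(10, 100)), c(12, 104), tolerance = 1e-9)
  expect_error(fit_alignment(10, 12), "at least 2")
  expect_error(fit_alignment(c(10, 10), c(11, 12)), "distinct")
})

test_that("applying then inverting the alignment recovers input times", {
  withr::local_seed(109)
  src <- runif(60, 5, 115)
  m <- fit_alignment(src, 1.02 * src - 1 + rnorm(60, 0, 0.05))
  t <- runif(20, 10, 110)
  # linear part inverts exactly; segment offsets invert where the offset
  # lookup lands in the same segment
  ident <- identity_alignment()
  expect_equal(invert_alignment(ident, apply_alignment(ident, t)), t,
               tolerance = 1e-12)
  lin <- m$intercept + m$slope * t
  expect_equal((lin - m$intercept) / m$slope, t, tolerance = 1e-9)

  # times outside the gradient get the linear map only
  expect_equal(apply_alignment(m, 130), m$intercept + m$slope * 130,
               tolerance = 1e-9)
})

test_that("alignment recovers simulated distortions to < 0.1 min median residual", {
  withr::local_seed(110)
  for (i in 1:10) {
    n <- 60
    src <- sort(runif(n, 2, 118))
    slope <- runif(1, 0.95, 1.05)
    intercept <- runif(1, -2, 2)
    ref <- slope * src + intercept
    for (b in seq_len(sample(0:3, 1))) {
      s <- runif(1, 0, 100)
      hit <- ref >= s & ref < s + runif(1, 10, 25)
      ref[hit] <- ref[hit] + runif(1, -0.6, 0.6)
    }
    ref <- ref + rnorm(n, 0, 0.05) # anchor jitter
    m <- fit_alignment(src, ref)
    expect_lt(median(abs(m$residuals)), 0.1)
  }
})

test_that("XIC extraction selects the right points and rejects bad windows", {
  feats <- tibble::tibble(mz = c(500.0, 500.2, 500.0),
                          rt = c(50, 50, 80), intensity = c(10, 20, 30))
  tr <- extract_xic(feats, 500.0, mz_tol = 0.05, rt_window = c(45, 55))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$intensity, 10)

  peak <- gaussian_trace()
  feats2 <- tibble::tibble(mz = 500.0, rt = peak$rt, intensity = peak$intensity)
  tr2 <- extract_xic(feats2[sample(nrow(feats2)), ], 500.0,
                     rt_window = c(49, 51))
  expect_equal(nrow(tr2), nrow(peak))
  expect_equal(tr2$rt, sort(peak$rt))

  expect_error(extract_xic(feats, 500, rt_window = c(55, 45)), "start < end")
  expect_error(extract_xic(feats, 500, rt_window = c(110, 130)),
               "outside gradient")
})

test_that("trapezoidal area matches closed forms", {
  rect <- tibble::tibble(rt = c(10, 12), intensity = c(7, 7))
  expect_equal(xic_area(rect), 14)
  expect_equal(xic_area(rect[0, ]), 0)
  expect_equal(xic_area(rect[1, ]), 0)

  peak <- gaussian_trace(amplitude = 1000, sigma = 0.1)
  analytic <- 1000 * 0.1 * sqrt(2 * pi)
  expect_lt(abs(xic_area(peak) - analytic) / analytic, 0.01)
})

test_that("quantitation of noiseless constructed runs gives exact ratios", {
  peak <- gaussian_trace(amplitude = 1000, sigma = 0.1, center = 50)
  one_run <- function(run_id, condition, scale) {
    tibble::tibble(run_id = run_id, condition = condition, mz = 500.0,
                   rt = peak$rt, intensity = peak$intensity * scale)
  }
  feats <- dplyr::bind_rows(one_run("n1", "normal", 1),
                            one_run("c1", "cataract", 1))
  ids <- make_ids(run_id = c("n1", "c1", "n1", "c1"),
                  peptide = "GSKAAR", mods = "phospho@2", charge = 2L,
                  rt = 50, mz = 500.0)
  # anchors need a second peptide for a 2-anchor fit; keep it identical runs
  feats2 <- dplyr::bind_rows(
    feats,
    dplyr::mutate(feats, mz = 600.0, rt = rt + 20))
  ids2 <- dplyr::bind_rows(
    ids, dplyr::mutate(ids, peptide = "AYLLTK", mz = 600.0, rt = 70))
  q <- quantify(feats2, build_global_list(ids2), quant_config())
  expect_equal(q$ratio, c(1, 1), tolerance = 1e-9)

  halved <- dplyr::bind_rows(
    one_run("n1", "normal", 1), one_run("c1", "cataract", 0.5),
    dplyr::mutate(dplyr::bind_rows(one_run("n1", "normal", 1),
                                   one_run("c1", "cataract", 1)),
                  mz = 600.0, rt = rt + 20))
  qh <- quantify(halved, build_global_list(ids2), quant_config())
  expect_equal(qh$ratio[qh$mz == 500], 0.5, tolerance = 1e-9)
  expect_equal(qh$ratio[qh$mz == 600], 1.0, tolerance = 1e-9)
})

test_that("quantitation is invariant to point order and run order", {
  cfg <- sim_config(seed = 21, n_peptides = 15, noise_cv = 0.05,
                    n_runs_per_condition = 2)
  sim <- simulate_experiment(cfg)
  gl <- build_global_list(sim$identifications)
  qc <- quant_config(reference_run = "normal_1")
  base <- quantify(sim$features, gl, qc)

  withr::local_seed(111)
  shuffled <- sim$features[sample(nrow(sim$features)), ]
  expect_equal(quantify(shuffled, gl, qc)$ratio, base$ratio, tolerance = 1e-12)

  reordered <- dplyr::arrange(sim$features, dplyr::desc(run_id))
  expect_equal(quantify(reordered, gl, qc)$ratio, base$ratio,
               tolerance = 1e-12)
})

test_that("cross-assignment reproduces the masked identification's quantity", {
  cfg <- sim_config(seed = 33, n_peptides = 12, noise_cv = 0,
                    ratio_log2_range = c(-1, 1), dropout_prob = 0,
                    rt_jitter = 0)
  sim <- simulate_experiment(cfg)
  gl_full <- build_global_list(sim$identifications)
  q_full <- quantify(sim$features, gl_full, quant_config())

  masked_key <- gl_full$key[1]
  ids_masked <- dplyr::anti_join(
    sim$identifications,
    tibble::tibble(peptide = gl_full$peptide[1], mods = gl_full$mods[1],
                   charge = gl_full$charge[1],
                   run_id = grep("cataract", sim$identifications$run_id,
                                 value = TRUE)[1]),
    by = c("run_id", "peptide", "mods", "charge"))
  expect_lt(nrow(ids_masked), nrow(sim$identifications))
  q_masked <- quantify(sim$features, build_global_list(ids_masked),
                       quant_config())
  r_full <- q_full$ratio[q_full$key == masked_key]
  r_masked <- q_masked$ratio[q_masked$key == masked_key]
  expect_true(q_masked$cross_assigned[q_masked$key == masked_key])
  expect_equal(r_masked, r_full, tolerance = 0.02)
})

test_that("ratios recover the simulated ground truth", {
  cfg <- sim_config(seed = 42, n_peptides = 50, noise_cv = 0.1)
  sim <- simulate_experiment(cfg)
  q <- quantify(sim$features, build_global_list(sim$identifications),
                quant_config())
  comp <- dplyr::inner_join(q, sim$ledger$peptides[, c("key", "true_ratio")],
                            by = "key")
  comp <- comp[!is.na(comp$ratio), ]
  expect_gte(nrow(comp), 40)
  err <- abs(log2(comp$ratio / comp$true_ratio))
  expect_gte(mean(err < 0.25), 0.9)
  expect_lt(abs(mean(log2(comp$ratio / comp$true_ratio))), 0.05)
})

test_that("log-ratio bias stays near zero over a ratio/noise grid", {
  seeds <- 1:4
  grid <- expand.grid(cv = c(0.05, 0.2), span = c(log2(0.1), log2(10)))
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_config(seed = seeds[i], n_peptides = 25,
                      noise_cv = grid$cv[i],
                      ratio_log2_range = sort(c(0, grid$span[i])))
    sim <- simulate_experiment(cfg)
    q <- quantify(sim$features, build_global_list(sim$identifications),
                  quant_config())
    comp <- dplyr::inner_join(q, sim$ledger$peptides[, c("key", "true_ratio")],
                              by = "key")
    comp <- comp[!is.na(comp$ratio), ]
    bias <- mean(log2(comp$ratio / comp$true_ratio))
    expect_lt(abs(bias), 0.1)
  }
})

test_that("quantify flags entries with no signal in a condition", {
  peak <- gaussian_trace(center = 30)
  feats <- dplyr::bind_rows(
    tibble::tibble(run_id = "n1", condition = "normal", mz = 500.0,
                   rt = peak$rt, intensity = peak$intensity),
    tibble::tibble(run_id = "c1", condition = "cataract", mz = 700.0,
                   rt = peak$rt + 40, intensity = peak$intensity))
  ids <- make_ids(run_id = c("n1", "c1"),
                  peptide = c("GSKAAR", "AYLLTK"),
                  mods = "phospho@2", charge = 2L,
                  rt = c(30, 70), mz = c(500.0, 700.0))
  q <- quantify(feats, build_global_list(ids), quant_config())
  expect_true(all(is.na(q$ratio)))
  expect_true(all(q$n_empty_runs == 1))
})
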