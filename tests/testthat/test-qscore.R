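# One shared set of fitted objects keeps the suite fast: the ensembles are
# deterministic given the cohort, so reuse across tests is safe.
train_cohort <- small_healthy(n = 1000, seed = 7)
global_ens <- fit_qscore_ensemble(train_cohort, scope = "global")

test_that("nu grid validates and defaults to 1%..30% in 1% steps", {
  g <- nu_grid()
  expect_equal(g$values, seq(0.01, 0.30, by = 0.01))
  expect_length(g$values, 30)
  expect_error(nu_grid(c(0.1, 0.1)), "strictly increasing")
  expect_error(nu_grid(c(0, 0.5)), "strictly increasing")
})

test_that("each grid machine obeys the soft nu-property on its training set", {
  fracs <- vapply(global_ens$machines, function(m) m$train_flag_frac, 0)
  nus <- global_ens$grid$values
  expect_true(all(fracs <= nus + 0.02))
  expect_true(all(fracs[nus >= 0.05] > 0))
  # and the stored fractions agree with recomputed decision values
  raw <- aortanorm:::build_feature_frame(train_cohort, global_ens$features,
                                         global_ens$age_policy)
  xn <- apply_normalization(global_ens$normalization, raw)
  f01 <- aortanorm:::ocsvm_decision(global_ens$machines[["nu_01"]], xn)
  expect_equal(mean(f01 < 0), global_ens$machines[["nu_01"]]$train_flag_frac)
})

test_that("duplicating the cohort leaves the decision regions unchanged", {
  # the empirical distribution is unchanged by duplication, so in exact
  # arithmetic every decision function is identical; assert equality up to
  # the quadratic-program solver tolerance and identical flags away from
  # the decision boundary
  h <- small_healthy(n = 150, seed = 29)
  doubled <- as.data.frame(h)[rep(seq_len(nrow(h)), 2), ]
  doubled$subject_id <- paste0(doubled$subject_id, "_", rep(1:2, each = nrow(h)))
  grid3 <- nu_grid(c(0.05, 0.10, 0.20))
  e1 <- fit_qscore_ensemble(h, scope = "global", grid = grid3)
  e2 <- fit_qscore_ensemble(as_aorta_cohort(doubled), scope = "global",
                            grid = grid3)
  dv1 <- aortanorm:::ensemble_decision_matrix(e1, h)
  dv2 <- aortanorm:::ensemble_decision_matrix(e2, h)
  # libsvm's one-class dual scales with the training count, so doubling the
  # data exactly doubles every decision value; the sign regions are what
  # duplication must leave unchanged
  scale <- stats::sd(dv2)
  expect_lt(max(abs(dv2 - 2 * dv1)), 0.02 * scale)
  clear <- abs(dv2) > 0.05 * scale
  expect_identical((dv1 < 0)[clear], (dv2 < 0)[clear])
})

test_that("a sparse well-separated minority cluster is flagged at nu above its mass", {
  # 95% of subjects form a dense majority; 5% form a diffuse, well-separated
  # cluster (elderly with grossly enlarged annulus) of much lower density
  set.seed(41)
  n <- 400
  minor <- seq_len(n) <= 20
  age <- c(runif(20, 60, 89), rnorm(380, 35, 8))
  female <- rep(c(1, 0), n / 2)
  height <- ifelse(female == 1, 162, 175) + rnorm(n, 0, 6)
  weight <- 22 * (height / 100)^2 + rnorm(n, 0, 4)
  aan <- c(rnorm(20, 42, 6), rnorm(380, 20, 2))
  df <- data.frame(subject_id = seq_len(n), age = pmin(pmax(age, 5), 89),
                   sex = ifelse(female == 1, "F", "M"),
                   height_cm = height, weight_kg = weight,
                   aan_mm = pmax(aan, 8), sov_mm = 28 + rnorm(n, 0, 2),
                   sj_mm = 24 + rnorm(n, 0, 2),
                   paa_mm = 26 + rnorm(n, 0, 2), group = "healthy")
  ens <- fit_qscore_ensemble(as_aorta_cohort(df), scope = "local",
                             level = "AAn", grid = nu_grid(0.10))
  dv <- aortanorm:::ensemble_decision_matrix(ens, df)
  flagged <- dv[, 1] < 0
  expect_gte(mean(flagged[minor]), 0.75)     # most of the minor cluster
  expect_lte(mean(flagged[!minor]), 0.08)    # few of the dense majority
  expect_gt(mean(flagged[minor]), mean(flagged[!minor]) + 0.5)
})

test_that("q_score is the smallest flagged grid percentile with above-grid sentinel", {
  center <- ensemble_center_record(global_ens, train_cohort)
  expect_true(is.infinite(q_score(global_ens, center)))
  # every decision function is positive at the centroid
  dv <- aortanorm:::ensemble_decision_matrix(global_ens, center)
  expect_true(all(dv > 0))
  # a record far outside the training range is flagged already at nu = 1%
  extreme <- subject_record(age = 89, sex = "M", height_cm = 200,
                            weight_kg = 150, aan_mm = 60, sov_mm = 80,
                            sj_mm = 70, paa_mm = 80)
  expect_equal(q_score(global_ens, extreme), 1)
  dv1 <- aortanorm:::ensemble_decision_matrix(global_ens, extreme)
  expect_lt(dv1[1, 1], 0)
  # missing features error
  expect_error(q_score(global_ens, subject_record(40, "F", 165, 60,
                                                  sov_mm = 28)),
               "missing")
})

test_that("held-out calibration: P(q <= nu) tracks nu within 3 points", {
  held_out <- generate_healthy(synthetic_config(n = 2000, seed = 8))
  q <- q_score(global_ens, held_out)
  for (nu in c(5, 10, 20, 30)) {
    expect_lt(abs(mean(q <= nu) - nu / 100), 0.03)
  }
})

test_that("threshold sets nest and q is deterministic across refits", {
  probe <- generate_healthy(synthetic_config(n = 200, seed = 43))
  q <- q_score(global_ens, probe)
  for (t_pair in list(c(2, 4), c(5, 10), c(10, 30))) {
    expect_true(all(which(q <= t_pair[1]) %in% which(q <= t_pair[2])))
  }
  refit <- fit_qscore_ensemble(train_cohort, scope = "global")
  expect_identical(q_score(refit, probe), q)
})

test_that("inflating all diameters along a ray drives q to the grid floor", {
  base <- ensemble_center_record(global_ens, train_cohort)
  sds <- vapply(AORTIC_LEVELS, function(lv)
    sd(as.data.frame(train_cohort)[[aortanorm:::diameter_col(lv)]]), 0)
  qs <- vapply(seq(0, 10, by = 0.5), function(k) {
    rec <- base
    for (lv in AORTIC_LEVELS) {
      col <- aortanorm:::diameter_col(lv)
      rec[[col]] <- rec[[col]] + k * sds[[lv]]
    }
    q_score(global_ens, rec)
  }, numeric(1))
  expect_equal(min(qs), 1)          # reaches the smallest grid percentile
  expect_lte(which(qs == 1)[1], 21) # within 10 training sds
})

test_that("local ensembles score per level and q_report applies the 2/4 thresholds", {
  locals <- lapply(AORTIC_LEVELS, function(lv)
    fit_qscore_ensemble(train_cohort, scope = "local", level = lv))
  names(locals) <- AORTIC_LEVELS
  center <- ensemble_center_record(global_ens, train_cohort)
  rep <- q_report(locals, global_ens, center)
  expect_true(all(rep$levels$category == "normal"))
  expect_equal(rep$global_category, "normal")
  # boundary conventions: 1% abnormal, 2% and 4% borderline, 5% normal
  expect_equal(q_category(c(1, 2, 4, 5, Inf)),
               c("abnormal", "borderline", "borderline", "normal", "normal"))
  # missing diameter: local NA, global unavailable
  partial <- center
  partial$aan_mm <- NA
  rep2 <- q_report(locals, global_ens, partial)
  expect_true(is.na(rep2$levels$q[rep2$levels$level == "AAn"]))
  expect_true(is.na(rep2$global_q))
  # mismatched age policies are refused
  locals_corr <- locals
  locals_corr$AAn <- fit_qscore_ensemble(train_cohort, scope = "local",
                                         level = "AAn",
                                         policy = age_policy(TRUE))
  expect_error(q_report(locals_corr, global_ens, center), "age policies")
})

test_that("age correction changes fit-time features and applies at scoring", {
  ens_corr <- fit_qscore_ensemble(train_cohort, scope = "global",
                                  policy = age_policy(TRUE))
  # the stored age range is on the corrected scale (bounded by the plateau)
  expect_lte(ens_corr$normalization$max[["age"]], 75)
  # an 89-year-old subject near the cohort's typical anthropometrics:
  # under correction their age maps inside the training range
  elderly <- subject_record(age = 89, sex = "F", height_cm = 162,
                            weight_kg = 58, aan_mm = 19, sov_mm = 28,
                            sj_mm = 24, paa_mm = 26)
  q_corr <- q_score(ens_corr, elderly)
  q_raw <- q_score(global_ens, elderly)
  expect_gte(q_corr, q_raw)  # correction should not make elders look worse
})

test_that("ensemble JSON serialization reproduces decision values exactly", {
  probe <- generate_healthy(synthetic_config(n = 50, seed = 47))
  path <- withr::local_tempfile(fileext = ".json")
  write_qscore_ensemble(global_ens, path)
  restored <- read_qscore_ensemble(path)
  expect_equal(aortanorm:::ensemble_decision_matrix(restored, probe),
               aortanorm:::ensemble_decision_matrix(global_ens, probe),
               tolerance = 1e-12)
  expect_identical(q_score(restored, probe), q_score(global_ens, probe))
})

test_that("two-diameter heatmap: centroid above-grid, nested level sets, contours", {
  hm <- q_heatmap(train_cohort, features = c("paa_mm", "sov_mm"),
                  resolution = 30)
  lat <- hm$lattice
  df <- as.data.frame(train_cohort)
  # the population mixes children and adults, so the joint mode (not the
  # marginal medians, which fall between the two clusters) is the point
  # that must lie inside every fitted support
  raw <- df[, c("paa_mm", "sov_mm")]
  xn <- apply_normalization(hm$ensemble$normalization, raw)
  kde <- rowMeans(exp(-hm$ensemble$gamma *
                        as.matrix(dist(xn))^2))
  mode_pt <- raw[which.max(kde), ]
  dense <- lat[which.min((lat$x - mode_pt$paa_mm)^2 +
                         (lat$y - mode_pt$sov_mm)^2), ]
  expect_true(is.infinite(dense$q))
  # {q < 2} is contained in {q <= 4} on the lattice
  expect_true(all(lat$q[lat$q < 2] <= 4))
  expect_true(all(which(lat$q < 2) %in% which(lat$q <= 4)))
  # both requested level sets produced contour polylines
  expect_true(all(c(2, 4) %in% vapply(hm$contours, `[[`, 0, "level")))
  expect_equal(hm$guideline_mm, 40)
  expect_error(q_heatmap(train_cohort, resolution = 1), "resolution")
})

test_that("too-small or degenerate training sets are refused", {
  tiny <- as.data.frame(small_healthy(n = 40, seed = 51))
  expect_error(fit_qscore_ensemble(as_aorta_cohort(tiny), scope = "global"),
               ">= 50")
})
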