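# Hit characterization: validation t-tests, dose trend, delay-vs-arrest,
# washout, morphology.

test_that("paired t-test matches the closed-form oracle", {
  # the worked example
  tt <- paired_ttest(c(50, 55, 60, 52), c(65, 70, 72, 66))
  or <- oracle_paired_t(c(50, 55, 60, 52), c(65, 70, 72, 66))
  expect_equal(tt$t, or$t, tolerance = 1e-12)
  expect_equal(tt$p, or$p, tolerance = 1e-12)

  # randomized inputs at 1e-10 relative tolerance
  set.seed(8)
  for (i in 1:25) {
    n <- sample(2:10, 1)
    a <- rnorm(n, 55, 10); b <- rnorm(n, 60, 10)
    tt <- paired_ttest(a, b)
    or <- oracle_paired_t(a, b)
    expect_equal(tt$t, or$t, tolerance = 1e-10)
    expect_equal(tt$p, or$p, tolerance = 1e-10)
    # cross-check against stats::t.test as an independent implementation
    st <- t.test(a, b, paired = TRUE)
    expect_equal(tt$p, st$p.value, tolerance = 1e-10)
  }

  expect_error(paired_ttest(1:3, 1:4), "equal length")
  expect_error(paired_ttest(1, 1), "at least 2")
})

test_that("degenerate zero-variance differences are flagged, not errors", {
  ident <- paired_ttest(c(60, 62, 64), c(60, 62, 64))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_equal(ident$stars, "ns")
  expect_true(ident$degenerate)

  shift <- paired_ttest(c(50, 52, 54), c(60, 62, 64))
  expect_equal(shift$p, 0)
  expect_true(shift$degenerate)
  expect_equal(shift$stars, "****")
})

test_that("significance stars follow the standard mapping", {
  expect_equal(p_stars(c(0.2, 0.049, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
  # boundaries are strict
  expect_equal(p_stars(c(0.05, 0.01, 0.001, 0.0001)),
               c("ns", "*", "**", "***"))
  expect_error(p_stars(1.2), "\\[0, 1\\]")
})

test_that("validation table is summarised per compound with stars", {
  val <- data.frame(
    compound_id = rep(c("Bortezomib", "Inert"), each = 8),
    experiment_id = rep(1:4, 4),
    arm = rep(rep(c("treated", "control"), each = 4), 2),
    enucleation_pct = c(31, 28, 35, 30, 64, 61, 66, 63,    # strong inhibitor
                        63, 60, 67, 62, 64, 61, 66, 63))   # inert
  out <- validate_compounds(val)
  expect_equal(nrow(out), 2)
  strong <- out[out$compound_id == "Bortezomib", ]
  expect_lt(strong$p, 0.01)
  expect_true(strong$stars %in% c("**", "***", "****"))
  expect_equal(out$stars[out$compound_id == "Inert"], "ns")
  outBH <- validate_compounds(val, adjust = "BH")
  expect_true(all(outBH$p_adj >= outBH$p))
  expect_error(validate_compounds(val[, -3]), "missing column")
})

test_that("dose trend detects monotone inhibition", {
  conc <- c(0.01, 0.1, 1, 10, 100)
  dt <- dose_trend(conc, c(65, 60, 40, 20, 10))
  expect_equal(dt$rho, -1)
  expect_true(dt$concentration_dependent)

  flat <- dose_trend(conc, rep(50, 5))
  expect_equal(flat$rho, 0)
  expect_false(flat$concentration_dependent)

  expect_error(dose_trend(c(1, 2), c(3, 4)), "at least 3")

  # Hill-curve responses called concentration dependent in >= 95% of sims
  hill <- function(c, ec50, imax) 65 * (1 - imax * c / (c + ec50))
  ok <- 0; n_sim <- 500
  set.seed(19)
  for (i in 1:n_sim) {
    resp <- hill(conc, ec50 = 1, imax = 0.8) + rnorm(5, 0, 2)
    ok <- ok + dose_trend(conc, resp)$concentration_dependent
  }
  expect_gte(ok / n_sim, 0.95)
})

test_that("mechanism classification separates delay from arrest", {
  kin <- kinetics_truth()
  run <- function(mech) {
    prof <- compound_profile("X", mech, max_inhibition = 0.8, ec50 = 0.05)
    ts <- simulate_kinetics(prof, c(5, 10), kin, seed = derive_seed(2, mech),
                            n_experiments = 3)
    g <- function(arm, t) ts$enucleation_pct[ts$arm == arm & ts$time_h == t]
    classify_mechanism(g("treated", 5), g("control", 5),
                       g("treated", 10), g("control", 10))
  }
  expect_equal(run("delay")$call, "delay")
  expect_equal(run("arrest")$call, "arrest")

  # treated identical to control at both timepoints
  mc <- classify_mechanism(c(60, 62, 64), c(60, 62, 64),
                           c(68, 70, 72), c(68, 70, 72))
  expect_equal(mc$call, "no_effect")
  expect_output(print(run("arrest")), "arrest")
})

test_that("washout recovery verdicts follow the margin rule", {
  tp <- c(0.5, 1, 3, 5)
  ctl <- c(20, 30, 50, 65)

  same <- washout_recovery(tp, ctl, ctl)
  expect_true(same$recovered)
  expect_equal(same$first_recovery_time, 0.5)

  stuck <- washout_recovery(tp, rep(5, 4), ctl)
  expect_false(stuck$recovered)
  expect_true(is.na(stuck$first_recovery_time))

  part <- washout_recovery(tp, c(5, 12, 45, 62), ctl)
  expect_true(part$recovered)
  expect_equal(part$first_recovery_time, 3)

  expect_error(washout_recovery(numeric(0), 1, 1), "no timepoints")
  expect_error(washout_recovery(1, 5, 6), "at least 2")
})

test_that("washout-reversible arrest compounds are called recovered", {
  prof <- compound_profile("X", "arrest", max_inhibition = 0.8, ec50 = 0.05)
  ts <- simulate_kinetics(prof, c(5.5, 6, 8, 10), washout_at = 5,
                          seed = 31, n_experiments = 3)
  agg <- aggregate(enucleation_pct ~ time_h + arm, ts, mean)
  tt <- agg[agg$arm == "treated", ]
  cc <- agg[agg$arm == "control", ]
  wr <- washout_recovery(tt$time_h - 5, tt$enucleation_pct,
                         cc$enucleation_pct)
  expect_true(wr$recovered)
})

test_that("morphology proportions summarise per experiment then across", {
  one <- data.frame(experiment_id = 1, class = c("A", "B"), count = c(50, 50))
  mp <- morphology_proportions(one)
  expect_equal(mp$summary$mean_proportion, c(0.5, 0.5))
  expect_true(all(is.na(mp$summary$sd_proportion)))

  three <- data.frame(experiment_id = rep(1:3, each = 2),
                      class = rep(c("A", "B"), 3),
                      count = rep(c(30, 70), 3))
  mp <- morphology_proportions(three)
  expect_equal(mp$summary$mean_proportion, c(0.3, 0.7))
  expect_equal(mp$summary$sd_proportion, c(0, 0))
  # per-experiment proportions sum to 1
  expect_equal(unname(rowSums(mp$per_experiment)), rep(1, 3))

  # multinomial recovery of a 30% segmentation phenotype
  probs <- c(round_nucleus = 0.4, segmented_nucleus = 0.3, extruding = 0.3)
  mc <- simulate_morphology_counts(probs, n_cells = c(300, 600),
                                   n_experiments = 4, seed = 2)
  mp <- morphology_proportions(mc)
  seg <- mp$summary$mean_proportion[mp$summary$class == "segmented_nucleus"]
  expect_lt(abs(seg - 0.3), 4 * sqrt(0.3 * 0.7 / 300) / sqrt(4))

  expect_error(morphology_proportions(data.frame(class = "A", count = 1)),
               "missing column")
})
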