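# Simulator: event-level wells, whole screens, kinetics, cell cycle and
# cytospin counts, all with known ground truth.

test_that("well simulation handles degenerate probabilities and conserves particles", {
  specs <- default_population_specs()

  tr0 <- well_truth("A1", "X", true_enucleation_prob = 0, n_cells = 500)
  ev0 <- simulate_well_events(tr0, specs, seed = 1)
  expect_equal(sum(ev0$truth_label %in% c("reticulocyte", "free_nucleus")), 0)
  expect_equal(nrow(ev0), 500)

  trd <- well_truth("A2", "X", true_enucleation_prob = 0.5,
                    dead_fraction = 1, n_cells = 300)
  evd <- simulate_well_events(trd, specs, seed = 2)
  expect_true(all(evd$truth_label == "dead_cell"))

  # conservation: one reticulocyte and one free nucleus per enucleation,
  # and all seeded cells accounted for
  tr <- well_truth("A3", "X", 0.4, dead_fraction = 0.1, n_cells = 2000)
  ev <- simulate_well_events(tr, specs, seed = 3)
  tab <- table(ev$truth_label)
  expect_equal(unname(tab["reticulocyte"]), unname(tab["free_nucleus"]))
  n_cells_accounted <- sum(tab[c("orthochromatic_erythroblast", "dead_cell",
                                 "reticulocyte")])
  expect_equal(unname(n_cells_accounted), 2000)
  expect_equal(nrow(ev), 2000 + unname(tab["reticulocyte"]))
})

test_that("well simulation is deterministic and matches the binomial oracle", {
  tr <- well_truth("B1", "X", 0.5, n_cells = 30000)
  ev1 <- simulate_well_events(tr, seed = 99)
  ev2 <- simulate_well_events(tr, seed = 99)
  expect_identical(ev1, ev2)

  # fraction of enucleation-origin events within 4 binomial SEs of 0.5
  n_enuc <- sum(ev1$truth_label == "reticulocyte")
  frac <- n_enuc / 30000
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / 30000))
})

test_that("well simulation validates inputs", {
  expect_error(well_truth("A1", "X", 1.2), "\\[0, 1\\]")
  expect_error(well_truth("A1", "X", 0.5, dead_fraction = -0.1), "\\[0, 1\\]")
  tr <- well_truth("A1", "X", 0.5)
  expect_error(simulate_well_events(tr, specs = list()), "missing")
})

test_that("expected measured enucleation is non-decreasing in the true probability", {
  probs <- seq(0, 1, by = 0.2)
  est <- vapply(probs, function(p) {
    tr <- well_truth("W", "X", p, n_cells = 8000)
    ev <- simulate_well_events(tr, seed = 7)
    cls <- classify_enucleation(gate_live(ev)$live)
    cls$n_enucleated / max(1, cls$n_enucleated + cls$n_nucleated)
  }, numeric(1))
  expect_true(all(diff(est) >= -0.02))  # monotone up to sampling noise
  expect_true(all(diff(est[c(1, 3, 5)]) > 0))
})

test_that("screen simulation reproduces the designed control and compound structure", {
  des <- screen_design(n_compounds = 20, n_cells = 5000)
  lib <- default_compound_library(20, n_inhibitors = 0, n_toxic = 0)
  sim <- simulate_screen(des, lib, seed = 5)

  # all-inactive library: nominal compound probabilities all at baseline
  truth_comp <- sim$truth[sim$truth$role == "compound", ]
  expect_true(all(truth_comp$p_nominal == des$baseline_enucleation))

  # positive-control wells essentially blocked
  cytod <- sim$counts[sim$counts$role == "pos_control", ]
  pct <- net_enucleation(cytod$n_enucleated, cytod$n_nucleated)
  expect_lt(mean(pct), 5)

  # every compound appears once per replicate; controls laid out as designed
  for (r in 1:2) {
    cw <- sim$counts[sim$counts$replicate == r & sim$counts$role == "compound", ]
    expect_setequal(cw$compound_id, sprintf("C%03d", 1:20))
    expect_equal(sum(sim$counts$replicate == r &
                       sim$counts$role == "neg_control"), des$n_dmso)
  }

  expect_error(simulate_screen(des, lib[1:5], seed = 1), "match")
})

test_that("replicate agreement rises as between-day noise vanishes", {
  # day-to-day shifts act at the plate level, so they only decorrelate
  # replicates when the library spans several plates
  lib <- default_compound_library(180, n_inhibitors = 12, n_toxic = 0)
  cor_at <- function(day_sd) {
    rs <- vapply(1:4, function(i) {
      des <- screen_design(n_compounds = 180, n_cells = 2000,
                           between_day_sd = day_sd)
      sim <- simulate_screen(des, lib, seed = 100 + i)
      comp <- sim$counts[sim$counts$role == "compound", ]
      pct <- net_enucleation(comp$n_enucleated, comp$n_nucleated)
      r1 <- pct[comp$replicate == 1][order(comp$compound_id[comp$replicate == 1])]
      r2 <- pct[comp$replicate == 2][order(comp$compound_id[comp$replicate == 2])]
      cor(r1, r2)
    }, numeric(1))
    mean(rs)
  }
  expect_gt(cor_at(0), cor_at(12))
})

test_that("kinetics follow the linear-rise-to-plateau curve per mechanism", {
  kin <- kinetics_truth()
  tp <- c(1, 2, 3, 4, 5, 6, 8, 10)

  none <- compound_profile("N", "none")
  ts <- simulate_kinetics(none, tp, kin, seed = 1, noise_sd = 0)
  ctl <- ts[ts$arm == "control" & ts$experiment == 1, ]
  trt <- ts[ts$arm == "treated" & ts$experiment == 1, ]
  expect_equal(trt$enucleation_pct, ctl$enucleation_pct)
  expect_true(all(diff(ctl$enucleation_pct) >= 0))
  expect_equal(max(ctl$enucleation_pct), 100 * kin$plateau)

  delay <- compound_profile("D", "delay", max_inhibition = 0.8, ec50 = 0.05)
  ts <- simulate_kinetics(delay, c(5, 10), kin, seed = 1, noise_sd = 0)
  gap <- function(t) {
    abs(mean(ts$enucleation_pct[ts$arm == "control" & ts$time_h == t]) -
        mean(ts$enucleation_pct[ts$arm == "treated" & ts$time_h == t]))
  }
  expect_lt(gap(10), gap(5))

  arr <- compound_profile("A", "arrest", max_inhibition = 0.8, ec50 = 0.05)
  ts <- simulate_kinetics(arr, c(5, 10), kin, seed = 1, noise_sd = 0)
  t5 <- mean(ts$enucleation_pct[ts$arm == "treated" & ts$time_h == 5])
  t10 <- mean(ts$enucleation_pct[ts$arm == "treated" & ts$time_h == 10])
  expect_equal(t10 - t5, 0)

  expect_error(simulate_kinetics(none, numeric(0)), "timepoints")
  expect_error(simulate_kinetics(none, c(-1, 5)), "non-negative")
})

test_that("cell-cycle simulation matches its fractions", {
  ev <- simulate_cellcycle_events(0, 0, 2000, seed = 1)
  fr <- cellcycle_fractions(ev)
  expect_equal(fr$non_proliferating, 1)
  expect_gt(fr$G0G1, 0.98)  # all 2N BrdU-negative

  ev <- simulate_cellcycle_events(1, 0, 2000, seed = 2)
  expect_true(all(ev$truth_label == "S"))
  expect_equal(cellcycle_fractions(ev)$S, 1, tolerance = 0.01)

  # binomial oracle at the enrichment scenario scale
  ev <- simulate_cellcycle_events(0.08, 0.02, 50000, seed = 3)
  fr <- cellcycle_fractions(ev)
  se <- sqrt(0.92 * 0.08 / 50000)
  expect_lt(abs(fr$non_proliferating - 0.92), 4 * se + 0.01)

  expect_error(simulate_cellcycle_events(0.7, 0.5, 100), "<= 1")
})

test_that("morphology counts are multinomial with the stated dispersion", {
  p1 <- c(segmented_nucleus = 1)
  mc <- simulate_morphology_counts(p1, n_cells = 200, n_experiments = 2,
                                   seed = 1)
  expect_true(all(mc$count[mc$class == "segmented_nucleus"] == 200))

  pu <- setNames(rep(0.25, 4), c("a", "b", "c", "d"))
  mc <- simulate_morphology_counts(pu, n_cells = 400, n_experiments = 1,
                                   seed = 2)
  expect_true(all(abs(mc$count - 100) < 4 * sqrt(400 * 0.25 * 0.75)))

  # nuclear-segmentation scenario: ~30% of cytospun cells
  probs <- c(round_nucleus = 0.25, polarized_nucleus = 0.2, extruding = 0.1,
             segmented_nucleus = 0.30, reticulocyte = 0.1, free_nucleus = 0.05)
  mc <- simulate_morphology_counts(probs, n_cells = 500, n_experiments = 3,
                                   seed = 3)
  seg <- mc[mc$class == "segmented_nucleus", ]
  tot <- aggregate(count ~ experiment_id, mc, sum)
  prop <- mean(seg$count / tot$count)
  expect_lt(abs(prop - 0.30), 4 * sqrt(0.3 * 0.7 / 500) / sqrt(3))

  expect_error(simulate_morphology_counts(c(a = 0.5, b = 0.4), 100), "sum to 1")
  expect_error(simulate_morphology_counts(c(0.5, 0.5), 100), "named")
})

test_that("seed streams are independent and reproducible", {
  expect_identical(derive_seed(1, "P1", "A1"), derive_seed(1, "P1", "A1"))
  expect_false(derive_seed(1, "P1", "A1") == derive_seed(1, "P1", "A2"))
  expect_false(derive_seed(1, "P1", "A1") == derive_seed(2, "P1", "A1"))
  expect_true(derive_seed(.Machine$integer.max, "x") < 2^31)
})
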