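# Gates, gating hierarchy and the assay's specific gates.

test_that("rectangle gates follow the half-open convention", {
  ev <- toy_events(200)
  g_all <- rect_gate("all", "FSC", c(-Inf, Inf))
  expect_equal(apply_gate(ev, g_all)$count, 200)

  empty <- ev[0, ]
  res <- apply_gate(empty, g_all)
  expect_equal(res$count, 0)
  expect_equal(nrow(res$members), 0)

  # half-open: min included, max excluded
  ev2 <- toy_events(5)
  ev2$FSC <- c(1, 2, 3, 4, 5)
  g <- rect_gate("mid", "FSC", c(2, 4))
  expect_equal(apply_gate(ev2, g)$count, 2)  # 2 and 3; 4 excluded

  expect_error(apply_gate(ev, rect_gate("x", "NOPE", c(0, 1))), "NOPE")
  expect_error(rect_gate("bad", "FSC", c(2, 2)), "min < max")
})

test_that("polygon membership matches a per-event brute-force oracle", {
  set.seed(11)
  ev <- toy_events(1000, seed = 11)
  # a non-convex pentagon
  verts <- rbind(c(1, 1), c(6, 1.5), c(4, 4), c(6, 7), c(1.5, 6))
  g <- polygon_gate("poly", "FSC", "SSC", verts)
  keep <- apply_gate(ev, g)$keep
  oracle <- vapply(seq_len(nrow(ev)), function(i)
    oracle_point_in_polygon(ev$FSC[i], ev$SSC[i], verts), logical(1))
  expect_identical(keep, oracle)

  # boundary points count as inside
  evb <- toy_events(3)
  evb$FSC <- c(1, 3.5, 10); evb$SSC <- c(1, 1.25, 10)  # vertex, on-edge, out
  expect_equal(apply_gate(evb, g)$keep, c(TRUE, TRUE, FALSE))

  expect_error(polygon_gate("l", "FSC", "SSC",
                            rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
})

test_that("gate conjunction is order-independent and idempotent", {
  ev <- toy_events(500, seed = 3)
  a <- rect_gate("a", "FSC", c(2, 6))
  b <- rect_gate("b", "SSC", c(1, 5))
  kab <- apply_gate(apply_gate(ev, a)$members, b)$members
  kba <- apply_gate(apply_gate(ev, b)$members, a)$members
  conj <- ev[apply_gate(ev, a)$keep & apply_gate(ev, b)$keep, ]
  expect_equal(kab[order(kab$event_id), ], conj, ignore_attr = TRUE)
  expect_equal(kba[order(kba$event_id), ], conj, ignore_attr = TRUE)
  # idempotence
  expect_equal(apply_gate(kab, b)$count, nrow(kab))
})

test_that("gating hierarchy conserves counts", {
  ev <- toy_events(400, seed = 9)
  h <- gating_hierarchy(
    list(rect_gate("big", "FSC", c(2, Inf)),
         rect_gate("hi_ssc", "SSC", c(4, Inf)),
         rect_gate("lo_ssc", "SSC", c(-Inf, 4))),
    parents = c("root", "big", "big"))
  pc <- apply_hierarchy(ev, h)
  expect_equal(pc$count[pc$node == "root"], 400)
  # children partition the parent (adjacent half-open gates)
  expect_equal(pc$count[pc$node == "hi_ssc"] + pc$count[pc$node == "lo_ssc"],
               pc$count[pc$node == "big"])
  expect_true(all(pc$fraction_of_parent[-1] >= 0 &
                    pc$fraction_of_parent[-1] <= 1))
  expect_error(gating_hierarchy(list(rect_gate("a", "FSC", c(0, 1))),
                                parents = "nope"), "parent")
})

test_that("live gate recovers the dead fraction", {
  # all dead
  trd <- well_truth("W", "X", 0, dead_fraction = 1, n_cells = 400)
  evd <- simulate_well_events(trd, seed = 1)
  lv <- gate_live(evd)
  expect_equal(lv$n_live, 0)
  expect_equal(lv$dead_fraction, 1)

  # dead fraction 0.2 at n = 30,000 (zero enucleation so particles = cells)
  tr <- well_truth("W", "X", 0, dead_fraction = 0.2, n_cells = 30000)
  ev <- simulate_well_events(tr, seed = 2)
  lv <- gate_live(ev)
  expect_lt(abs(lv$dead_fraction - 0.2), 4 * sqrt(0.2 * 0.8 / 30000) + 0.01)

  # no dead cells: misclassification below the channel-model floor
  tr0 <- well_truth("W", "X", 0.5, dead_fraction = 0, n_cells = 30000)
  ev0 <- simulate_well_events(tr0, seed = 3)
  expect_lt(gate_live(ev0)$dead_fraction, 0.01)

  expect_error(gate_live(data.frame(FSC = 1)), "PI")
})

test_that("enucleation classification matches the ground truth", {
  specs <- default_population_specs()

  # pure reticulocytes: nothing lands in the nucleated class
  retic <- simulate_well_events(well_truth("W", "X", 1, n_cells = 1000),
                                specs, seed = 1)
  retic <- retic[retic$truth_label == "reticulocyte", ]
  cls <- classify_enucleation(retic)
  expect_lt(cls$n_nucleated / nrow(retic), 0.005)

  # DMSO-like well
  ev <- simulate_well_events(well_truth("W", "DMSO", 0.65, 0.05, 30000),
                             specs, seed = 2)
  cls <- classify_enucleation(gate_live(ev)$live)
  frac <- cls$n_enucleated / (cls$n_enucleated + cls$n_nucleated)
  expect_lt(abs(frac - 0.65), 4 * sqrt(0.65 * 0.35 / 30000) + 0.01)

  # cytochalasin-D-like well: enucleation blocked
  ev <- simulate_well_events(well_truth("W", "CytoD", 0.02, 0.05, 30000),
                             specs, seed = 3)
  cls <- classify_enucleation(gate_live(ev)$live)
  expect_lt(cls$n_enucleated / (cls$n_enucleated + cls$n_nucleated), 0.05)

  expect_error(classify_enucleation(data.frame(Ter119 = 1)), "Hoechst")
})

test_that("free nuclei fall outside both analysis classes by default", {
  nuc <- simulate_well_events(well_truth("W", "X", 1, n_cells = 2000),
                              seed = 4)
  nuc <- nuc[nuc$truth_label == "free_nucleus", ]
  cls <- classify_enucleation(nuc)
  expect_lt((cls$n_enucleated + cls$n_nucleated) / nrow(nuc), 0.01)

  # configurable alternative: Ter119-positive nuclei enter the nucleated class
  specs_pos <- default_population_specs(free_nucleus_ter119_positive = TRUE)
  nuc2 <- simulate_well_events(well_truth("W", "X", 1, n_cells = 2000),
                               specs_pos, seed = 4)
  nuc2 <- nuc2[nuc2$truth_label == "free_nucleus", ]
  cls2 <- classify_enucleation(nuc2)
  expect_gt(cls2$n_nucleated / nrow(nuc2), 0.95)
})

test_that("orthochromatic sort gate is pure and excludes the right events", {
  specs <- default_population_specs()
  # mixed spleen-like input with labels
  mk <- function(pop, n) {
    ev <- erythroscreen:::draw_population_events(specs[[pop]], n)
    cbind(event_id = seq_len(n), ev)
  }
  set.seed(21)
  mixed <- rbind(mk("orthochromatic_erythroblast", 3000),
                 mk("late_erythroblast", 1500),
                 mk("reticulocyte", 2000),
                 mk("free_nucleus", 800),
                 mk("dead_cell", 400))
  srt <- gate_orthochromatic_sort(mixed)
  purity <- mean(srt$sorted$truth_label == "orthochromatic_erythroblast")
  expect_gte(purity, 0.95)
  expect_gt(srt$n_late, 0)
  expect_gt(mean(srt$late$truth_label == "late_erythroblast"), 0.9)

  # reticulocyte-only input: everything is Hoechst-negative, sort is empty
  retic_only <- mk("reticulocyte", 500)
  expect_equal(gate_orthochromatic_sort(retic_only)$n_sorted, 0)

  # dead orthochromatic cells are excluded by PI
  dead <- mk("dead_cell", 500)
  expect_lt(gate_orthochromatic_sort(dead)$n_sorted, 10)

  expect_error(gate_orthochromatic_sort(data.frame(Ter119 = 1)), "missing")
})

test_that("cell-cycle fractions sum to one and split BrdU-negatives by DNA", {
  ev <- simulate_cellcycle_events(0, 0, 1000, seed = 5)
  fr <- cellcycle_fractions(ev)
  expect_equal(fr$non_proliferating, 1)

  ev <- simulate_cellcycle_events(0.11, 0.05, 20000, seed = 6)
  fr <- cellcycle_fractions(ev)
  expect_equal(fr$S + fr$G0G1 + fr$G2M, 1)
  expect_equal(fr$non_proliferating, fr$G0G1 + fr$G2M)
  expect_lt(abs(fr$G2M - 0.05), 4 * sqrt(0.05 * 0.95 / 20000) + 0.01)
  expect_error(cellcycle_fractions(data.frame(BrdU = 1)), "DNA")
})
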