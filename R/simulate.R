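# Event-level and count-level simulation of erythroid enucleation screens.
#
# The generator emulates the statistical structure of a 96-well
# flow-cytometry enucleation assay: sorted orthochromatic erythroblasts
# (30,000 cells/well) enucleate with a well-specific probability; each
# enucleation splits one cell into two particles (a reticulocyte and a free
# nucleus); a fraction of cells die and become PI-positive; plates carry
# DMSO negative and cytochalasin D positive control wells; duplicate screens
# are run as separate plates on separate days with between-day noise.

#' Derive a reproducible sub-stream seed
#'
#' Combines a master seed with arbitrary string/integer tokens (plate id,
#' well id, ...) into a deterministic integer below 2^31, so that every
#' well and plate gets its own reproducible RNG stream.
#'
#' @param master Integer master seed.
#' @param ... Tokens (coerced to character) identifying the sub-stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483629  # prime < 2^31
  h <- as.numeric(master) %% m
  for (tok in list(...)) {
    for (code in utf8ToInt(paste0("|", as.character(tok)))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h)
}

#' Ground-truth compound effect profile
#'
#' @param compound_id Character id.
#' @param mechanism One of \code{"none"}, \code{"arrest"}, \code{"delay"},
#'   \code{"toxic"}.  Arrest compounds hold enucleation at its suppressed
#'   level; delay compounds let it catch up to control after the 5 h readout;
#'   toxic compounds kill cells (PI-positive) rather than block enucleation.
#' @param max_inhibition Relative reduction of the enucleation probability at
#'   saturating dose, in [0, 1].
#' @param ec50 Concentration (uM) of half-maximal effect; must be > 0.
#' @param toxicity Fraction of cells rendered PI-positive, in [0, 1].
#' @param recovery_halftime Hours for a delay compound to close half its
#'   remaining gap to control after the 5 h readout.  The default (0.75 h)
#'   makes the treated culture statistically indistinguishable from control
#'   by 10 h at typical assay noise — the delay archetype has reached
#'   vehicle-control levels by the late readout.
#' @return An object of class \code{"compound_profile"}.
#' @export
compound_profile <- function(compound_id, mechanism = "none",
                             max_inhibition = 0, ec50 = 0.1,
                             toxicity = 0, recovery_halftime = 0.75) {
  mechanism <- match.arg(mechanism, c("none", "arrest", "delay", "toxic"))
  if (!is.numeric(max_inhibition) || max_inhibition < 0 || max_inhibition > 1)
    stop("max_inhibition must be in [0, 1]", call. = FALSE)
  if (!is.numeric(toxicity) || toxicity < 0 || toxicity > 1)
    stop("toxicity must be in [0, 1]", call. = FALSE)
  if (!is.numeric(ec50) || ec50 <= 0)
    stop("ec50 must be > 0", call. = FALSE)
  if (mechanism == "none" && max_inhibition != 0)
    stop("mechanism 'none' implies max_inhibition = 0", call. = FALSE)
  if (!is.numeric(recovery_halftime) || recovery_halftime <= 0)
    stop("recovery_halftime must be > 0", call. = FALSE)
  structure(list(compound_id = as.character(compound_id),
                 mechanism = mechanism,
                 max_inhibition = max_inhibition,
                 ec50 = ec50, toxicity = toxicity,
                 recovery_halftime = recovery_halftime),
            class = "compound_profile")
}

# Hill-type fractional effect of a concentration given an EC50 (coefficient 1)
dose_effect <- function(concentration, ec50, hill = 1) {
  stopifnot(concentration >= 0, ec50 > 0)
  concentration^hill / (concentration^hill + ec50^hill)
}

#' Default 324-compound ground-truth library
#'
#' A deterministic library mirroring the screened chemical library's scale:
#' 324 compounds, of which \code{n_inhibitors} (default 25, the number of
#' confirmed inhibitors) truly reduce enucleation with relative reductions
#' spanning \code{inhibition_range}, split between arrest-type and delay-type
#' mechanisms; \code{n_toxic} compounds are cytotoxic without a specific
#' enucleation effect; the rest are inactive.  Inhibitor potency (ec50) is
#' well below the 1 uM screening concentration so the screen operates near
#' saturation.
#'
#' @param n_compounds Library size (default 324).
#' @param n_inhibitors Number of true enucleation inhibitors (default 25 at
#'   the full library size, scaled proportionally for smaller libraries).
#' @param inhibition_range Range of relative reduction for the inhibitors
#'   (default 0.4 to 0.9, i.e. all at or above a 40 percent relative effect).
#' @param n_toxic Number of cytotoxic compounds (default 4).
#' @return List of \code{\link{compound_profile}} objects, length
#'   \code{n_compounds}.
#' @export
default_compound_library <- function(n_compounds = 324,
                                     n_inhibitors = min(25, round(n_compounds * 25 / 324)),
                                     inhibition_range = c(0.4, 0.9),
                                     n_toxic = min(4, round(n_compounds * 4 / 324))) {
  stopifnot(n_inhibitors + n_toxic <= n_compounds)
  ids <- sprintf("C%03d", seq_len(n_compounds))
  lib <- lapply(ids, function(id) compound_profile(id))
  if (n_inhibitors > 0) {
    # spread inhibitors evenly through the plate order
    pos <- unique(round(seq(1, n_compounds, length.out = n_inhibitors)))
    eff <- seq(inhibition_range[1], inhibition_range[2],
               length.out = n_inhibitors)
    for (i in seq_len(n_inhibitors)) {
      mech <- if (i %% 2 == 1) "arrest" else "delay"
      lib[[pos[i]]] <- compound_profile(ids[pos[i]], mechanism = mech,
                                        max_inhibition = eff[i],
                                        ec50 = 0.05)
    }
    tox_pos <- setdiff(seq_len(n_compounds), pos)
    tox_pos <- tox_pos[round(seq(2, length(tox_pos) - 1,
                                 length.out = n_toxic))]
  } else {
    tox_pos <- round(seq(2, n_compounds - 1, length.out = n_toxic))
  }
  for (j in tox_pos) {
    lib[[j]] <- compound_profile(ids[j], mechanism = "toxic", toxicity = 0.5)
  }
  lib
}

#' Screen design parameters
#'
#' @param n_compounds Number of library compounds (default 324).
#' @param concentration Screening concentration in uM (default 1).
#' @param n_replicates Number of biological replicates, each run as a separate
#'   plate set on a separate day (default 2).
#' @param n_cells Cells seeded per well (default 30000).
#' @param baseline_enucleation Negative-control (DMSO) enucleation fraction at
#'   the 5 h readout (default 0.65).
#' @param pos_control_level Residual enucleation fraction in cytochalasin D
#'   wells (default 0.02; enucleation is essentially blocked).
#' @param between_day_sd Between-day plate-level noise, sd in percentage
#'   points (default 4).
#' @param within_plate_sd Within-plate well-level noise, sd in percentage
#'   points (default 3).
#' @param baseline_dead_fraction Background dead-cell fraction (default 0.05).
#' @param n_dmso,n_cytod Control wells per plate (default 4 each).
#' @return An object of class \code{"screen_design"}.
#' @export
screen_design <- function(n_compounds = 324, concentration = 1,
                          n_replicates = 2, n_cells = 30000,
                          baseline_enucleation = 0.65,
                          pos_control_level = 0.02,
                          between_day_sd = 4, within_plate_sd = 3,
                          baseline_dead_fraction = 0.05,
                          n_dmso = 4, n_cytod = 4) {
  stopifnot(n_compounds >= 1, concentration > 0, n_replicates >= 1,
            n_cells >= 1,
            baseline_enucleation >= 0, baseline_enucleation <= 1,
            pos_control_level >= 0, pos_control_level <= 1,
            between_day_sd >= 0, within_plate_sd >= 0,
            baseline_dead_fraction >= 0, baseline_dead_fraction <= 1,
            n_dmso >= 2, n_cytod >= 2, n_dmso + n_cytod < 96)
  structure(list(n_compounds = n_compounds, concentration = concentration,
                 n_replicates = n_replicates, n_cells = n_cells,
                 baseline_enucleation = baseline_enucleation,
                 pos_control_level = pos_control_level,
                 between_day_sd = between_day_sd,
                 within_plate_sd = within_plate_sd,
                 baseline_dead_fraction = baseline_dead_fraction,
                 n_dmso = n_dmso, n_cytod = n_cytod),
            class = "screen_design")
}

#' Per-well ground truth
#'
#' @param well_id Well label, e.g. \code{"A1"}.
#' @param compound_id Compound id or control label.
#' @param true_enucleation_prob Enucleation probability at readout, in [0, 1].
#' @param dead_fraction Fraction of dead (PI-positive) cells, in [0, 1].
#' @param n_cells Number of cells seeded (default 30000).
#' @return An object of class \code{"well_truth"}.
#' @export
well_truth <- function(well_id, compound_id = NA_character_,
                       true_enucleation_prob, dead_fraction = 0,
                       n_cells = 30000) {
  if (!is.numeric(true_enucleation_prob) || true_enucleation_prob < 0 ||
      true_enucleation_prob > 1)
    stop("true_enucleation_prob must be in [0, 1]", call. = FALSE)
  if (!is.numeric(dead_fraction) || dead_fraction < 0 || dead_fraction > 1)
    stop("dead_fraction must be in [0, 1]", call. = FALSE)
  if (!is.numeric(n_cells) || n_cells < 1)
    stop("n_cells must be >= 1", call. = FALSE)
  structure(list(well_id = as.character(well_id),
                 compound_id = as.character(compound_id),
                 true_enucleation_prob = true_enucleation_prob,
                 dead_fraction = dead_fraction,
                 n_cells = as.integer(n_cells)),
            class = "well_truth")
}

# Draw channel values for n events of one population spec.
draw_population_events <- function(spec, n) {
  cols <- lapply(es_channels(), function(ch) {
    p <- spec$channel_params[[ch]]
    stats::rnorm(n, mean = p[1], sd = p[2])
  })
  names(cols) <- es_channels()
  df <- as.data.frame(cols)
  df$truth_label <- rep(spec$name, n)
  df
}

#' Simulate one well of event-level cytometry data
#'
#' Each live cell enucleates with probability
#' \code{truth$true_enucleation_prob}; an enucleation event splits the cell
#' into two particles, a reticulocyte and a free nucleus, both emitted as
#' events.  A \code{dead_fraction} of cells is emitted as PI-positive dead
#' events.  Every event carries its ground-truth population label.
#'
#' @param truth A \code{\link{well_truth}}.
#' @param specs Population channel models
#'   (default \code{\link{default_population_specs}()}).
#' @param seed Integer seed for this well's RNG stream.
#' @return Event \code{data.frame} with columns \code{event_id}, the channels
#'   of \code{\link{es_channels}}, and \code{truth_label}.  Number of rows is
#'   \code{n_cells + (number of enucleations)} since enucleation yields two
#'   particles per cell.
#' @export
simulate_well_events <- function(truth, specs = default_population_specs(),
                                 seed = 1L) {
  if (!inherits(truth, "well_truth")) stop("truth must be a well_truth",
                                           call. = FALSE)
  validate_population_specs(specs)
  set.seed(seed)
  n <- truth$n_cells
  is_dead <- stats::runif(n) < truth$dead_fraction
  n_dead <- sum(is_dead)
  n_live <- n - n_dead
  enuc <- stats::runif(n_live) < truth$true_enucleation_prob
  n_enuc <- sum(enuc)
  parts <- list(
    draw_population_events(specs$orthochromatic_erythroblast, n_live - n_enuc),
    draw_population_events(specs$reticulocyte, n_enuc),
    draw_population_events(specs$free_nucleus, n_enuc),
    draw_population_events(specs$dead_cell, n_dead)
  )
  ev <- do.call(rbind, parts)
  if (nrow(ev)) ev <- cbind(event_id = seq_len(nrow(ev)), ev)
  else ev <- cbind(event_id = integer(0), ev)
  rownames(ev) <- NULL
  ev
}

# Standard 96-well ids in row-major order: A1..A12, B1..B12, ...
well_ids_96 <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

# Control layout: n_dmso + n_cytod wells placed at fixed, spread-out
# positions; the remainder are compound wells in row-major order.
plate_layout <- function(n_dmso = 4, n_cytod = 4) {
  wells <- well_ids_96()
  ctrl_slots <- c("A1", "A12", "D6", "D7", "E6", "E7", "H1", "H12",
                  "B1", "B12", "G1", "G12")
  dmso <- ctrl_slots[seq_len(n_dmso)]
  cytod <- ctrl_slots[n_dmso + seq_len(n_cytod)]
  role <- rep("compound", length(wells))
  names(role) <- wells
  role[dmso] <- "neg_control"
  role[cytod] <- "pos_control"
  data.frame(well_id = wells, role = unname(role[wells]),
             stringsAsFactors = FALSE)
}

#' Simulate a full duplicate compound screen
#'
#' Lays the library across as many 96-well plates as needed (each with the
#' design's DMSO and cytochalasin D control wells), runs each replicate as a
#' separate set of plates on a separate day with an independent plate-level
#' between-day noise draw, adds well-level within-plate noise, and samples
#' gated counts (fast count-level mode) or full event tables per well.
#'
#' @param design A \code{\link{screen_design}}.
#' @param library List of \code{\link{compound_profile}}s, length
#'   \code{design$n_compounds}.
#' @param seed Master integer seed; together with the design it fully
#'   determines the output.
#' @param mode \code{"counts"} (default; emits per-well gated counts directly,
#'   suitable for whole-screen work) or \code{"events"} (additionally emits an
#'   event table per well; use a reduced \code{n_cells} for tractability).
#' @param specs Population channel models used in event mode.
#' @return An object of class \code{"screen_sim"}: list with \code{counts}
#'   (per-well data.frame: plate_id, well_id, replicate, role, compound_id,
#'   concentration, n_enucleated, n_nucleated, n_live, n_total), \code{truth}
#'   (per-well nominal and realized enucleation probabilities plus per-well
#'   seeds), \code{events} (named list of event tables in event mode),
#'   \code{design} and \code{library}.
#' @export
simulate_screen <- function(design = screen_design(),
                            library = default_compound_library(design$n_compounds),
                            seed = 1L, mode = c("counts", "events"),
                            specs = default_population_specs()) {
  mode <- match.arg(mode)
  if (length(library) != design$n_compounds)
    stop("library size (", length(library),
         ") does not match design$n_compounds (", design$n_compounds, ")",
         call. = FALSE)
  layout <- plate_layout(design$n_dmso, design$n_cytod)
  n_comp_wells <- sum(layout$role == "compound")
  n_plates <- ceiling(design$n_compounds / n_comp_wells)
  lib_ids <- vapply(library, `[[`, character(1), "compound_id")
  names(library) <- lib_ids

  rows <- list(); events <- list(); k <- 0L
  for (rep_i in seq_len(design$n_replicates)) {
    comp_idx <- 0L
    for (plate_i in seq_len(n_plates)) {
      plate_id <- sprintf("P%d_rep%d", plate_i, rep_i)
      set.seed(derive_seed(seed, "day", plate_i, rep_i))
      day_shift <- stats::rnorm(1, 0, design$between_day_sd / 100)
      for (w in seq_len(nrow(layout))) {
        role <- layout$role[w]; well_id <- layout$well_id[w]
        if (role == "compound") {
          comp_idx <- comp_idx + 1L
          if (comp_idx > design$n_compounds) next  # trailing empty wells
          prof <- library[[comp_idx]]
          cid <- prof$compound_id
          d <- dose_effect(design$concentration, prof$ec50)
          p_nom <- design$baseline_enucleation * (1 - prof$max_inhibition * d)
          dead <- min(1, design$baseline_dead_fraction + prof$toxicity)
        } else if (role == "neg_control") {
          cid <- "DMSO"
          p_nom <- design$baseline_enucleation
          dead <- design$baseline_dead_fraction
        } else {
          cid <- "CytoD"
          p_nom <- design$pos_control_level
          dead <- design$baseline_dead_fraction
        }
        wseed <- derive_seed(seed, plate_id, well_id)
        set.seed(wseed)
        p_real <- min(1, max(0, p_nom + day_shift +
                               stats::rnorm(1, 0, design$within_plate_sd / 100)))
        k <- k + 1L
        if (mode == "events") {
          tr <- well_truth(well_id, cid, p_real, dead, design$n_cells)
          ev <- simulate_well_events(tr, specs,
                                     seed = derive_seed(wseed, "events"))
          events[[paste(plate_id, well_id, sep = ":")]] <- ev
          n_dead <- sum(ev$truth_label == "dead_cell")
          n_enuc <- sum(ev$truth_label == "reticulocyte")
          n_nuc <- sum(ev$truth_label == "orthochromatic_erythroblast")
          n_total <- nrow(ev)
        } else {
          n_dead <- stats::rbinom(1, design$n_cells, dead)
          live_cells <- design$n_cells - n_dead
          n_enuc <- stats::rbinom(1, live_cells, p_real)
          n_nuc <- live_cells - n_enuc
          n_total <- design$n_cells + n_enuc  # enucleation adds a particle
        }
        rows[[k]] <- data.frame(
          plate_id = plate_id, well_id = well_id, replicate = rep_i,
          role = role, compound_id = cid,
          concentration = if (role == "compound") design$concentration else NA_real_,
          n_enucleated = n_enuc, n_nucleated = n_nuc,
          n_live = n_enuc * 2L + n_nuc, n_total = n_total,
          p_nominal = p_nom, p_realized = p_real, dead_fraction = dead,
          well_seed = wseed, stringsAsFactors = FALSE)
      }
    }
  }
  all <- do.call(rbind, rows)
  counts <- all[, c("plate_id", "well_id", "replicate", "role", "compound_id",
                    "concentration", "n_enucleated", "n_nucleated",
                    "n_live", "n_total")]
  truth <- all[, c("plate_id", "well_id", "replicate", "role", "compound_id",
                   "p_nominal", "p_realized", "dead_fraction", "well_seed")]
  structure(list(counts = counts, truth = truth,
                 events = if (mode == "events") events else NULL,
                 design = design, library = library, seed = seed),
            class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("Simulated enucleation screen\n")
  cat("  compounds:", x$design$n_compounds,
      " replicates:", x$design$n_replicates,
      " cells/well:", x$design$n_cells, "\n")
  cat("  wells:", nrow(x$counts),
      " plates:", length(unique(x$counts$plate_id)), "\n")
  if (!is.null(x$events)) cat("  event tables:", length(x$events), "\n")
  invisible(x)
}

#' Enucleation kinetics ground truth
#'
#' The control enucleation fraction rises linearly from the sort and
#' plateaus near 70 percent at about 6 hours.
#'
#' @param plateau Plateau enucleation fraction (default 0.70).
#' @param t_plateau Hours at which the plateau is reached (default 6).
#' @return An object of class \code{"kinetics_truth"} with a
#'   \code{control(t)} curve function.
#' @export
kinetics_truth <- function(plateau = 0.70, t_plateau = 6) {
  stopifnot(plateau > 0, plateau <= 1, t_plateau > 0)
  structure(list(plateau = plateau, t_plateau = t_plateau,
                 rate = plateau / t_plateau,
                 control = function(t) plateau * pmin(pmax(t, 0) / t_plateau, 1)),
            class = "kinetics_truth")
}

#' Simulate an enucleation time course for one compound
#'
#' Control wells follow the linear-rise-to-plateau kinetics.  Arrest
#' compounds hold the treated culture at its suppressed level from the
#' treatment readout (5 h) onwards; delay compounds converge back to the
#' control curve with the profile's \code{recovery_halftime}; inactive and
#' purely toxic compounds track control.  With \code{washout_at} set, the
#' treated culture resumes control-rate kinetics from its current level at
#' the washout time (used for washout-recovery experiments).
#'
#' @param profile A \code{\link{compound_profile}}.
#' @param timepoints Hours (non-empty, non-negative) at which to observe.
#' @param kinetics A \code{\link{kinetics_truth}}.
#' @param seed Integer seed.
#' @param n_experiments Independent replicate experiments (default 3).
#' @param noise_sd Observation noise sd on the fraction scale (default 0.03).
#' @param concentration Treatment concentration in uM (default 1).
#' @param suppression_until Hours during which the compound acts before any
#'   delay-type recovery begins (default 5, the screen readout time).
#' @param washout_at Optional hour at which the compound is washed out.
#' @return data.frame with columns \code{time_h}, \code{experiment},
#'   \code{arm} (\code{"control"}/\code{"treated"}) and
#'   \code{enucleation_pct}.
#' @export
simulate_kinetics <- function(profile, timepoints, kinetics = kinetics_truth(),
                              seed = 1L, n_experiments = 3, noise_sd = 0.03,
                              concentration = 1, suppression_until = 5,
                              washout_at = NULL) {
  if (!length(timepoints) || any(timepoints < 0))
    stop("timepoints must be non-empty and non-negative", call. = FALSE)
  timepoints <- sort(unique(as.numeric(timepoints)))
  d <- dose_effect(concentration, profile$ec50)
  supp <- if (profile$mechanism %in% c("arrest", "delay"))
    profile$max_inhibition * d else 0

  treated_curve <- function(t) {
    ctrl <- kinetics$control
    base <- ctrl(t) * (1 - supp)
    if (!is.null(washout_at)) {
      # compound removed: resume control-rate rise from the level at washout
      lvl <- treated_level_no_washout(washout_at)
      out <- ifelse(t <= washout_at, treated_level_no_washout(t),
                    pmin(kinetics$plateau,
                         lvl + kinetics$rate * (t - washout_at)))
      return(out)
    }
    treated_level_no_washout(t)
  }
  treated_level_no_washout <- function(t) {
    ctrl <- kinetics$control
    if (profile$mechanism == "arrest") {
      # held at the suppressed level reached by the readout time
      ifelse(t <= suppression_until, ctrl(t) * (1 - supp),
             ctrl(suppression_until) * (1 - supp))
    } else if (profile$mechanism == "delay") {
      gap5 <- ctrl(suppression_until) * supp
      ifelse(t <= suppression_until, ctrl(t) * (1 - supp),
             ctrl(t) - gap5 * 2^(-(t - suppression_until) /
                                   profile$recovery_halftime))
    } else {
      ctrl(t)
    }
  }

  set.seed(seed)
  grid <- expand.grid(time_h = timepoints, experiment = seq_len(n_experiments),
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  ctrl_obs <- pmin(1, pmax(0, kinetics$control(grid$time_h) +
                                stats::rnorm(n, 0, noise_sd)))
  trt_obs <- pmin(1, pmax(0, treated_curve(grid$time_h) +
                               stats::rnorm(n, 0, noise_sd)))
  rbind(
    data.frame(grid, arm = "control", enucleation_pct = 100 * ctrl_obs,
               stringsAsFactors = FALSE),
    data.frame(grid, arm = "treated", enucleation_pct = 100 * trt_obs,
               stringsAsFactors = FALSE)
  )
}

#' Simulate BrdU / 7-AAD cell-cycle events
#'
#' S-phase cells are BrdU-positive with intermediate DNA content; G0/G1 cells
#' are BrdU-negative with 2N DNA; G2/M cells are BrdU-negative with 4N DNA.
#'
#' @param fraction_s Fraction of S-phase cells.
#' @param fraction_g2m Fraction of G2/M cells;
#'   \code{fraction_s + fraction_g2m} must not exceed 1.
#' @param n_cells Number of events.
#' @param seed Integer seed.
#' @param specs Population specs providing the baseline channel model.
#' @return Event data.frame (channels as \code{\link{es_channels}}) with
#'   \code{truth_label} in \code{\{"S", "G0G1", "G2M"\}}.
#' @export
simulate_cellcycle_events <- function(fraction_s, fraction_g2m, n_cells,
                                      seed = 1L,
                                      specs = default_population_specs()) {
  if (fraction_s < 0 || fraction_g2m < 0 || fraction_s + fraction_g2m > 1)
    stop("fractions must be non-negative with fraction_s + fraction_g2m <= 1",
         call. = FALSE)
  stopifnot(n_cells >= 1)
  set.seed(seed)
  u <- stats::runif(n_cells)
  phase <- ifelse(u < fraction_s, "S",
                  ifelse(u < fraction_s + fraction_g2m, "G2M", "G0G1"))
  base <- specs$orthochromatic_erythroblast
  ev <- draw_population_events(base, n_cells)
  dna2n <- base$channel_params$DNA
  n <- n_cells
  # overwrite BrdU and DNA per phase
  ev$BrdU <- ifelse(phase == "S", stats::rnorm(n, 4.0, 0.40),
                    stats::rnorm(n, 1.0, 0.35))
  ev$DNA <- ifelse(phase == "G0G1", stats::rnorm(n, dna2n[1], dna2n[2]),
            ifelse(phase == "G2M", stats::rnorm(n, 2 * dna2n[1], 1.8 * dna2n[2]),
                   stats::runif(n, 1.15 * dna2n[1], 1.85 * dna2n[1])))
  ev$truth_label <- phase
  cbind(event_id = seq_len(n), ev)
}

#' Simulate cytospin morphology class counts
#'
#' Multinomial draws per independent experiment over a morphology taxonomy,
#' with the per-experiment number of enumerated cells drawn uniformly from a
#' configurable range (cytospin counts in the assay ranged roughly from 112
#' to 541 cells per experiment).
#'
#' @param class_probs Named numeric vector of class probabilities summing
#'   to 1.
#' @param n_cells Either a single count used for every experiment or a
#'   \code{c(min, max)} range to sample from (default \code{c(112, 541)}).
#' @param n_experiments Number of independent experiments.
#' @param seed Integer seed.
#' @return data.frame with columns \code{experiment_id}, \code{class},
#'   \code{count}.
#' @export
simulate_morphology_counts <- function(class_probs, n_cells = c(112, 541),
                                       n_experiments = 4, seed = 1L) {
  if (is.null(names(class_probs)) || any(!nzchar(names(class_probs))))
    stop("class_probs must be a named vector", call. = FALSE)
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop("class_probs must sum to 1", call. = FALSE)
  if (any(class_probs < 0)) stop("class_probs must be non-negative",
                                 call. = FALSE)
  stopifnot(n_experiments >= 1, all(n_cells >= 1))
  set.seed(seed)
  ns <- if (length(n_cells) == 1L) rep(n_cells, n_experiments)
        else round(stats::runif(n_experiments, n_cells[1], n_cells[2]))
  out <- lapply(seq_len(n_experiments), function(i) {
    cnt <- stats::rmultinom(1, ns[i], class_probs)[, 1]
    data.frame(experiment_id = i, class = names(class_probs), count = cnt,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Default cytospin morphology taxonomy
#'
#' @return Character vector of morphology class names.
#' @export
morphology_classes <- function() {
  c("round_nucleus", "polarized_nucleus", "extruding", "segmented_nucleus",
    "reticulocyte", "free_nucleus")
}
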