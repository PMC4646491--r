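# Orchestration: simulation -> gating -> screen analysis -> follow-up as
# reproducible file-based runs.  These functions are the package-level
# surface behind the thin command-line front-end in inst/cli/erythroscreen.R.

#' Simulate a screen and write its files
#'
#' Writes the per-well gated-count CSV, the plate map CSV and the ground
#' truth JSON for a simulated duplicate screen (and, in event mode, one
#' event CSV per well).  Deterministic given the config.
#'
#' @param config A \code{\link{run_config}}.
#' @param out_dir Output directory (created if needed).
#' @param mode \code{"counts"} (default) or \code{"events"}.
#' @return Invisibly, the \code{screen_sim} object.
#' @export
run_simulate_screen <- function(config, out_dir, mode = c("counts", "events")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- default_population_specs(config$free_nucleus_ter119_positive)
  sim <- simulate_screen(config$design,
                         default_compound_library(config$design$n_compounds),
                         seed = config$seed, mode = mode, specs = specs)
  write_csv_prov(sim$counts, file.path(out_dir, "counts.csv"), config)
  pm <- sim$counts[, c("plate_id", "well_id", "replicate", "role",
                       "compound_id", "concentration")]
  write_csv_prov(pm, file.path(out_dir, "plate_map.csv"), config)
  write_truth_json(sim, file.path(out_dir, "truth.json"), config)
  if (mode == "events") {
    ev_dir <- file.path(out_dir, "events")
    dir.create(ev_dir, showWarnings = FALSE)
    for (key in names(sim$events)) {
      fname <- paste0(gsub(":", "_", key), ".csv")
      write_events_csv(sim$events[[key]], file.path(ev_dir, fname), config)
    }
  }
  invisible(sim)
}

# Gate a directory of per-well event CSVs (named <plate>_<well>.csv) into a
# gated-count table using the plate map for roles/compounds.
gate_event_dir <- function(events_dir, plate_map, thresholds = default_thresholds()) {
  rows <- lapply(seq_len(nrow(plate_map)), function(i) {
    pm <- plate_map[i, ]
    path <- file.path(events_dir,
                      paste0(pm$plate_id, "_", pm$well_id, ".csv"))
    if (!file.exists(path))
      stop("plate map names well ", pm$plate_id, ":", pm$well_id,
           " but no event file ", basename(path), " exists", call. = FALSE)
    ev <- read_events_csv(path)
    lv <- gate_live(ev, thresholds$pi)
    cls <- classify_enucleation(lv$live, thresholds$ter119,
                                thresholds$hoechst)
    data.frame(pm[, c("plate_id", "well_id", "replicate", "role",
                      "compound_id")],
               concentration = if ("concentration" %in% names(pm))
                 pm$concentration else NA_real_,
               n_enucleated = cls$n_enucleated,
               n_nucleated = cls$n_nucleated,
               n_live = lv$n_live, n_total = nrow(ev),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Analyse a screen from count- or event-level files
#'
#' Runs gating (when given event CSVs), the net-enucleation statistic,
#' plate-median normalization, hit calling and QC, and writes the
#' plate-results CSV, hit-list CSV and QC JSON with provenance.  Count-level
#' input bypasses gating and yields the same hit list as event-level input
#' generated from the same truth.
#'
#' @param config A \code{\link{run_config}}.
#' @param out_dir Output directory.
#' @param counts_csv Path to a gated-count CSV (count-level path), or NULL.
#' @param events_dir Directory of per-well event CSVs (event-level path),
#'   requires \code{plate_map_csv}.
#' @param plate_map_csv Plate-map CSV path (event-level path).
#' @return Invisibly, the \code{\link{analyze_screen}} result.
#' @export
run_analyze <- function(config, out_dir, counts_csv = NULL,
                        events_dir = NULL, plate_map_csv = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(counts_csv)) {
    counts <- read_counts_csv(counts_csv)
  } else {
    if (is.null(events_dir) || is.null(plate_map_csv))
      stop("need either counts_csv or (events_dir + plate_map_csv)",
           call. = FALSE)
    pm <- read_plate_map(plate_map_csv)
    counts <- gate_event_dir(events_dir, pm)
  }
  res <- analyze_screen(counts, scale_method = config$scale_method,
                        hit_threshold = config$hit_threshold)
  if (any(!res$plates$qc_pass))
    warning("plate(s) failing Z'-factor QC: ",
            paste(res$plates$plate_id[!res$plates$qc_pass], collapse = ", "),
            call. = FALSE)
  wells_out <- res$wells[, c("plate_id", "well_id", "replicate", "role",
                             "compound_id", "n_enucleated", "n_nucleated",
                             "net_enucleation_pct", "centered", "z",
                             "qc_flags")]
  write_csv_prov(wells_out, file.path(out_dir, "plate_results.csv"), config)
  write_csv_prov(res$hits, file.path(out_dir, "hit_list.csv"), config)
  qc <- list(provenance = list(config_hash = config_hash(config),
                               seed = config$seed),
             replicate_r = res$replicate_r,
             plates = res$plates)
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(res)
}

#' Run the follow-up analyses from CSV tables
#'
#' @param config A \code{\link{run_config}}.
#' @param out_dir Output directory.
#' @param validation_csv Long table \code{compound_id, experiment_id, arm,
#'   timepoint_h, enucleation_pct}; rows at the 5 h readout (or without a
#'   \code{timepoint_h} column) feed the paired-t validation, and compounds
#'   with both 5 h and 10 h readings get a delay/arrest mechanism call.
#' @param dose_csv Optional table \code{compound_id, concentration,
#'   enucleation_pct} for the monotone-trend test.
#' @param washout_csv Optional table \code{compound_id, time_h, treated_pct,
#'   control_pct} of post-washout means.
#' @param morphology_csv Optional table \code{experiment_id, class, count}
#'   (single condition) or with a \code{condition} column.
#' @return Invisibly, a list of the report data.frames that were written.
#' @export
run_validate <- function(config, out_dir, validation_csv,
                         dose_csv = NULL, washout_csv = NULL,
                         morphology_csv = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  val <- read_csv_prov(validation_csv)
  req <- c("compound_id", "experiment_id", "arm", "enucleation_pct")
  miss <- setdiff(req, names(val))
  if (length(miss))
    stop("validation table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  has_t <- "timepoint_h" %in% names(val)
  val5 <- if (has_t) val[val$timepoint_h <= 5 | is.na(val$timepoint_h), ]
          else val
  out$validation <- validate_compounds(val5)
  write_csv_prov(out$validation, file.path(out_dir, "validation.csv"), config)

  if (has_t && any(val$timepoint_h > 5, na.rm = TRUE)) {
    mech_rows <- lapply(unique(val$compound_id), function(cid) {
      v <- val[val$compound_id == cid, ]
      if (!any(v$timepoint_h > 5, na.rm = TRUE)) return(NULL)
      arm_t <- function(arm, late) {
        sel <- v$arm == arm & (if (late) v$timepoint_h > 5 else v$timepoint_h <= 5)
        vv <- v[sel, ]
        vv$enucleation_pct[order(vv$experiment_id)]
      }
      t5 <- arm_t("treated", FALSE); c5 <- arm_t("control", FALSE)
      t10 <- arm_t("treated", TRUE); c10 <- arm_t("control", TRUE)
      if (!length(t10) || !length(c10) || length(t5) < 2) return(NULL)
      mc <- classify_mechanism(t5, c5, t10, c10, alpha = config$alpha,
                               compound_id = cid)
      data.frame(compound_id = cid, call = mc$call,
                 delta_5h = mc$delta_5h, p_5h = mc$test_5h$p,
                 delta_10h = mc$delta_10h, p_10h = mc$test_10h$p,
                 stringsAsFactors = FALSE)
    })
    mech <- do.call(rbind, mech_rows)
    if (!is.null(mech)) {
      out$mechanism <- mech
      write_csv_prov(mech, file.path(out_dir, "mechanism_calls.csv"), config)
    }
  }

  if (!is.null(dose_csv)) {
    dose <- read_csv_prov(dose_csv)
    rows <- lapply(unique(dose$compound_id), function(cid) {
      d <- dose[dose$compound_id == cid, ]
      dt <- dose_trend(d$concentration, d$enucleation_pct,
                       alpha = config$alpha)
      data.frame(compound_id = cid, rho = dt$rho, p = dt$p,
                 concentration_dependent = dt$concentration_dependent,
                 stringsAsFactors = FALSE)
    })
    out$dose <- do.call(rbind, rows)
    write_csv_prov(out$dose, file.path(out_dir, "dose_trend.csv"), config)
  }

  if (!is.null(washout_csv)) {
    wo <- read_csv_prov(washout_csv)
    rows <- lapply(unique(wo$compound_id), function(cid) {
      w <- wo[wo$compound_id == cid, ]
      wr <- washout_recovery(w$time_h, w$treated_pct, w$control_pct,
                             margin = config$washout_margin)
      data.frame(compound_id = cid, recovered = wr$recovered,
                 first_recovery_time = wr$first_recovery_time,
                 stringsAsFactors = FALSE)
    })
    out$washout <- do.call(rbind, rows)
    write_csv_prov(out$washout, file.path(out_dir, "washout.csv"), config)
  }

  if (!is.null(morphology_csv)) {
    mo <- read_csv_prov(morphology_csv)
    conds <- if ("condition" %in% names(mo)) unique(mo$condition) else NA
    rows <- lapply(conds, function(cond) {
      m <- if (is.na(cond)) mo else mo[mo$condition == cond, ]
      mp <- morphology_proportions(m)
      data.frame(condition = if (is.na(cond)) "all" else cond, mp$summary,
                 stringsAsFactors = FALSE)
    })
    out$morphology <- do.call(rbind, rows)
    write_csv_prov(out$morphology, file.path(out_dir, "morphology.csv"),
                   config)
  }
  invisible(out)
}
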