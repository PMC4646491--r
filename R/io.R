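# CSV / JSON format handling.  CSV is the contract format throughout; event
# tables, plate maps, gated counts and follow-up tables are plain CSVs.
# Output files carry a one-line '#' provenance comment (config hash + seed),
# which the readers here skip.

#' Run configuration
#'
#' Collects every knob of a reproducible pipeline run: the master seed, the
#' z-score scale convention, thresholds and alpha levels, and the simulator
#' design.
#'
#' @param seed Master integer seed.
#' @param scale_method Plate z-score scale: \code{"sd"} or \code{"mad"}.
#' @param hit_threshold z threshold for potential hits (default -1).
#' @param alpha Significance level for follow-up tests (default 0.05).
#' @param washout_margin Recovery margin in percentage points (default 10).
#' @param design A \code{\link{screen_design}}.
#' @param free_nucleus_ter119_positive Channel-model switch for extruded
#'   nuclei (see \code{\link{default_population_specs}}).
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(seed = 1L, scale_method = c("sd", "mad"),
                       hit_threshold = -1, alpha = 0.05, washout_margin = 10,
                       design = screen_design(),
                       free_nucleus_ter119_positive = FALSE) {
  scale_method <- match.arg(scale_method)
  stopifnot(is.numeric(seed), length(seed) == 1L, alpha > 0, alpha < 1)
  structure(list(seed = as.integer(seed), scale_method = scale_method,
                 hit_threshold = hit_threshold, alpha = alpha,
                 washout_margin = washout_margin, design = design,
                 free_nucleus_ter119_positive = free_nucleus_ter119_positive),
            class = "run_config")
}

# FNV-1a string hash (hex); no external digest dependency.
fnv1a_hash <- function(s) {
  h <- 2166136261
  for (code in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Hash a run configuration
#'
#' @param config A \code{\link{run_config}}.
#' @return 8-hex-digit hash string recorded in output provenance.
#' @export
config_hash <- function(config) {
  fnv1a_hash(as.character(jsonlite::toJSON(unclass_recursive(config),
                                           auto_unbox = TRUE, digits = NA)))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

provenance_line <- function(config) {
  sprintf("# provenance: config_hash=%s seed=%d package=erythroscreen %s",
          config_hash(config), config$seed,
          as.character(utils::packageVersion("erythroscreen")))
}

write_csv_prov <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(provenance_line(config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_prov <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read event tables as CSV
#'
#' Header: \code{event_id, FSC, SSC, Hoechst, Ter119, CD44, PI, BrdU, DNA,
#' truth_label}; \code{truth_label} may be blank for real (non-simulated)
#' data.
#'
#' @param events Event data.frame.
#' @param path File path.
#' @param config Optional \code{\link{run_config}} for the provenance line.
#' @return The path (write) or the event data.frame (read).
#' @export
write_events_csv <- function(events, path, config = NULL) {
  cols <- c("event_id", es_channels(), "truth_label")
  if (!("truth_label" %in% names(events))) events$truth_label <- ""
  write_csv_prov(events[, intersect(cols, names(events))], path, config)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- read_csv_prov(path)
  miss <- setdiff(es_channels(), names(ev))
  if (length(miss))
    stop("event CSV missing channel(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ev
}

#' Read a plate map CSV
#'
#' Columns: \code{plate_id}, \code{well_id}, \code{replicate}, \code{role}
#' (\code{compound}/\code{neg_control}/\code{pos_control}), \code{compound_id}
#' and optionally \code{concentration}.
#'
#' @param path File path.
#' @return Plate-map data.frame.
#' @export
read_plate_map <- function(path) {
  pm <- read_csv_prov(path)
  if (!nrow(pm)) stop("empty plate map", call. = FALSE)
  req <- c("plate_id", "well_id", "replicate", "role", "compound_id")
  miss <- setdiff(req, names(pm))
  if (length(miss))
    stop("plate map missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(pm$role), c("compound", "neg_control", "pos_control"))
  if (length(bad))
    stop("unknown role(s) in plate map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  pm
}

#' Read a gated-count CSV
#'
#' Columns: \code{plate_id}, \code{well_id}, \code{replicate}, \code{role},
#' \code{compound_id}, \code{n_enucleated}, \code{n_nucleated} and optionally
#' \code{n_live}, \code{n_total}, \code{concentration}.
#'
#' @param path File path.
#' @return Counts data.frame suitable for \code{\link{analyze_screen}}.
#' @export
read_counts_csv <- function(path) {
  cc <- read_csv_prov(path)
  req <- c("plate_id", "well_id", "replicate", "role", "compound_id",
           "n_enucleated", "n_nucleated")
  miss <- setdiff(req, names(cc))
  if (length(miss))
    stop("counts CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cc
}

#' Read gate definitions from a JSON gating file
#'
#' The file holds a list of gate records: \code{name}, \code{parent}
#' (\code{"root"} or an earlier gate), \code{type} (\code{"rect"} or
#' \code{"polygon"}), \code{channel_x}, optionally \code{channel_y},
#' \code{xlim}/\code{ylim} or \code{vertices}, \code{transform} and
#' \code{cofactor}.
#'
#' @param path JSON file path.
#' @return A \code{\link{gating_hierarchy}}.
#' @export
read_gates_json <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  gates <- lapply(spec, function(g) {
    tr <- if (is.null(g$transform)) "identity" else g$transform
    cf <- if (is.null(g$cofactor)) 150 else g$cofactor
    if (identical(g$type, "polygon")) {
      polygon_gate(g$name, g$channel_x, g$channel_y,
                   do.call(rbind, lapply(g$vertices, unlist)),
                   transform = tr, cofactor = cf)
    } else {
      rect_gate(g$name, g$channel_x, unlist(g$xlim),
                channel_y = g$channel_y,
                ylim = if (is.null(g$ylim)) NULL else unlist(g$ylim),
                transform = tr, cofactor = cf)
    }
  })
  parents <- vapply(spec, function(g)
    if (is.null(g$parent)) "root" else g$parent, character(1))
  gating_hierarchy(gates, parents)
}

#' Write a simulation truth record as JSON
#'
#' @param sim A \code{screen_sim} from \code{\link{simulate_screen}}.
#' @param path Output JSON path.
#' @param config Optional \code{\link{run_config}} recorded in the file.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(sim, path, config = NULL) {
  rec <- list(
    seed = sim$seed,
    design = unclass(sim$design),
    library = lapply(sim$library, unclass),
    wells = sim$truth)
  if (!is.null(config))
    rec$provenance <- list(config_hash = config_hash(config),
                           seed = config$seed)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
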