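# Net-enucleation statistic, plate-median normalization, z-score hit calling
# and plate QC.

#' Net enucleation percentage
#'
#' The screen's readout: the number of enucleated cells
#' (Ter119-positive/Hoechst-negative) divided by the sum of enucleated cells
#' and nucleated erythroblasts (Ter119-positive/Hoechst-positive), times 100.
#'
#' @param n_enucleated,n_nucleated Non-negative counts (vectorised).
#' @return Percentage in [0, 100]; \code{NA} (missing, not zero) where both
#'   counts are zero.
#' @export
net_enucleation <- function(n_enucleated, n_nucleated) {
  if (any(n_enucleated < 0, na.rm = TRUE) || any(n_nucleated < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  denom <- n_enucleated + n_nucleated
  ifelse(denom == 0, NA_real_, 100 * n_enucleated / denom)
}

#' Plate-median normalization and z-scores
#'
#' Centers compound-well readouts by the plate median and scales them into
#' z-scores.  Control wells are excluded from both the median and the scale
#' (they are extreme by construction); missing wells propagate as missing.
#'
#' @param values Numeric vector of raw compound-well percentages (may contain
#'   \code{NA}).
#' @param scale_method \code{"sd"} (default; sample standard deviation of the
#'   median-centered values) or \code{"mad"} (1.4826 times the median absolute
#'   deviation, robust to strong hits).
#' @return List with \code{centered}, \code{z}, \code{plate_median} and
#'   \code{scale}.
#' @export
normalize_plate <- function(values, scale_method = c("sd", "mad")) {
  scale_method <- match.arg(scale_method)
  ok <- !is.na(values)
  if (sum(ok) < 3)
    stop("need at least 3 non-missing compound-well values", call. = FALSE)
  med <- stats::median(values[ok])
  centered <- values - med
  s <- if (scale_method == "sd") stats::sd(centered[ok])
       else stats::mad(centered[ok])  # default constant 1.4826
  if (!is.finite(s) || s == 0)
    stop("degenerate plate: zero scale (all compound wells identical)",
         call. = FALSE)
  list(centered = centered, z = centered / s, plate_median = med, scale = s)
}

#' Hit calling over two replicate plates
#'
#' A compound is a potential hit when its z-score is strictly below the
#' threshold in either replicate (the selection rule used for the screen;
#' default threshold -1).  Compounds with a missing z in one replicate are
#' called on the remaining replicate and flagged.
#'
#' @param z_rep1,z_rep2 Named (by compound id) or plain numeric z-score
#'   vectors over the same compound set, in the same order if unnamed.
#' @param threshold Hit threshold (default -1, strict inequality).
#' @return data.frame with \code{compound_id}, \code{z_rep1}, \code{z_rep2},
#'   \code{is_potential_hit}, \code{flagged_single_replicate}.
#' @export
call_hits <- function(z_rep1, z_rep2, threshold = -1) {
  ids1 <- names(z_rep1); ids2 <- names(z_rep2)
  if (!is.null(ids1) && !is.null(ids2)) {
    if (!setequal(ids1, ids2))
      stop("compound sets differ between replicates", call. = FALSE)
    z_rep2 <- z_rep2[ids1]
    ids <- ids1
  } else {
    if (length(z_rep1) != length(z_rep2))
      stop("compound sets differ between replicates", call. = FALSE)
    ids <- if (!is.null(ids1)) ids1 else
           if (!is.null(ids2)) ids2 else
           sprintf("compound_%d", seq_along(z_rep1))
  }
  hit1 <- !is.na(z_rep1) & z_rep1 < threshold
  hit2 <- !is.na(z_rep2) & z_rep2 < threshold
  both_missing <- is.na(z_rep1) & is.na(z_rep2)
  data.frame(compound_id = ids,
             z_rep1 = unname(z_rep1), z_rep2 = unname(z_rep2),
             is_potential_hit = ifelse(both_missing, NA, hit1 | hit2),
             flagged_single_replicate = xor(is.na(z_rep1), is.na(z_rep2)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Replicate correlation
#'
#' Pearson correlation of raw compound-well readouts between the two
#' biological replicates; pairs with any missing value are dropped.
#'
#' @param values_rep1,values_rep2 Numeric vectors over the same compounds.
#' @return Pearson r.
#' @export
replicate_correlation <- function(values_rep1, values_rep2) {
  if (length(values_rep1) != length(values_rep2))
    stop("replicate vectors must have equal length", call. = FALSE)
  ok <- !is.na(values_rep1) & !is.na(values_rep2)
  if (sum(ok) < 3) stop("need at least 3 shared non-missing pairs",
                        call. = FALSE)
  stats::cor(values_rep1[ok], values_rep2[ok])
}

#' Z'-factor plate quality control
#'
#' Z' = 1 - 3 (sd_neg + sd_pos) / |mean_neg - mean_pos| computed on the raw
#' enucleation percentages of the DMSO (negative) and cytochalasin D
#' (positive) control wells.  Plates with Z' below \code{fail_below} are
#' flagged failing (the hit list is still produced).
#'
#' @param neg_values,pos_values Control-well enucleation percentages
#'   (at least 2 wells per role).
#' @param fail_below Z' threshold for flagging (default 0).
#' @return List with control means/sds, \code{z_prime} (\code{-Inf} when the
#'   control means coincide) and \code{pass}.
#' @export
plate_qc <- function(neg_values, pos_values, fail_below = 0) {
  neg_values <- neg_values[!is.na(neg_values)]
  pos_values <- pos_values[!is.na(pos_values)]
  if (length(neg_values) < 2 || length(pos_values) < 2)
    stop("need at least 2 wells per control role", call. = FALSE)
  m_neg <- mean(neg_values); m_pos <- mean(pos_values)
  s_neg <- stats::sd(neg_values); s_pos <- stats::sd(pos_values)
  sep <- abs(m_neg - m_pos)
  z_prime <- if (sep == 0) -Inf else 1 - 3 * (s_neg + s_pos) / sep
  list(mean_neg = m_neg, sd_neg = s_neg, mean_pos = m_pos, sd_pos = s_pos,
       z_prime = z_prime, pass = is.finite(z_prime) && z_prime >= fail_below)
}

#' Analyse a duplicate enucleation screen
#'
#' The pipeline's central analysis step: computes the net-enucleation
#' percentage per well from gated counts, normalizes every plate by its
#' median (control wells excluded), transforms compound wells into z-scores,
#' assesses replicate reproducibility and control-based QC, and calls
#' potential hits with the strict either-replicate rule.
#'
#' @param counts Per-well gated-count data.frame with columns
#'   \code{plate_id}, \code{well_id}, \code{replicate}, \code{role},
#'   \code{compound_id}, \code{n_enucleated}, \code{n_nucleated} (and
#'   optionally \code{n_live}, \code{n_total}).
#' @param scale_method z-score scale convention: \code{"sd"} or \code{"mad"}.
#' @param hit_threshold z threshold for potential hits (default -1).
#' @param min_live Wells with fewer than this many gated erythroid events are
#'   voided (QC flag \code{low_event}; default 500).
#' @param max_dead_fraction Wells whose dead fraction (requires \code{n_live}
#'   and \code{n_total}) exceeds this are flagged \code{high_death} but not
#'   voided: cytotoxicity is itself a readout (default 0.5).
#' @param qc_fail_below Z'-factor below which a plate is flagged failing.
#' @return An object of class \code{"enucleation_screen"} with elements
#'   \code{wells} (per-well results incl. \code{net_enucleation_pct},
#'   \code{centered}, \code{z}, \code{qc_flags}), \code{plates} (per-plate
#'   median/scale/QC), \code{hits} (per-compound hit calls),
#'   \code{replicate_r}, and the call parameters.
#' @export
analyze_screen <- function(counts, scale_method = c("sd", "mad"),
                           hit_threshold = -1, min_live = 500,
                           max_dead_fraction = 0.5, qc_fail_below = 0) {
  scale_method <- match.arg(scale_method)
  req <- c("plate_id", "well_id", "replicate", "role", "compound_id",
           "n_enucleated", "n_nucleated")
  miss <- setdiff(req, names(counts))
  if (length(miss))
    stop("counts is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  wells <- counts
  wells$net_enucleation_pct <- net_enucleation(wells$n_enucleated,
                                               wells$n_nucleated)
  gated <- wells$n_enucleated + wells$n_nucleated
  flags <- ifelse(gated < min_live, "low_event", "")
  if (all(c("n_live", "n_total") %in% names(wells))) {
    dead_frac <- 1 - wells$n_live / wells$n_total
    flags <- paste0(flags, ifelse(!is.na(dead_frac) &
                                    dead_frac > max_dead_fraction,
                                  ";high_death", ""))
  }
  wells$qc_flags <- sub("^;", "", flags)
  voided <- grepl("low_event", wells$qc_flags)
  wells$net_enucleation_pct[voided] <- NA_real_

  wells$centered <- NA_real_
  wells$z <- NA_real_
  plate_rows <- list()
  for (pid in unique(wells$plate_id)) {
    sel <- wells$plate_id == pid
    comp <- sel & wells$role == "compound"
    norm <- normalize_plate(wells$net_enucleation_pct[comp], scale_method)
    wells$centered[comp] <- norm$centered
    wells$z[comp] <- norm$z
    neg <- wells$net_enucleation_pct[sel & wells$role == "neg_control"]
    pos <- wells$net_enucleation_pct[sel & wells$role == "pos_control"]
    qc <- plate_qc(neg, pos, fail_below = qc_fail_below)
    plate_rows[[pid]] <- data.frame(
      plate_id = pid, replicate = wells$replicate[sel][1],
      plate_median = norm$plate_median, scale = norm$scale,
      mean_neg = qc$mean_neg, sd_neg = qc$sd_neg,
      mean_pos = qc$mean_pos, sd_pos = qc$sd_pos,
      z_prime = qc$z_prime, qc_pass = qc$pass,
      stringsAsFactors = FALSE)
  }
  plates <- do.call(rbind, plate_rows); rownames(plates) <- NULL

  comp_wells <- wells[wells$role == "compound", ]
  reps <- sort(unique(comp_wells$replicate))
  if (length(reps) != 2)
    stop("expected exactly 2 replicates, found ", length(reps), call. = FALSE)
  r1 <- comp_wells[comp_wells$replicate == reps[1], ]
  r2 <- comp_wells[comp_wells$replicate == reps[2], ]
  if (!setequal(r1$compound_id, r2$compound_id))
    stop("compound sets differ between replicates", call. = FALSE)
  z1 <- stats::setNames(r1$z, r1$compound_id)
  z2 <- stats::setNames(r2$z, r2$compound_id)[names(z1)]
  raw1 <- stats::setNames(r1$net_enucleation_pct, r1$compound_id)
  raw2 <- stats::setNames(r2$net_enucleation_pct, r2$compound_id)[names(raw1)]
  hits <- call_hits(z1, z2, threshold = hit_threshold)
  rep_r <- replicate_correlation(raw1, raw2)

  structure(list(wells = wells, plates = plates, hits = hits,
                 replicate_r = rep_r,
                 params = list(scale_method = scale_method,
                               hit_threshold = hit_threshold,
                               min_live = min_live,
                               max_dead_fraction = max_dead_fraction,
                               qc_fail_below = qc_fail_below)),
            class = "enucleation_screen")
}

#' @export
print.enucleation_screen <- function(x, ...) {
  n_hit <- sum(x$hits$is_potential_hit, na.rm = TRUE)
  cat("Enucleation screen analysis\n")
  cat(sprintf("  %d compounds on %d plates (%d replicates)\n",
              nrow(x$hits), nrow(x$plates),
              length(unique(x$plates$replicate))))
  cat(sprintf("  replicate Pearson r = %.3f\n", x$replicate_r))
  cat(sprintf("  potential hits (z < %g in either replicate): %d\n",
              x$params$hit_threshold, n_hit))
  invisible(x)
}

#' @export
summary.enucleation_screen <- function(object, ...) {
  x <- object
  cat("Enucleation screen analysis (scale:", x$params$scale_method, ")\n\n")
  cat("Plates:\n")
  print(x$plates[, c("plate_id", "plate_median", "scale", "mean_neg",
                     "mean_pos", "z_prime", "qc_pass")], row.names = FALSE,
        digits = 4)
  cat(sprintf("\nReplicate Pearson r: %.3f\n", x$replicate_r))
  hits <- x$hits[which(x$hits$is_potential_hit), ]
  hits <- hits[order(pmin(hits$z_rep1, hits$z_rep2, na.rm = TRUE)), ]
  cat(sprintf("Potential hits (z < %g in either replicate): %d\n",
              x$params$hit_threshold, nrow(hits)))
  if (nrow(hits)) print(utils::head(hits, 40), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot an analysed screen
#'
#' Replicate-1 versus replicate-2 scatter of raw net-enucleation
#' percentages with potential hits highlighted, plus a bar chart of the hit
#' z-scores.
#'
#' @param x An \code{enucleation_screen}.
#' @param which \code{"scatter"}, \code{"hits"} or \code{"both"}.
#' @param ... Passed to \code{plot}.
#' @export
plot.enucleation_screen <- function(x, which = c("both", "scatter", "hits"),
                                    ...) {
  which <- match.arg(which)
  comp <- x$wells[x$wells$role == "compound", ]
  reps <- sort(unique(comp$replicate))
  r1 <- comp[comp$replicate == reps[1], ]
  r2 <- comp[comp$replicate == reps[2], ]
  v1 <- stats::setNames(r1$net_enucleation_pct, r1$compound_id)
  v2 <- stats::setNames(r2$net_enucleation_pct, r2$compound_id)[names(v1)]
  is_hit <- stats::setNames(x$hits$is_potential_hit,
                            x$hits$compound_id)[names(v1)]
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  }
  if (which %in% c("both", "scatter")) {
    graphics::plot(v1, v2, pch = 16, cex = 0.6,
                   col = ifelse(!is.na(is_hit) & is_hit, "firebrick", "grey40"),
                   xlab = "replicate 1 net enucleation (%)",
                   ylab = "replicate 2 net enucleation (%)",
                   main = sprintf("Replicates (r = %.2f)", x$replicate_r), ...)
    graphics::abline(0, 1, lty = 2, col = "grey60")
  }
  if (which %in% c("both", "hits")) {
    hits <- x$hits[which(x$hits$is_potential_hit), ]
    if (nrow(hits)) {
      zmin <- pmin(hits$z_rep1, hits$z_rep2, na.rm = TRUE)
      ord <- order(zmin)
      graphics::barplot(zmin[ord], names.arg = hits$compound_id[ord],
                        las = 2, cex.names = 0.5, col = "firebrick",
                        ylab = "min replicate z-score",
                        main = sprintf("%d potential hits", nrow(hits)))
      graphics::abline(h = x$params$hit_threshold, lty = 2)
    } else {
      graphics::plot.new(); graphics::title("no potential hits")
    }
  }
  invisible(x)
}

#' Recount potential hits from a transcribed raw screen table
#'
#' Re-derives the potential-hit count from a per-well raw readout table (for
#' example a transcription of a published screen's supplementary raw data):
#' plate-median normalization, z-scores under a given scale convention, and
#' the strict z-below-threshold either-replicate rule.
#'
#' @param raw data.frame with columns \code{plate_id}, \code{replicate},
#'   \code{compound_id}, \code{role} and \code{enucleation_pct} (control rows
#'   optional; only \code{role == "compound"} rows enter the normalization).
#' @param scale_method \code{"sd"} or \code{"mad"}.
#' @param hit_threshold Default -1.
#' @return List with \code{n_hits}, \code{hits} (the call table) and
#'   \code{scale_method}.
#' @export
recount_hits <- function(raw, scale_method = c("sd", "mad"),
                         hit_threshold = -1) {
  scale_method <- match.arg(scale_method)
  req <- c("plate_id", "replicate", "compound_id", "role", "enucleation_pct")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("raw table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  comp <- raw[raw$role == "compound", ]
  comp$z <- NA_real_
  for (pid in unique(comp$plate_id)) {
    sel <- comp$plate_id == pid
    comp$z[sel] <- normalize_plate(comp$enucleation_pct[sel],
                                   scale_method)$z
  }
  reps <- sort(unique(comp$replicate))
  if (length(reps) != 2)
    stop("expected exactly 2 replicates", call. = FALSE)
  z1 <- with(comp[comp$replicate == reps[1], ],
             stats::setNames(z, compound_id))
  z2 <- with(comp[comp$replicate == reps[2], ],
             stats::setNames(z, compound_id))
  hits <- call_hits(z1, z2, threshold = hit_threshold)
  list(n_hits = sum(hits$is_potential_hit, na.rm = TRUE), hits = hits,
       scale_method = scale_method)
}
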