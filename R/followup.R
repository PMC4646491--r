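# Hit characterization: paired-t validation with the star convention,
# concentration-dependence testing, delay-vs-arrest classification, washout
# recovery, and cytospin morphology quantification.

#' Significance stars
#'
#' The standard convention: * p < 0.05, ** p < 0.01, *** p < 0.001,
#' **** p < 0.0001, ns otherwise.
#'
#' @param p p value(s) in [0, 1].
#' @return Character vector of stars.
#' @export
p_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must be in [0, 1]", call. = FALSE)
  ifelse(is.na(p), NA_character_,
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 0.05, "*", "ns")))))
}

#' Paired t-test on per-experiment enucleation percentages
#'
#' Two-sided paired Student's t-test of treated versus control readouts
#' paired by experiment, with the significance-star convention.  Degenerate
#' zero-variance differences do not error (tiny n makes them reachable):
#' p is reported as 1 when the differences are identically zero and as 0
#' otherwise, with \code{degenerate = TRUE}.
#'
#' @param treated,control Equal-length numeric vectors (n >= 2), one value
#'   per paired experiment.
#' @param compound_id Optional label carried through.
#' @return List of class \code{"paired_ttest"}: \code{t}, \code{df}, \code{p},
#'   \code{stars}, \code{mean_diff}, per-arm \code{mean}/\code{sd},
#'   \code{n}, \code{degenerate}.
#' @export
paired_ttest <- function(treated, control, compound_id = NA_character_) {
  if (length(treated) != length(control))
    stop("treated and control must have equal length", call. = FALSE)
  n <- length(treated)
  if (n < 2) stop("need at least 2 paired experiments", call. = FALSE)
  d <- treated - control
  sd_d <- stats::sd(d)
  degenerate <- sd_d == 0
  if (degenerate) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(list(compound_id = compound_id, t = t_stat, df = n - 1, p = p,
                 stars = p_stars(p), mean_diff = mean(d),
                 mean_treated = mean(treated), sd_treated = stats::sd(treated),
                 mean_control = mean(control), sd_control = stats::sd(control),
                 n = n, degenerate = degenerate),
            class = "paired_ttest")
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("Paired t-test%s: t(%d) = %.3f, p = %.4g [%s]%s\n",
              if (!is.na(x$compound_id)) paste0(" (", x$compound_id, ")") else "",
              x$df, x$t, x$p, x$stars,
              if (x$degenerate) " (degenerate: zero-variance differences)" else ""))
  cat(sprintf("  treated %.1f +/- %.1f, control %.1f +/- %.1f (n = %d)\n",
              x$mean_treated, x$sd_treated, x$mean_control, x$sd_control, x$n))
  invisible(x)
}

#' Validate a set of compounds against the vehicle control
#'
#' Runs \code{\link{paired_ttest}} per compound on a long-format validation
#' table.  No multiple-testing correction is applied by default (per-compound
#' stars are reported uncorrected); Benjamini-Hochberg adjusted p values can
#' be added.
#'
#' @param validation data.frame with columns \code{compound_id},
#'   \code{experiment_id}, \code{arm} (\code{"treated"}/\code{"control"}) and
#'   \code{enucleation_pct}.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame, one row per compound, with means, sds, t, p, stars
#'   (and \code{p_adj} when adjusted).
#' @export
validate_compounds <- function(validation, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  req <- c("compound_id", "experiment_id", "arm", "enucleation_pct")
  miss <- setdiff(req, names(validation))
  if (length(miss))
    stop("validation table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- lapply(unique(validation$compound_id), function(cid) {
    v <- validation[validation$compound_id == cid, ]
    tr <- v[v$arm == "treated", ]
    ct <- v[v$arm == "control", ]
    ct <- ct[match(tr$experiment_id, ct$experiment_id), ]
    if (any(is.na(ct$experiment_id)))
      stop("compound ", cid, ": unmatched experiments between arms",
           call. = FALSE)
    tt <- paired_ttest(tr$enucleation_pct, ct$enucleation_pct, cid)
    data.frame(compound_id = cid, n_experiments = tt$n,
               mean_treated = tt$mean_treated, sd_treated = tt$sd_treated,
               mean_control = tt$mean_control, sd_control = tt$sd_control,
               t = tt$t, p = tt$p, stars = tt$stars,
               degenerate = tt$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$stars_adj <- p_stars(out$p_adj)
  }
  out
}

#' Monotone concentration-dependence test
#'
#' One-sided Spearman rank test for a decreasing enucleation response with
#' increasing concentration (no EC50 is fitted; the question is only whether
#' inhibition is concentration dependent).
#'
#' @param concentrations Numeric, length >= 3.
#' @param responses Enucleation percentages, same length (mean per
#'   concentration or per-replicate values with repeated concentrations).
#' @param alpha Verdict level (default 0.05).
#' @return List with \code{rho}, \code{p} (one-sided, decreasing),
#'   \code{concentration_dependent} verdict and \code{alpha}.
#' @export
dose_trend <- function(concentrations, responses, alpha = 0.05) {
  if (length(concentrations) < 3)
    stop("need at least 3 concentrations", call. = FALSE)
  if (length(concentrations) != length(responses))
    stop("concentrations and responses must have equal length", call. = FALSE)
  if (stats::sd(responses) == 0) {
    # constant response carries no trend information
    return(list(rho = 0, p = 1, concentration_dependent = FALSE,
                alpha = alpha))
  }
  ct <- suppressWarnings(
    stats::cor.test(concentrations, responses, method = "spearman",
                    alternative = "less", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value,
       concentration_dependent = ct$p.value < alpha, alpha = alpha)
}

#' Delay-versus-arrest mechanism classification
#'
#' Compares treated and control enucleation at the treatment readout (5 h)
#' and a late timepoint (10 h) with paired t-tests.  Suppression at a
#' timepoint means a significant two-sided paired test with a negative
#' treated-minus-control mean difference.  A compound is called
#' \code{"delay"} when suppressed at 5 h but indistinguishable from control
#' at 10 h (it catches up), \code{"arrest"} when suppressed at both, and
#' \code{"no_effect"} otherwise.
#'
#' @param treated_5h,control_5h,treated_10h,control_10h Per-experiment
#'   enucleation percentages (paired by position, n >= 2 each).
#' @param alpha Significance level per timepoint (default 0.05).
#' @param compound_id Optional label.
#' @return List of class \code{"mechanism_call"}: \code{call},
#'   \code{suppressed_5h}, \code{suppressed_10h}, the two test objects and
#'   the supporting mean deltas.
#' @export
classify_mechanism <- function(treated_5h, control_5h,
                               treated_10h, control_10h,
                               alpha = 0.05, compound_id = NA_character_) {
  t5 <- paired_ttest(treated_5h, control_5h, compound_id)
  t10 <- paired_ttest(treated_10h, control_10h, compound_id)
  sup5 <- t5$p < alpha && t5$mean_diff < 0
  sup10 <- t10$p < alpha && t10$mean_diff < 0
  call <- if (sup5 && sup10) "arrest" else if (sup5) "delay" else "no_effect"
  structure(list(compound_id = compound_id, call = call,
                 suppressed_5h = sup5, suppressed_10h = sup10,
                 delta_5h = t5$mean_diff, delta_10h = t10$mean_diff,
                 test_5h = t5, test_10h = t10, alpha = alpha),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("Mechanism call%s: %s\n",
              if (!is.na(x$compound_id)) paste0(" (", x$compound_id, ")") else "",
              x$call))
  cat(sprintf("  5 h:  delta = %+.1f pp, p = %.4g%s\n", x$delta_5h,
              x$test_5h$p, if (x$suppressed_5h) " (suppressed)" else ""))
  cat(sprintf("  10 h: delta = %+.1f pp, p = %.4g%s\n", x$delta_10h,
              x$test_10h$p, if (x$suppressed_10h) " (suppressed)" else ""))
  invisible(x)
}

#' Washout recovery assessment
#'
#' After washing a reversible inhibitor out, the treated culture should
#' climb back to control levels.  The culture is called recovered when the
#' treated readout comes within \code{margin} percentage points of control
#' by the final post-washout timepoint; the first timepoint at which that
#' happens is reported.
#'
#' @param timepoints Hours after washout, length >= 2, increasing.
#' @param treated,control Enucleation percentages at those timepoints
#'   (means across experiments).
#' @param margin Recovery margin in percentage points (default 10).
#' @return List with \code{recovered}, \code{first_recovery_time}
#'   (\code{NA} if never), and the per-timepoint \code{gap} (control -
#'   treated).
#' @export
washout_recovery <- function(timepoints, treated, control, margin = 10) {
  if (!length(timepoints)) stop("no timepoints", call. = FALSE)
  if (length(timepoints) < 2)
    stop("need at least 2 post-washout timepoints", call. = FALSE)
  if (length(treated) != length(timepoints) ||
      length(control) != length(timepoints))
    stop("treated/control must match timepoints in length", call. = FALSE)
  ord <- order(timepoints)
  timepoints <- timepoints[ord]; treated <- treated[ord]
  control <- control[ord]
  gap <- control - treated
  within <- gap <= margin
  list(recovered = within[length(within)],
       first_recovery_time = if (any(within)) timepoints[which(within)[1]]
                             else NA_real_,
       timepoints = timepoints, gap = gap, margin = margin)
}

#' Cytospin morphology class proportions
#'
#' Per-experiment class proportions, then cross-experiment mean and sd per
#' class.  Classes absent from an experiment count as zero; every experiment
#' must use the same taxonomy (a class seen in any experiment belongs to it).
#'
#' @param counts data.frame with columns \code{experiment_id}, \code{class},
#'   \code{count} (as from \code{\link{simulate_morphology_counts}}).
#' @return List with \code{per_experiment} (proportion matrix, experiments x
#'   classes) and \code{summary} data.frame (\code{class},
#'   \code{mean_proportion}, \code{sd_proportion}; sd is \code{NA} with a
#'   single experiment).
#' @export
morphology_proportions <- function(counts) {
  req <- c("experiment_id", "class", "count")
  miss <- setdiff(req, names(counts))
  if (length(miss))
    stop("counts table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(counts$count < 0)) stop("counts must be non-negative", call. = FALSE)
  tab <- stats::xtabs(count ~ experiment_id + class, data = counts)
  totals <- rowSums(tab)
  if (any(totals == 0)) stop("experiment with zero total count", call. = FALSE)
  props <- sweep(tab, 1, totals, "/")
  sds <- if (nrow(props) > 1) apply(props, 2, stats::sd)
         else rep(NA_real_, ncol(props))
  list(per_experiment = props,
       summary = data.frame(class = colnames(props),
                            mean_proportion = colMeans(props),
                            sd_proportion = sds,
                            stringsAsFactors = FALSE, row.names = NULL))
}
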