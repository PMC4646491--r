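#' Canonical cytometry channel set
#'
#' All event tables in this package share a fixed channel vocabulary:
#' forward and side scatter (\code{FSC}, \code{SSC}), the DNA stain
#' Hoechst 33342 (\code{Hoechst}), the erythroid surface marker
#' \code{Ter119}, the maturation marker \code{CD44}, the dead-cell stain
#' propidium iodide (\code{PI}), the S-phase label \code{BrdU} and total
#' DNA content by 7-AAD (\code{DNA}).
#'
#' Fluorescence channels are represented on a transformed (asinh-like)
#' intensity scale throughout; \code{DNA} is kept linear because DNA
#' content gating (2N vs 4N) is conventionally done on a linear axis.
#'
#' @return Character vector of channel names.
#' @export
es_channels <- function() {
  c("FSC", "SSC", "Hoechst", "Ter119", "CD44", "PI", "BrdU", "DNA")
}

#' Inverse hyperbolic sine transform for cytometry intensities
#'
#' @param x Numeric vector of raw intensities.
#' @param cofactor Positive scale divisor applied before \code{asinh};
#'   150 is a common choice for conventional cytometers.
#' @return Transformed values, same length as \code{x}.
#' @export
asinh_transform <- function(x, cofactor = 150) {
  stopifnot(is.numeric(cofactor), length(cofactor) == 1L, cofactor > 0)
  asinh(x / cofactor)
}

#' Population channel model
#'
#' Describes one simulated cell population as an independent Gaussian per
#' channel on the transformed intensity scale (equivalently, log-normal-like
#' on the raw scale).  No spectral spillover is modelled; gates are defined
#' in the same transformed space.
#'
#' @param name Population label; one of
#'   \code{"orthochromatic_erythroblast"}, \code{"reticulocyte"},
#'   \code{"free_nucleus"}, \code{"late_erythroblast"}, \code{"dead_cell"}.
#' @param channel_params Named list; each element a numeric
#'   \code{c(location, spread)} pair for one channel in
#'   \code{\link{es_channels}}.
#' @return An object of class \code{"population_spec"}.
#' @export
population_spec <- function(name, channel_params) {
  valid <- c("orthochromatic_erythroblast", "reticulocyte", "free_nucleus",
             "late_erythroblast", "dead_cell")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop("unknown population name: ", paste(name, collapse = ", "),
         call. = FALSE)
  }
  missing_ch <- setdiff(es_channels(), names(channel_params))
  if (length(missing_ch)) {
    stop("channel_params missing channels: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  for (ch in es_channels()) {
    p <- channel_params[[ch]]
    if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)) || p[2] <= 0) {
      stop("channel ", ch, ": need finite c(location, spread) with spread > 0",
           call. = FALSE)
    }
  }
  structure(list(name = name, channel_params = channel_params),
            class = "population_spec")
}

#' Default population channel models
#'
#' Locations and spreads (transformed scale except \code{DNA}, linear) chosen
#' so that the biologically ordered relationships hold: reticulocytes are
#' smaller than orthochromatic erythroblasts (lower FSC/SSC), Hoechst-negative
#' and Ter119-positive; free (extruded) nuclei are small, Hoechst-high and by
#' default Ter119-low so they fall outside the erythroid analysis gates;
#' late erythroblasts carry higher CD44; dead cells are PI-positive.
#'
#' @param free_nucleus_ter119_positive If \code{TRUE}, emit extruded nuclei as
#'   Ter119-positive so they enter the nucleated-erythroid analysis gate
#'   (their surface-marker status is not observable from the assay itself;
#'   both conventions are supported).
#' @return Named list of \code{\link{population_spec}} objects.
#' @export
default_population_specs <- function(free_nucleus_ter119_positive = FALSE) {
  base_dna <- c(200, 14)  # 2N modal DNA content, linear scale
  mk <- function(name, FSC, SSC, Hoechst, Ter119, CD44, PI,
                 BrdU = c(1.0, 0.35), DNA = base_dna) {
    population_spec(name, list(FSC = FSC, SSC = SSC, Hoechst = Hoechst,
                               Ter119 = Ter119, CD44 = CD44, PI = PI,
                               BrdU = BrdU, DNA = DNA))
  }
  ter119_nuc <- if (free_nucleus_ter119_positive) c(6.0, 0.35) else c(1.5, 0.35)
  list(
    orthochromatic_erythroblast = mk("orthochromatic_erythroblast",
      FSC = c(4.0, 0.30), SSC = c(4.0, 0.30), Hoechst = c(5.0, 0.35),
      Ter119 = c(6.0, 0.35), CD44 = c(2.0, 0.35), PI = c(1.0, 0.35)),
    reticulocyte = mk("reticulocyte",
      FSC = c(3.2, 0.30), SSC = c(3.2, 0.30), Hoechst = c(1.0, 0.35),
      Ter119 = c(6.0, 0.35), CD44 = c(2.0, 0.35), PI = c(1.0, 0.35)),
    free_nucleus = mk("free_nucleus",
      FSC = c(2.5, 0.30), SSC = c(2.8, 0.30), Hoechst = c(6.0, 0.35),
      Ter119 = ter119_nuc, CD44 = c(1.5, 0.35), PI = c(1.0, 0.35)),
    late_erythroblast = mk("late_erythroblast",
      FSC = c(4.4, 0.30), SSC = c(4.3, 0.30), Hoechst = c(5.0, 0.35),
      Ter119 = c(6.0, 0.35), CD44 = c(4.5, 0.35), PI = c(1.0, 0.35)),
    dead_cell = mk("dead_cell",
      FSC = c(3.6, 0.40), SSC = c(4.2, 0.40), Hoechst = c(5.0, 0.45),
      Ter119 = c(5.5, 0.60), CD44 = c(2.2, 0.60), PI = c(5.0, 0.40))
  )
}

# Internal sanity check on a set of population specs; enforces the ordered
# relationships the simulator relies on.
validate_population_specs <- function(specs) {
  needed <- c("orthochromatic_erythroblast", "reticulocyte", "free_nucleus",
              "dead_cell")
  missing_pop <- setdiff(needed, names(specs))
  if (length(missing_pop)) {
    stop("population specs missing: ", paste(missing_pop, collapse = ", "),
         call. = FALSE)
  }
  loc <- function(pop, ch) specs[[pop]]$channel_params[[ch]][1]
  if (loc("reticulocyte", "FSC") >= loc("orthochromatic_erythroblast", "FSC") ||
      loc("reticulocyte", "SSC") >= loc("orthochromatic_erythroblast", "SSC")) {
    stop("reticulocyte FSC/SSC must lie below orthochromatic locations",
         call. = FALSE)
  }
  if (loc("reticulocyte", "Hoechst") >= loc("orthochromatic_erythroblast", "Hoechst")) {
    stop("reticulocyte Hoechst location must be in the negative regime",
         call. = FALSE)
  }
  if (loc("dead_cell", "PI") <= loc("orthochromatic_erythroblast", "PI")) {
    stop("dead_cell PI location must be in the PI-positive regime",
         call. = FALSE)
  }
  invisible(specs)
}

# Midpoint (transformed scale) between two population locations on a channel;
# the default rule for placing thresholds, since real gate boundaries are
# instrument- and staining-dependent.
midpoint_threshold <- function(specs, channel, pop_lo, pop_hi) {
  (specs[[pop_lo]]$channel_params[[channel]][1] +
   specs[[pop_hi]]$channel_params[[channel]][1]) / 2
}

#' Default gating thresholds derived from the channel model
#'
#' Thresholds sit at the midpoint, on the transformed scale, between the two
#' relevant population locations of the supplied channel model.  All are
#' overridable wherever they are consumed.
#'
#' @param specs Population specs as from \code{\link{default_population_specs}}.
#' @return Named list with \code{pi}, \code{hoechst}, \code{ter119},
#'   \code{cd44}, \code{brdu} and \code{dna_4n} thresholds.
#' @export
default_thresholds <- function(specs = default_population_specs()) {
  validate_population_specs(specs)
  list(
    pi = midpoint_threshold(specs, "PI", "orthochromatic_erythroblast",
                            "dead_cell"),
    hoechst = midpoint_threshold(specs, "Hoechst", "reticulocyte",
                                 "orthochromatic_erythroblast"),
    # negative reference capped at 1.5 so the threshold stays meaningful when
    # free nuclei are configured Ter119-positive
    ter119 = (min(specs$free_nucleus$channel_params$Ter119[1], 1.5) +
              specs$orthochromatic_erythroblast$channel_params$Ter119[1]) / 2,
    cd44 = if ("late_erythroblast" %in% names(specs)) {
      midpoint_threshold(specs, "CD44", "orthochromatic_erythroblast",
                         "late_erythroblast")
    } else 3.25,
    brdu = 2.5,
    # standard practice: 4N cut at 1.5x the 2N modal DNA signal (linear)
    dna_4n = 1.5 * specs$orthochromatic_erythroblast$channel_params$DNA[1]
  )
}
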