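# Gates and gating hierarchies over event tables.
#
# Gates are evaluated on transformed intensities (the simulator already emits
# asinh-scale values, so the default transform is the identity; an asinh
# transform with per-channel cofactor is available for raw-scale data).
# Rectangles are half-open, [min, max), so adjacent gates partition without
# double counting; polygon membership uses the even-odd rule with boundary
# points counted as inside.

#' Construct a rectangle gate
#'
#' @param name Gate name.
#' @param channel_x,channel_y Channel names; omit \code{channel_y} (NULL) for
#'   a 1-D threshold gate.
#' @param xlim,ylim Numeric \code{c(min, max)}; use \code{-Inf}/\code{Inf}
#'   for unbounded sides.  Membership is \code{min <= value < max}.
#' @param transform \code{"identity"} (default) or \code{"asinh"}.
#' @param cofactor asinh cofactor if \code{transform = "asinh"}.
#' @return An object of class \code{"gate"}.
#' @export
rect_gate <- function(name, channel_x, xlim, channel_y = NULL, ylim = NULL,
                      transform = c("identity", "asinh"), cofactor = 150) {
  transform <- match.arg(transform)
  check_lim <- function(lim, lab) {
    if (!is.numeric(lim) || length(lim) != 2L || !(lim[1] < lim[2]))
      stop(lab, " must be c(min, max) with min < max", call. = FALSE)
  }
  check_lim(xlim, "xlim")
  if (!is.null(channel_y)) check_lim(ylim, "ylim")
  structure(list(name = name, type = "rect",
                 channel_x = channel_x, channel_y = channel_y,
                 xlim = xlim, ylim = ylim,
                 transform = transform, cofactor = cofactor),
            class = "gate")
}

#' Construct a polygon gate
#'
#' @param name Gate name.
#' @param channel_x,channel_y Channel names.
#' @param vertices Two-column numeric matrix (x, y) of at least 3
#'   non-collinear vertices, in transformed space.
#' @param transform,cofactor As in \code{\link{rect_gate}}.
#' @return An object of class \code{"gate"}.
#' @export
polygon_gate <- function(name, channel_x, channel_y, vertices,
                         transform = c("identity", "asinh"), cofactor = 150) {
  transform <- match.arg(transform)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("vertices must be an n x 2 matrix with n >= 3", call. = FALSE)
  # non-collinearity: every vertex against the line through the first two
  v <- vertices
  cross <- (v[2, 1] - v[1, 1]) * (v[, 2] - v[1, 2]) -
           (v[2, 2] - v[1, 2]) * (v[, 1] - v[1, 1])
  if (all(abs(cross) < 1e-12))
    stop("polygon vertices are collinear", call. = FALSE)
  structure(list(name = name, type = "polygon",
                 channel_x = channel_x, channel_y = channel_y,
                 vertices = vertices,
                 transform = transform, cofactor = cofactor),
            class = "gate")
}

apply_gate_transform <- function(x, gate) {
  if (gate$transform == "asinh") asinh_transform(x, gate$cofactor) else x
}

# Vectorized even-odd point-in-polygon with boundary points inside.
points_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    # boundary: point collinear with segment and within its bounding box
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    on_seg <- abs(cross) < 1e-12 &
      px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | on_seg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Apply a gate to an event table
#'
#' @param events Event data.frame containing the gate's channels.
#' @param gate A \code{\link{rect_gate}} or \code{\link{polygon_gate}}.
#' @return List with \code{members} (the subset data.frame), \code{count},
#'   and \code{keep} (logical membership vector).
#' @export
apply_gate <- function(events, gate) {
  if (!inherits(gate, "gate")) stop("gate must be a gate object", call. = FALSE)
  chans <- c(gate$channel_x, gate$channel_y)
  miss <- setdiff(chans, names(events))
  if (length(miss))
    stop("missing channel(s) in event table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(events)) {
    return(list(members = events, count = 0L, keep = logical(0)))
  }
  x <- apply_gate_transform(events[[gate$channel_x]], gate)
  if (gate$type == "rect") {
    keep <- x >= gate$xlim[1] & x < gate$xlim[2]
    if (!is.null(gate$channel_y)) {
      y <- apply_gate_transform(events[[gate$channel_y]], gate)
      keep <- keep & y >= gate$ylim[1] & y < gate$ylim[2]
    }
  } else {
    y <- apply_gate_transform(events[[gate$channel_y]], gate)
    keep <- points_in_polygon(x, y, gate$vertices)
  }
  list(members = events[keep, , drop = FALSE], count = sum(keep), keep = keep)
}

#' Live-cell gate (PI exclusion)
#'
#' Dead and dying cells take up propidium iodide; events at or above the PI
#' threshold are excluded.  The reported dead fraction doubles as a
#' cytotoxicity readout, distinguishing blocked enucleation from cell death.
#'
#' @param events Event data.frame with a \code{PI} channel.
#' @param threshold PI threshold on the transformed scale; default from
#'   \code{\link{default_thresholds}}.
#' @return List with \code{live} (PI-negative subset), \code{n_live},
#'   \code{n_dead} and \code{dead_fraction}.
#' @export
gate_live <- function(events, threshold = default_thresholds()$pi) {
  if (!("PI" %in% names(events)))
    stop("missing channel(s) in event table: PI", call. = FALSE)
  g <- rect_gate("live", "PI", c(-Inf, threshold))
  res <- apply_gate(events, g)
  n <- nrow(events)
  list(live = res$members, n_live = res$count, n_dead = n - res$count,
       dead_fraction = if (n > 0) (n - res$count) / n else NA_real_)
}

#' Classify enucleation among live events
#'
#' Counts enucleated cells (Ter119-positive, Hoechst-negative reticulocytes)
#' and nucleated erythroblasts (Ter119-positive, Hoechst-positive).
#' Ter119-negative events (debris, extruded nuclei under the default channel
#' model) are counted in neither class.
#'
#' @param live_events Live-gated event data.frame with \code{Ter119} and
#'   \code{Hoechst} channels.
#' @param ter119_threshold,hoechst_threshold Thresholds on the transformed
#'   scale; defaults from \code{\link{default_thresholds}}.
#' @return List with \code{n_enucleated}, \code{n_nucleated} and the logical
#'   index vectors \code{is_enucleated}, \code{is_nucleated}.
#' @export
classify_enucleation <- function(live_events,
                                 ter119_threshold = default_thresholds()$ter119,
                                 hoechst_threshold = default_thresholds()$hoechst) {
  miss <- setdiff(c("Ter119", "Hoechst"), names(live_events))
  if (length(miss))
    stop("missing channel(s) in event table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ter_pos <- live_events$Ter119 >= ter119_threshold
  hoe_neg <- live_events$Hoechst < hoechst_threshold
  is_enuc <- ter_pos & hoe_neg
  is_nuc <- ter_pos & !hoe_neg
  list(n_enucleated = sum(is_enuc), n_nucleated = sum(is_nuc),
       is_enucleated = is_enuc, is_nucleated = is_nuc)
}

#' Orthochromatic-erythroblast sort gate
#'
#' Reproduces the sort logic used to enrich cells poised to enucleate:
#' PI-negative (live), Hoechst-positive (nucleated; all enucleated cells
#' excluded from the sort), Ter119-high and CD44-low.  The adjacent
#' "late erythroblast" gate (same Ter119 regime, higher CD44) is also
#' reported for comparison.
#'
#' @param events Event data.frame with Ter119, CD44, Hoechst and PI channels.
#' @param thresholds Threshold list as from \code{\link{default_thresholds}}.
#' @param cd44_high_max Upper CD44 bound for the late-erythroblast gate
#'   (default \code{Inf}).
#' @return List with \code{sorted} (orthochromatic subset), \code{n_sorted},
#'   \code{late} (late-erythroblast subset), \code{n_late} and \code{n_input}.
#' @export
gate_orthochromatic_sort <- function(events,
                                     thresholds = default_thresholds(),
                                     cd44_high_max = Inf) {
  miss <- setdiff(c("Ter119", "CD44", "Hoechst", "PI"), names(events))
  if (length(miss))
    stop("missing channel(s) in event table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  live <- gate_live(events, thresholds$pi)$live
  nucleated <- if (nrow(live))
    live[live$Hoechst >= thresholds$hoechst, , drop = FALSE] else live
  ter_hi <- nucleated$Ter119 >= thresholds$ter119
  ortho <- ter_hi & nucleated$CD44 < thresholds$cd44
  late <- ter_hi & nucleated$CD44 >= thresholds$cd44 &
    nucleated$CD44 < cd44_high_max
  list(sorted = nucleated[ortho, , drop = FALSE], n_sorted = sum(ortho),
       late = nucleated[late, , drop = FALSE], n_late = sum(late),
       n_input = nrow(events))
}

#' Cell-cycle fractions from BrdU / DNA staining
#'
#' S-phase cells are BrdU-positive; BrdU-negative cells are split by DNA
#' content into G0/G1 (2N, below the 4N threshold) and G2/M (4N).  The
#' non-proliferating fraction is the BrdU-negative total (G0/G1 + G2/M).
#'
#' @param events Event data.frame with \code{BrdU} and \code{DNA} channels.
#' @param brdu_threshold BrdU positivity threshold (transformed scale).
#' @param dna_4n_threshold Linear DNA threshold separating 2N from 4N;
#'   default 1.5x the 2N modal signal.
#' @return List of fractions \code{S}, \code{G0G1}, \code{G2M} (summing to 1
#'   over gated events) and \code{non_proliferating = G0G1 + G2M}, plus
#'   \code{n}.
#' @export
cellcycle_fractions <- function(events,
                                brdu_threshold = default_thresholds()$brdu,
                                dna_4n_threshold = default_thresholds()$dna_4n) {
  miss <- setdiff(c("BrdU", "DNA"), names(events))
  if (length(miss))
    stop("missing channel(s) in event table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(events)
  if (!n) stop("no events to gate", call. = FALSE)
  s <- events$BrdU >= brdu_threshold
  g2m <- !s & events$DNA >= dna_4n_threshold
  g0g1 <- !s & !g2m
  list(S = mean(s), G0G1 = mean(g0g1), G2M = mean(g2m),
       non_proliferating = mean(!s), n = n)
}

#' Gating hierarchy
#'
#' An ordered set of gates forming a tree rooted at "all events"; each gate
#' is evaluated within its parent's population.
#'
#' @param gates List of \code{gate} objects.
#' @param parents Character vector, same length: parent gate name or
#'   \code{"root"}.
#' @return An object of class \code{"gating_hierarchy"}.
#' @export
gating_hierarchy <- function(gates, parents) {
  nms <- vapply(gates, `[[`, character(1), "name")
  if (length(gates) != length(parents))
    stop("gates and parents must have equal length", call. = FALSE)
  if (anyDuplicated(nms)) stop("duplicate gate names", call. = FALSE)
  for (i in seq_along(parents)) {
    p <- parents[i]
    if (p != "root" && !(p %in% nms[seq_len(i - 1L)]))
      stop("parent '", p, "' of gate '", nms[i],
           "' must appear earlier or be 'root'", call. = FALSE)
  }
  structure(list(gates = gates, names = nms, parents = parents),
            class = "gating_hierarchy")
}

#' Apply a gating hierarchy to an event table
#'
#' @param events Event data.frame.
#' @param hierarchy A \code{\link{gating_hierarchy}}.
#' @return data.frame of population counts: \code{node}, \code{parent},
#'   \code{count}, \code{fraction_of_parent}.
#' @export
apply_hierarchy <- function(events, hierarchy) {
  keep <- list(root = rep(TRUE, nrow(events)))
  counts <- data.frame(node = "root", parent = NA_character_,
                       count = nrow(events), fraction_of_parent = NA_real_,
                       stringsAsFactors = FALSE)
  for (i in seq_along(hierarchy$gates)) {
    g <- hierarchy$gates[[i]]
    parent_keep <- keep[[hierarchy$parents[i]]]
    res <- apply_gate(events, g)
    this_keep <- res$keep & parent_keep
    keep[[g$name]] <- this_keep
    pc <- sum(parent_keep)
    counts <- rbind(counts, data.frame(
      node = g$name, parent = hierarchy$parents[i],
      count = sum(this_keep),
      fraction_of_parent = if (pc > 0) sum(this_keep) / pc else NA_real_,
      stringsAsFactors = FALSE))
  }
  counts
}
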