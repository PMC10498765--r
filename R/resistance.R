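#' Blood rheology
#'
#' Blood is modelled as a Newtonian fluid in steady laminar flow. Defaults:
#' dynamic viscosity 0.0035 Pa s, density 1050 kg/m^3.
#'
#' @param viscosity dynamic viscosity, Pa s.
#' @param density mass density, kg/m^3.
#' @return an object of class `blood_properties`.
#' @export
blood_properties <- function(viscosity = 0.0035, density = 1050) {
  stopifnot(viscosity > 0, density > 0)
  structure(list(viscosity = viscosity, density = density),
            class = "blood_properties")
}

#' Poiseuille resistance of a segment
#'
#' The hydraulic resistance of a branch under steady laminar flow,
#' `R = 8 pi mu L / A^2` with `A` the mean of the end cross-sections
#' (equivalently `128 mu L / (pi d^4)` for a uniform tube). When the
#' segment carries a diameter profile the resistance is integrated
#' piecewise over the profile intervals, `R = sum_k 8 pi mu dL_k / A_k^2`
#' with `A_k` the two-point mean area of interval `k`; for a profile with
#' no interior points this reduces exactly to the closed form.
#'
#' @param seg a [segment()].
#' @param blood a [blood_properties()].
#' @return resistance, Pa s/m^3.
#' @export
#' @examples
#' segment_resistance(segment("s", 0.01, 0.003, 0.003))  # 1.7605e7
segment_resistance <- function(seg, blood = blood_properties()) {
  .piecewise_resistance(segment_intervals(seg), blood)
}

.piecewise_resistance <- function(iv, blood) {
  a <- (pi * iv$d0^2 / 4 + pi * iv$d1^2 / 4) / 2
  if (any(a <= 0))
    stop("singular geometry: zero cross-section area", call. = FALSE)
  sum(8 * pi * blood$viscosity * (iv$x1 - iv$x0) / a^2)
}

#' Effective resistance of a stenosed segment
#'
#' The stenosis-modified resistance of a branch. In the default linear
#' model the lesion's narrowed diameter (`ref_diameter * (1 - severity)`)
#' overrides the profile over the lesion span and the Poiseuille density is
#' integrated piecewise, so the resistance is flow-independent and the
#' whole network stays linear. The optional nonlinear model adds a
#' Borda-Carnot-type expansion loss at the lesion exit,
#' `dP_t = K_t * rho / (2 A_0^2) * (A_0/A_s - 1)^2 * Q^2` with `K_t = 1.52`
#' (classical empirical coefficient), returned as the equivalent resistance
#' `dP_t / Q`. This term stands in for the extra pressure loss that a
#' three-dimensional flow field develops at an abrupt lumen expansion,
#' which a pure Poiseuille line model does not see.
#'
#' @param seg a [segment()].
#' @param stenoses stenosis data frame (rows not on `seg` are ignored);
#'   `NULL` for a healthy segment.
#' @param blood a [blood_properties()].
#' @param Q through-flow in m^3/s, or `NULL` (default) for the linear model.
#' @param k_t empirical expansion-loss coefficient (default 1.52).
#' @return effective resistance, Pa s/m^3.
#' @export
stenosis_effective_resistance <- function(seg, stenoses = NULL,
                                          blood = blood_properties(),
                                          Q = NULL, k_t = 1.52) {
  st <- stenoses
  if (!is.null(st) && nrow(st)) {
    st <- st[st$segment == seg$id, , drop = FALSE]
    if (any(st$severity >= 1 | st$ref_diameter * (1 - st$severity) <= 0))
      stop("singular geometry: stenosis closes the lumen on segment '",
           seg$id, "'", call. = FALSE)
  }
  r <- .piecewise_resistance(segment_intervals(seg, st), blood)
  if (!is.null(Q) && !is.null(st) && nrow(st)) {
    for (k in seq_len(nrow(st))) {
      a0 <- pi * st$ref_diameter[k]^2 / 4
      as <- pi * (st$ref_diameter[k] * (1 - st$severity[k]))^2 / 4
      dp <- k_t * blood$density / (2 * a0^2) * (a0 / as - 1)^2 * Q^2
      r <- r + if (Q > 0) dp / Q else 0
    }
  }
  r
}

#' Calibrate microcirculation resistance at rest
#'
#' Identifies the lumped resistance of the distal vascular bed behind every
#' epicardial outlet from the resting state. Walking each root-to-outlet
#' path stepwise from the proximal to the distal end, the Ohm-analogy
#' pressure drop `dP = R_seg * Q_seg` is subtracted from the resting mean
#' blood pressure (with `Q_seg` the conserved through-flow, i.e. the sum of
#' resting flows of all outlets under that segment). The remaining pressure
#' at the outlet is the microcirculation inlet pressure `P_i`, and the
#' resting microcirculation resistance is `R_i = P_i / Q_i` (venous
#' pressure taken as zero). Healthy geometry is used throughout: minimal
#' microvascular resistance does not depend on epicardial stenosis
#' severity, so calibration must not either.
#'
#' @param tree a [coronary_tree()].
#' @param p_mbp resting mean blood pressure, mmHg.
#' @param resting a resting `flow_assignment` from [distribute_flow()].
#' @param blood a [blood_properties()].
#' @return a `resistance_map`: list with named numeric vectors
#'   `epicardial` (per segment, healthy, Pa s/m^3), `micro_rest` and
#'   `micro_hyper` (`NULL` until [hyperemia_resistance()] is applied), and
#'   `p_outlet_rest` (microcirculation inlet pressures, Pa).
#' @export
calibrate_microcirculation <- function(tree, p_mbp, resting,
                                       blood = blood_properties()) {
  p0 <- mmHg_to_Pa(p_mbp)
  q <- resting$outflows
  if (!all(tree$outlets %in% names(q)))
    stop("resting flows missing for outlet(s): ",
         paste(setdiff(tree$outlets, names(q)), collapse = ", "),
         call. = FALSE)
  ids <- names(tree$segments)
  r_seg <- vapply(tree$segments, segment_resistance, numeric(1),
                  blood = blood)
  q_seg <- vapply(ids, function(i) sum(q[descendant_outlets(tree, i)]),
                  numeric(1))
  # distal-node pressure of every segment, top-down
  p_node <- setNames(numeric(length(ids)), ids)
  walk <- function(id, p_in) {
    p_out <- p_in - r_seg[[id]] * q_seg[[id]]
    p_node[[id]] <<- p_out
    for (ch in tree$children[[id]]) walk(ch, p_out)
  }
  walk(tree$root, p0)
  p_i <- p_node[tree$outlets]
  bad <- names(p_i)[p_i <= 0]
  if (length(bad))
    stop("calibration failed: nonpositive microcirculation inlet pressure ",
         "at outlet(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(epicardial = r_seg,
                 micro_rest = p_i / q[tree$outlets],
                 micro_hyper = NULL,
                 p_outlet_rest = p_i),
            class = "resistance_map")
}
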