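#' Solver settings for hyperemic flow identification
#'
#' @param alpha under-relaxation factor in (0, 1] (default 0.3). When
#'   `adaptive = TRUE` the factor is halved -- and the iteration restarted
#'   from the best iterate seen -- whenever the residual blows past 4x the
#'   best value or stops improving for 20 iterations, which keeps stiff
#'   networks (severe proximal stenoses) from oscillating or diverging.
#' @param tol dimensionless residual tolerance (default 1e-4). The residual
#'   is the worst-outlet mismatch between the network outlet pressure and
#'   the microcirculation pressure demand, normalized by the inlet
#'   pressure: `max_j |P_j - Q_j R_j| / P0`.
#' @param max_iter iteration cap (default 10000).
#' @param init initialization of the outlet flows: `"resting"` (default;
#'   start from the resting assignment, guaranteed positive and close to
#'   the solution) or `"series"` (per-outlet Ohm estimate
#'   `P0 / (R_j + sum of healthy path resistances)`, used when no resting
#'   assignment is supplied).
#' @param literal_relaxation logical; if `TRUE` the outlet pressures are advanced
#'   by the literal printed relaxation update
#'   `P_new = P_old + alpha (P0 - P_old + Q_new R_j)` instead of being
#'   re-evaluated through the network solve. The literal update's fixed
#'   point (`P = P0 + Q R_j`) is inconsistent with the flow update's fixed
#'   point and with the stated matching condition, so this mode exists for
#'   comparison only. See the package vignette.
#' @param adaptive logical; enable the divergence-triggered halving of
#'   `alpha` described above.
#' @return an object of class `solver_settings`.
#' @export
solver_settings <- function(alpha = 0.3, tol = 1e-4, max_iter = 10000L,
                            init = c("resting", "series"),
                            literal_relaxation = FALSE, adaptive = TRUE) {
  stopifnot(alpha > 0, alpha <= 1, tol > 0, max_iter >= 1)
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
                 init = match.arg(init), literal_relaxation = literal_relaxation,
                 adaptive = adaptive),
            class = "solver_settings")
}

# Effective epicardial resistance of every segment: stenosis overrides
# included; in nonlinear mode the expansion-loss term uses the segment's
# through-flow.
.effective_resistances <- function(tree, q_seg, blood,
                                   stenosis_model = c("linear", "nonlinear"),
                                   k_t = 1.52) {
  stenosis_model <- match.arg(stenosis_model)
  ids <- names(tree$segments)
  vapply(ids, function(i)
    stenosis_effective_resistance(
      tree$segments[[i]], tree$stenoses, blood,
      Q = if (stenosis_model == "nonlinear") q_seg[[i]] else NULL,
      k_t = k_t),
    numeric(1))
}

.through_flows <- function(tree, outlet_flows) {
  vapply(names(tree$segments),
         function(i) sum(outlet_flows[descendant_outlets(tree, i)]),
         numeric(1))
}

#' Forward network pressure solve
#'
#' Given positive outlet flows, computes the steady pressure field of the
#' resistive network: segment through-flows follow from mass conservation
#' (each segment carries the sum of its descendant outlet flows), and the
#' pressure at a segment's distal node is the inlet pressure minus the
#' accumulated `R_eff * Q` drops along its root path. Stenosis overrides
#' are included in `R_eff`.
#'
#' @param tree a [coronary_tree()].
#' @param outlet_flows named numeric, m^3/s per outlet id.
#' @param p0 inlet pressure, Pa.
#' @param blood a [blood_properties()].
#' @param stenosis_model `"linear"` (flow-independent resistances, default)
#'   or `"nonlinear"` (adds the expansion-loss term).
#' @param k_t expansion-loss coefficient for the nonlinear model.
#' @param r_eff optional precomputed effective segment resistances (linear
#'   model only; an internal fast path for iterative callers).
#' @return a `network_state`: list with `p_in` (Pa), `p_node` (named,
#'   pressure at each segment's distal node, Pa), `q_seg` (through-flows),
#'   `r_eff` (effective segment resistances), plus the model arguments.
#' @export
network_pressures <- function(tree, outlet_flows, p0,
                              blood = blood_properties(),
                              stenosis_model = c("linear", "nonlinear"),
                              k_t = 1.52, r_eff = NULL) {
  stenosis_model <- match.arg(stenosis_model)
  q_seg <- .through_flows(tree, outlet_flows)
  # linear resistances are flow-independent and may be passed in precomputed
  if (is.null(r_eff))
    r_eff <- .effective_resistances(tree, q_seg, blood, stenosis_model, k_t)
  ids <- names(tree$segments)
  p_node <- setNames(numeric(length(ids)), ids)
  walk <- function(id, p_up) {
    p <- p_up - r_eff[[id]] * q_seg[[id]]
    p_node[[id]] <<- p
    for (ch in tree$children[[id]]) walk(ch, p)
  }
  walk(tree$root, p0)
  structure(list(p_in = p0, p_node = p_node, q_seg = q_seg, r_eff = r_eff,
                 blood = blood, stenosis_model = stenosis_model, k_t = k_t),
            class = "network_state")
}

#' Pressure at an arbitrary arc position
#'
#' Evaluates the pressure of a solved [network_pressures()] state at arc
#' position `x` (metres from the proximal end) on a given segment, by
#' partial piecewise-Poiseuille integration of the stenosis-modified
#' profile. In the nonlinear model the lesion expansion loss is applied at
#' the lesion's distal shoulder.
#'
#' @param tree a [coronary_tree()].
#' @param state a `network_state` from [network_pressures()].
#' @param seg_id segment id.
#' @param x arc position in `[0, L]`, metres.
#' @return pressure, Pa.
#' @export
arc_pressure <- function(tree, state, seg_id, x) {
  seg <- tree$segments[[seg_id]]
  if (is.null(seg)) stop("unknown segment id: '", seg_id, "'", call. = FALSE)
  if (x < -1e-12 || x > seg$length + 1e-12)
    stop("arc position out of range for segment '", seg_id, "'",
         call. = FALSE)
  x <- min(max(x, 0), seg$length)
  p_up <- if (is.na(seg$parent)) state$p_in else state$p_node[[seg$parent]]
  q <- state$q_seg[[seg_id]]
  st <- tree$stenoses[tree$stenoses$segment == seg_id, , drop = FALSE]
  iv <- segment_intervals(seg, st)
  a <- (pi * iv$d0^2 / 4 + pi * iv$d1^2 / 4) / 2
  dl <- pmin(pmax(x - iv$x0, 0), iv$x1 - iv$x0)
  r_partial <- sum(8 * pi * state$blood$viscosity * dl / a^2)
  if (state$stenosis_model == "nonlinear" && nrow(st)) {
    for (k in seq_len(nrow(st))) {
      if (x >= st$start[k] + st$length[k] - 1e-15 && q > 0) {
        a0 <- pi * st$ref_diameter[k]^2 / 4
        as <- pi * (st$ref_diameter[k] * (1 - st$severity[k]))^2 / 4
        r_partial <- r_partial +
          state$k_t * state$blood$density / (2 * a0^2) *
            (a0 / as - 1)^2 * q
      }
    }
  }
  p_up - r_partial * q
}

#' Identify hyperemic outlet flows by under-relaxed fixed-point iteration
#'
#' The hyperemic working point of the coronary network couples three
#' quantities: the stenotic (epicardial) resistance seen by each outlet,
#' the calibrated microcirculation resistance behind it, and the hyperemic
#' inlet pressure. The iteration alternates (a) a relaxed flow update from
#' the microcirculation's Ohm demand,
#' `Q_j <- (1 - alpha) Q_j + alpha P_j / R_j`, with (b) re-evaluation of
#' the outlet pressures `P_j` through the forward network solve at the new
#' flows. It stops when the epicardial pressure drops plus the
#' microcirculation demand match the inlet pressure at every outlet:
#' `max_j |P_j - Q_j R_j| / P0 <= tol`. At that point each outlet satisfies
#' `Q_j R_j + sum(path drops at Q) = P0`.
#'
#' Negative intermediate flows (possible for extreme stenoses at large
#' `alpha`) are clipped to a small positive value with a warning; outlet
#' order is deterministic (sorted ids) so runs are bit-reproducible.
#'
#' @param tree a [coronary_tree()].
#' @param p0 hyperemic inlet pressure, Pa.
#' @param r_j named numeric, hyperemic microcirculation resistance per
#'   outlet, Pa s/m^3.
#' @param settings a [solver_settings()].
#' @param blood a [blood_properties()].
#' @param init_flows optional named numeric of starting outlet flows
#'   (m^3/s), typically the resting assignment; required when
#'   `settings$init == "resting"`.
#' @param stenosis_model,k_t passed to [network_pressures()].
#' @return list with `flows` (a hyperemic `flow_assignment`), `state` (the
#'   final `network_state`) and `report` (a `convergence_report`: list of
#'   `iterations`, `residual`, `history`, `converged`, `alpha_final`).
#' @export
identify_hyperemic_flows <- function(tree, p0, r_j,
                                     settings = solver_settings(),
                                     blood = blood_properties(),
                                     init_flows = NULL,
                                     stenosis_model = c("linear",
                                                        "nonlinear"),
                                     k_t = 1.52) {
  stenosis_model <- match.arg(stenosis_model)
  outlets <- tree$outlets
  if (!all(outlets %in% names(r_j)))
    stop("r_j missing for outlet(s): ",
         paste(setdiff(outlets, names(r_j)), collapse = ", "), call. = FALSE)
  r_j <- r_j[outlets]
  if (settings$init == "resting" && !is.null(init_flows)) {
    q <- init_flows[outlets]
  } else {
    r_path <- vapply(outlets, function(o)
      sum(vapply(path_to_root(tree, o), function(i)
        segment_resistance(tree$segments[[i]], blood), numeric(1))),
      numeric(1))
    q <- p0 / (r_j + r_path)
  }
  alpha <- settings$alpha
  history <- numeric(0)
  clipped <- FALSE
  converged <- FALSE
  r_eff0 <- if (stenosis_model == "linear")
    .effective_resistances(tree, NULL, blood, "linear", k_t) else NULL

  # precomputed network topology for the iteration hot path: preorder ids
  # (parents first), parent indices, and the segment-by-outlet incidence
  # used to accumulate through-flows
  ids <- names(tree$segments)
  topo <- character(0)
  stack <- tree$root
  while (length(stack)) {
    id <- stack[1L]
    stack <- stack[-1L]
    topo <- c(topo, id)
    stack <- c(tree$children[[id]], stack)
  }
  par_idx <- match(vapply(topo, function(i) tree$segments[[i]]$parent,
                          character(1)), topo)
  inc <- matrix(0, length(topo), length(outlets),
                dimnames = list(topo, outlets))
  for (j in seq_along(outlets))
    inc[path_to_root(tree, outlets[j]), j] <- 1
  out_idx <- match(outlets, topo)

  # outlet pressures for candidate flows (vectorized forward pass)
  fwd_p <- function(qq) {
    q_seg <- as.vector(inc %*% qq)
    r <- if (is.null(r_eff0))
      .effective_resistances(tree, setNames(q_seg, topo)[ids], blood,
                             stenosis_model, k_t)[topo]
    else r_eff0[topo]
    drop <- r * q_seg
    p <- numeric(length(topo))
    for (i in seq_along(topo))
      p[i] <- (if (is.na(par_idx[i])) p0 else p[par_idx[i]]) - drop[i]
    p[out_idx]
  }

  if (settings$literal_relaxation) {
    # literal printed relaxation of the outlet pressures; kept for
    # comparison -- its fixed point P = P0 + Q R_j is inconsistent with the
    # matching condition, so this mode does not generally converge to it
    p <- fwd_p(q)
    for (it in seq_len(settings$max_iter)) {
      q_new <- (1 - alpha) * q + alpha * p / r_j
      if (any(q_new <= 0)) { clipped <- TRUE; q_new <- pmax(q_new, 1e-15) }
      p <- p + alpha * (p0 - p + q_new * r_j)
      q <- q_new
      res <- max(abs(p - q * r_j)) / p0
      history <- c(history, res)
      if (res <= settings$tol) { converged <- TRUE; break }
    }
  } else {
    p <- fwd_p(q)
    best_res <- Inf
    best_q <- q
    stall <- 0L
    for (it in seq_len(settings$max_iter)) {
      res <- max(abs(p - q * r_j)) / p0
      if (!is.finite(res)) res <- Inf
      history <- c(history, res)
      if (res <= settings$tol) { converged <- TRUE; break }
      if (is.infinite(res) && !settings$adaptive) break
      if (res < best_res) {
        best_res <- res
        best_q <- q
        stall <- 0L
      } else if (settings$adaptive) {
        stall <- stall + 1L
        if (res > 4 * best_res || stall >= 20L) {
          # diverging or oscillating at this relaxation factor: halve it
          # and restart from the best iterate seen so far
          alpha <- alpha / 2
          q <- best_q
          p <- fwd_p(q)
          stall <- 0L
          next
        }
      }
      q <- (1 - alpha) * q + alpha * p / r_j
      if (any(q <= 0)) { clipped <- TRUE; q <- pmax(q, 1e-15) }
      p <- fwd_p(q)
    }
  }
  state <- network_pressures(tree, q, p0, blood, stenosis_model, k_t,
                             r_eff = r_eff0)
  if (clipped)
    warning("negative intermediate outlet flow clipped to epsilon",
            call. = FALSE)
  report <- structure(
    list(iterations = length(history),
         residual = history[length(history)],
         history = history, converged = converged, alpha_final = alpha),
    class = "convergence_report")
  list(flows = flow_assignment(sum(q), q, "hyperemic"),
       state = state, report = report)
}

#' Direct linear solve of the hyperemic network
#'
#' For the linear stenosis model every resistance is flow-independent, so
#' the coupled outlet flows satisfy an exact linear system: for each outlet
#' `j`, the path drops plus the microcirculation demand equal the inlet
#' pressure,
#' `sum_{s in path(j)} R_s (sum_{k under s} Q_k) + R_j Q_j = P0`.
#' Equivalently `(M + diag(R_j)) Q = P0 1` where `M[j, k]` is the summed
#' resistance of the shared root path of outlets `j` and `k`. This is the
#' independent oracle for [identify_hyperemic_flows()].
#'
#' @inheritParams identify_hyperemic_flows
#' @return a hyperemic `flow_assignment`.
#' @export
direct_solve_linear <- function(tree, p0, r_j,
                                blood = blood_properties()) {
  outlets <- tree$outlets
  r_j <- r_j[outlets]
  r_eff <- .effective_resistances(tree, NULL, blood, "linear")
  paths <- lapply(outlets, path_to_root, tree = tree)
  n <- length(outlets)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    shared <- intersect(paths[[j]], paths[[k]])
    M[j, k] <- sum(r_eff[shared])
  }
  M <- M + diag(r_j, n)
  q <- tryCatch(solve(M, rep(p0, n)),
                error = function(e)
                  stop("singular network system: ", conditionMessage(e),
                       call. = FALSE))
  flow_assignment(sum(q), setNames(q, outlets), "hyperemic")
}
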