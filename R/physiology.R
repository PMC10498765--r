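#' Patient physiology
#'
#' Scalar physiological inputs for one patient. Systolic/diastolic pressure
#' and cardiac output drive the boundary-condition identification; heart
#' rate and myocardial mass are required only by the diameter-flow
#' comparator [ffr_d()].
#'
#' @param p_sp systolic blood pressure, mmHg.
#' @param p_dp diastolic blood pressure, mmHg.
#' @param cardiac_output cardiac output, L/min.
#' @param heart_rate beats per minute (optional).
#' @param myocardial_mass left-ventricular myocardial mass, g (optional).
#' @return an object of class `patient_physiology`.
#' @export
#' @examples
#' patient_physiology(120, 80, 4.2)
patient_physiology <- function(p_sp, p_dp, cardiac_output,
                               heart_rate = NA_real_,
                               myocardial_mass = NA_real_) {
  if (!(p_sp > p_dp && p_dp > 0))
    stop("require systolic > diastolic > 0 (got ", p_sp, ", ", p_dp, ")",
         call. = FALSE)
  if (!(cardiac_output > 0))
    stop("cardiac output must be > 0", call. = FALSE)
  structure(list(p_sp = p_sp, p_dp = p_dp,
                 cardiac_output = cardiac_output,
                 heart_rate = heart_rate,
                 myocardial_mass = myocardial_mass),
            class = "patient_physiology")
}

#' Resting mean blood pressure
#'
#' The standard clinical estimate of mean arterial pressure from cuff
#' measurements: one third systolic plus two thirds diastolic,
#' `P_MBP = (P_sp + 2 P_dp) / 3`.
#'
#' @param p_sp systolic pressure, mmHg.
#' @param p_dp diastolic pressure, mmHg.
#' @return mean blood pressure, mmHg.
#' @export
#' @examples
#' mean_blood_pressure(120, 80)  # 93.33 mmHg
mean_blood_pressure <- function(p_sp, p_dp) {
  if (any(!(p_sp > p_dp & p_dp > 0)))
    stop("require systolic > diastolic > 0", call. = FALSE)
  (p_sp + 2 * p_dp) / 3
}

#' Total resting coronary flow from cardiac output
#'
#' Resting coronary blood flow is taken as a fixed fraction (default 4%) of
#' cardiac output, the accepted clinical statistic for a resting heart.
#'
#' @param cardiac_output cardiac output, L/min.
#' @param fraction coronary fraction of cardiac output (default 0.04).
#' @return total coronary inflow, m^3/s.
#' @export
#' @examples
#' total_coronary_flow(4.2)  # 2.8e-6 m^3/s = 0.168 L/min
total_coronary_flow <- function(cardiac_output, fraction = 0.04) {
  if (!(cardiac_output > 0))
    stop("cardiac output must be > 0", call. = FALSE)
  Lmin_to_m3s(fraction * cardiac_output)
}

#' Allometric distribution of flow over the tree
#'
#' Splits the inlet flow over the outlets by the allometric scaling law
#' relating branch flow to branch diameter, `Q proportional to D^m` with
#' exponent `m = 7/3`. At each junction the daughters' shares are
#' `D_k^m / sum_j D_j^m`, so flow is conserved exactly at every junction;
#' a single child passes the parent flow through unchanged. Daughter
#' diameters are read from the healthy geometry (stenosis annotations are
#' overlays on the interior profile and never affect junction diameters).
#'
#' @param tree a [coronary_tree()].
#' @param q_total inlet flow, m^3/s.
#' @param exponent allometric exponent (default `7/3`).
#' @param diameter which daughter diameter to use at a junction:
#'   `"proximal"` (default, the junction-local measurement) or `"mean"`
#'   (mean of end diameters).
#' @return a `flow_assignment`: list with `q_total`, named numeric
#'   `outflows` (m^3/s per outlet id), and `state = "resting"`.
#' @export
#' @examples
#' tr <- coronary_tree(list(
#'   segment("root", 0.02, 0.004, 0.004),
#'   segment("a", 0.02, 0.003, 0.003, parent = "root"),
#'   segment("b", 0.02, 0.002, 0.002, parent = "root")))
#' distribute_flow(tr, 2e-6)
distribute_flow <- function(tree, q_total, exponent = 7 / 3,
                            diameter = c("proximal", "mean")) {
  if (!(q_total > 0)) stop("q_total must be > 0", call. = FALSE)
  diameter <- match.arg(diameter)
  dia <- function(s)
    if (diameter == "proximal") s$d_prox else (s$d_prox + s$d_dist) / 2
  outflows <- numeric(0)
  recurse <- function(id, q) {
    ch <- tree$children[[id]]
    if (length(ch) == 0L) {
      outflows[[id]] <<- q
      return(invisible())
    }
    d <- vapply(ch, function(c) dia(tree$segments[[c]]), numeric(1))
    w <- (d / max(d))^exponent  # normalized to keep large exponents finite
    share <- w / sum(w)
    for (k in seq_along(ch)) recurse(ch[k], q * share[k])
  }
  recurse(tree$root, q_total)
  flow_assignment(q_total, outflows[sort(names(outflows))], "resting")
}

flow_assignment <- function(q_total, outflows, state) {
  structure(list(q_total = q_total, outflows = outflows, state = state),
            class = "flow_assignment")
}

#' Hyperemic inlet pressure
#'
#' Adenosine-induced maximal hyperemia lowers mean aortic pressure; the
#' clinical statistic used here is a 12% reduction:
#' `P0 = (1 - drop) * P_MBP`.
#'
#' @param p_mbp resting mean blood pressure, mmHg.
#' @param drop fractional pressure reduction (default 0.12).
#' @return hyperemic inlet pressure, mmHg.
#' @export
hyperemia_pressure <- function(p_mbp, drop = 0.12) {
  (1 - drop) * p_mbp
}

#' Hyperemic microcirculation resistance
#'
#' Under maximal hyperemia the distal microvascular bed dilates; its
#' resistance is taken as a fixed fraction (default 0.23) of the resting
#' value, independent of epicardial stenosis severity.
#'
#' @param r_rest resting microcirculation resistance(s), Pa s/m^3.
#' @param factor hyperemic/resting resistance ratio (default 0.23).
#' @return hyperemic resistance(s), same shape as `r_rest`.
#' @export
hyperemia_resistance <- function(r_rest, factor = 0.23) {
  if (any(r_rest < 0))
    stop("resistance must be nonnegative", call. = FALSE)
  factor * r_rest
}
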