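#' Synthetic cohort specification
#'
#' Parameters of the synthetic vessel/cohort generator. Trees are rooted
#' binary trees whose daughter diameters obey a Murray-type branching
#' relation with a random asymmetry ratio; each vessel carries one graded
#' stenosis; physiology scalars are drawn from truncated normal
#' distributions matching a stable-angina cohort (cardiac output
#' 4.2 +/- 1.6 L/min, heart rate 68 +/- 24 bpm, myocardial mass
#' 142.5 +/- 46.6 g, mean blood pressure near 95 mmHg); the noisy
#' "invasive" reference FFR is the exact linear-network FFR plus additive
#' Gaussian noise on the FFR scale.
#'
#' @param n number of vessels (default 86).
#' @param seed integer seed; all draws flow from it.
#' @param depth_range integer range of tree depth (generations; depth 1 is
#'   a single segment).
#' @param root_diameter_mm range of root proximal diameters, mm.
#' @param murray_exponent exponent `m` of `D_parent^m = sum D_daughter^m`
#'   (default 3).
#' @param asymmetry range of the daughter diameter ratio `D2/D1`.
#' @param length_diameter_ratio segment length as a multiple of its
#'   proximal diameter (default 10).
#' @param taper distal/proximal diameter ratio within a segment
#'   (default 0.9).
#' @param min_diameter_mm smallest branch diameter grown, mm (default 1,
#'   the reconstruction limit of clinical CT angiography); a junction
#'   whose daughters would fall below it is not created.
#' @param severity_range support of the uniform stenosis severity draw
#'   (default `c(0.2, 0.8)`).
#' @param noise_sd standard deviation of the reference-FFR noise, FFR
#'   units (default 0.02, of the order of the agreement spread between
#'   computed and wire-measured FFR).
#' @param stenosis_model lesion model used for the *estimate* pipelines;
#'   the reference oracle is always the exact linear solve.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 86L, seed = 1L, depth_range = c(3L, 5L),
                        root_diameter_mm = c(3, 4.5),
                        murray_exponent = 3, asymmetry = c(0.6, 1),
                        length_diameter_ratio = 10, taper = 0.9,
                        min_diameter_mm = 1,
                        severity_range = c(0.2, 0.8), noise_sd = 0.02,
                        stenosis_model = c("linear", "nonlinear")) {
  stopifnot(n >= 1, noise_sd >= 0,
            severity_range[1] > 0, severity_range[2] < 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 depth_range = as.integer(depth_range),
                 root_diameter_mm = root_diameter_mm,
                 murray_exponent = murray_exponent, asymmetry = asymmetry,
                 length_diameter_ratio = length_diameter_ratio,
                 taper = taper, min_diameter = min_diameter_mm * 1e-3,
                 severity_range = severity_range,
                 noise_sd = noise_sd,
                 stenosis_model = match.arg(stenosis_model)),
            class = "cohort_spec")
}

#' Generate one synthetic coronary tree
#'
#' Builds a rooted binary tree. At each junction a daughter asymmetry
#' ratio `r = D2/D1` is drawn and the daughter proximal diameters satisfy
#' the Murray relation `D_p^m = D1^m + D2^m` applied to the parent's
#' distal diameter, so `D1 = D_p / (1 + r^m)^(1/m)`. Segment length is
#' proportional to its proximal diameter, with a linear within-segment
#' taper. Deterministic for a fixed seed.
#'
#' @param seed integer seed.
#' @param spec a [cohort_spec()].
#' @param depth optional fixed depth (otherwise drawn from
#'   `spec$depth_range`).
#' @return a [coronary_tree()] without stenoses.
#' @export
generate_tree <- function(seed, spec = cohort_spec(), depth = NULL) {
  set.seed(seed)
  if (is.null(depth))
    depth <- sample(seq(spec$depth_range[1], spec$depth_range[2]), 1L)
  d_root <- stats::runif(1, spec$root_diameter_mm[1],
                         spec$root_diameter_mm[2]) * 1e-3
  m <- spec$murray_exponent
  segs <- list()
  grow <- function(id, parent, d_prox, level) {
    d_dist <- d_prox * spec$taper
    segs[[id]] <<- segment(id, spec$length_diameter_ratio * d_prox,
                           d_prox, d_dist, parent = parent)
    if (level >= depth) return(invisible())
    r <- stats::runif(1, spec$asymmetry[1], spec$asymmetry[2])
    d1 <- d_dist / (1 + r^m)^(1 / m)
    d2 <- r * d1
    if (min(d1, d2) < spec$min_diameter) return(invisible())
    grow(paste0(id, "L"), id, d1, level + 1L)
    grow(paste0(id, "R"), id, d2, level + 1L)
  }
  grow("s", NA_character_, d_root, 1L)
  coronary_tree(segs, name = paste0("synthetic-", seed))
}

# one stenosis on a random segment: lesion spans the middle 40% of the
# segment, reference diameter = healthy diameter at the lesion midpoint
.draw_stenosis <- function(tree, severity) {
  ids <- names(tree$segments)
  seg <- tree$segments[[sample(ids, 1L)]]
  start <- 0.3 * seg$length
  len <- 0.4 * seg$length
  mid_frac <- (start + len / 2) / seg$length
  ref <- seg$d_prox + (seg$d_dist - seg$d_prox) * mid_frac
  stenosis(seg$id, start, len, severity, ref)
}

.draw_physiology <- function() {
  p_dp <- max(stats::rnorm(1, 80, 8), 50)
  pulse <- max(stats::rnorm(1, 46, 8), 20)
  co <- max(stats::rnorm(1, 4.2, 1.6), 2)
  hr <- max(stats::rnorm(1, 68, 24), 45)
  mass <- max(stats::rnorm(1, 142.5, 46.6), 60)
  patient_physiology(p_dp + pulse, p_dp, co, heart_rate = hr,
                     myocardial_mass = mass)
}

#' Generate a synthetic cohort
#'
#' Draws `spec$n` stenosed vessels with per-vessel physiology and a noisy
#' reference FFR. The reference is the exact linear-network FFR (direct
#' solve of the identified hyperemic system) plus Gaussian noise of
#' standard deviation `spec$noise_sd`, clipped to (0, 1] -- a simple
#' emulation of pressure-wire measurement error. All randomness flows from
#' `spec$seed`, so the output is fully reproducible.
#'
#' @param spec a [cohort_spec()].
#' @return list with `trees` (named list of [coronary_tree()]s, stenoses
#'   attached), `physiology` (data frame, one row per vessel) and
#'   `reference` (data frame: `vessel_id`, `oracle_ffr`, `reference_ffr`,
#'   `severity`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  tree_seeds <- sample.int(.Machine$integer.max, spec$n)
  severities <- stats::runif(spec$n, spec$severity_range[1],
                             spec$severity_range[2])
  trees <- list()
  phys_rows <- list()
  ref_rows <- list()
  for (i in seq_len(spec$n)) {
    id <- sprintf("v%03d", i)
    tree <- generate_tree(tree_seeds[i], spec)
    # stenosis and physiology draws continue the per-vessel stream seeded
    # inside generate_tree, so each vessel is reproducible in isolation
    st <- .draw_stenosis(tree, severities[i])
    tree <- coronary_tree(unname(tree$segments), st, name = id)
    phys <- .draw_physiology()
    oracle <- ffr_u(tree, phys, solver = "direct")
    noise <- if (spec$noise_sd > 0) stats::rnorm(1, 0, spec$noise_sd) else 0
    ref <- min(max(oracle$ffr[1] + noise, 1e-6), 1)
    trees[[id]] <- tree
    phys_rows[[i]] <- data.frame(
      vessel_id = id, p_sp = phys$p_sp, p_dp = phys$p_dp,
      cardiac_output = phys$cardiac_output, heart_rate = phys$heart_rate,
      myocardial_mass = phys$myocardial_mass, stringsAsFactors = FALSE)
    ref_rows[[i]] <- data.frame(
      vessel_id = id, oracle_ffr = oracle$ffr[1], reference_ffr = ref,
      severity = severities[i], stringsAsFactors = FALSE)
  }
  list(trees = trees,
       physiology = do.call(rbind, phys_rows),
       reference = do.call(rbind, ref_rows),
       spec = spec)
}
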