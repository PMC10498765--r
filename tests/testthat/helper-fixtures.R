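# Fixture builders shared across the suite. All geometry in SI metres.

# single uniform vessel
single_vessel <- function(L = 0.03, d = 0.003, id = "v") {
  coronary_tree(list(segment(id, L, d, d)))
}

# root + two daughters, equal (symmetric) or given diameters
bifurcation_tree <- function(d1 = 0.003, d2 = 0.003, d_root = 0.004,
                             L = 0.02) {
  coronary_tree(list(
    segment("root", L, d_root, d_root),
    segment("a", L, d1, d1, parent = "root"),
    segment("b", L, d2, d2, parent = "root")))
}

# three-level symmetric binary tree (7 segments, 4 outlets)
three_level_tree <- function(d_root = 0.004, L = 0.02) {
  r <- 2^(-1 / 3)  # symmetric Murray daughter ratio
  d1 <- d_root * r
  d2 <- d1 * r
  coronary_tree(list(
    segment("r", L, d_root, d_root),
    segment("rL", L, d1, d1, parent = "r"),
    segment("rR", L, d1, d1, parent = "r"),
    segment("rLL", L, d2, d2, parent = "rL"),
    segment("rLR", L, d2, d2, parent = "rL"),
    segment("rRL", L, d2, d2, parent = "rR"),
    segment("rRR", L, d2, d2, parent = "rR")))
}

demo_physiology <- function() patient_physiology(126, 80, 4.2, 68, 142.5)

# random stenosed tree + calibrated hyperemic boundary set, for solver
# property tests
random_hyperemic_problem <- function(seed, severity = NULL) {
  spec <- cohort_spec(depth_range = c(2L, 5L), seed = seed)
  tree <- generate_tree(seed, spec)
  set.seed(seed + 1L)
  if (is.null(severity)) severity <- runif(1, 0.2, 0.8)
  ids <- names(tree$segments)
  seg <- tree$segments[[sample(ids, 1L)]]
  st <- stenosis(seg$id, 0.3 * seg$length, 0.4 * seg$length, severity,
                 (seg$d_prox + seg$d_dist) / 2)
  tree <- coronary_tree(unname(tree$segments), st)
  phys <- patient_physiology(runif(1, 110, 140), runif(1, 65, 90),
                             runif(1, 3, 6))
  p_mbp <- mean_blood_pressure(phys$p_sp, phys$p_dp)
  resting <- distribute_flow(tree, total_coronary_flow(phys$cardiac_output))
  rmap <- calibrate_microcirculation(tree, p_mbp, resting)
  list(tree = tree, resting = resting,
       p0 = mmHg_to_Pa(hyperemia_pressure(p_mbp)),
       r_j = hyperemia_resistance(rmap$micro_rest))
}

# exhaustive pairwise AUC oracle (ties count one half); lower FFR = diseased
brute_force_auc <- function(estimates, labels) {
  s <- -estimates
  pos <- s[as.logical(labels)]
  neg <- s[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
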