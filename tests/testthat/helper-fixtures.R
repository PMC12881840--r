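# Shared fixtures: built in code at test time, no stored data files.

square_poly <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

# manifest with arbitrary per-origin patient counts; every patient gets one
# resection with one slide unless a hierarchy is supplied
make_manifest <- function(n_pancreas = 2, n_si = 2, n_other = 1) {
  origins <- c(rep("pancreas", n_pancreas), rep("small_intestine", n_si),
               rep("other", n_other))
  ids <- sprintf("p%03d", seq_along(origins))
  as_manifest(data.frame(patient_id = ids,
                         specimen_id = paste0(ids, "_s1"),
                         slide_id = paste0(ids, "_sl1"),
                         origin = origins,
                         specimen_kind = "resection"))
}

# constant-valued preprocessed tile
const_tile <- function(value, side = 8) array(value, dim = c(side, side, 3))

# small, clearly separable embedding cohort for classifier tests
make_separable_cohort <- function(seed = 1, n_per_class = 4, n_patches = 30,
                                  dim = 4, delta = 8) {
  simulate_cohort(simulation_config(
    n_pancreas = n_per_class, n_si = n_per_class, n_other = 0,
    patches_per_patient = n_patches, dim = dim, delta = delta,
    sigma_patch = 1, sigma_patient = 0.3, seed = seed))
}

# Brute-force threshold-search oracle: enumerate every interval with
# endpoints drawn from the pooled sums +/- eps, keep those capturing exactly
# i other sums (and containing 0 when the constraint applies and is
# satisfiable), and minimise the in-class count. Returns the capture count
# and the minimal in-class count; independent of the window enumeration the
# implementation uses.
oracle_thresholds <- function(cal, i, contain_zero = TRUE, eps = 1e-9) {
  others <- cal$other_sums
  inclass <- c(cal$pancreas_sums, cal$si_sums)
  if (i == 0) {
    return(list(i = 0L, n_inclass = sum(inclass >= 0 & inclass <= 0)))
  }
  pooled <- sort(unique(c(others, inclass)))
  # 0 must be a representable endpoint: under the contain-zero constraint the
  # optimal interval may terminate exactly at the decision boundary
  cand <- sort(unique(c(pooled - eps, pooled, pooled + eps, 0)))
  best <- Inf
  found_zero <- FALSE
  # pass 1: honour the contain-zero constraint; pass 2 only if infeasible
  for (pass in 1:2) {
    for (lo in cand) {
      for (hi in cand[cand >= lo]) {
        if (pass == 1 && contain_zero && !(lo <= 0 && hi >= 0)) next
        if (sum(others >= lo & others <= hi) != i) next
        if (pass == 1) found_zero <- TRUE
        n_in <- sum(inclass >= lo & inclass <= hi)
        if (n_in < best) best <- n_in
      }
    }
    if (!contain_zero || found_zero || pass == 2) break
  }
  list(i = as.integer(i), n_inclass = best)
}

random_calibration_set <- function(n_max = 12) {
  n_other <- sample(1:4, 1)
  n_bin <- sample(2:(n_max - n_other), 1)
  sums <- round(stats::rnorm(n_other + n_bin, 0, 3), 3)
  # make values distinct as the acceptance criterion states
  while (anyDuplicated(sums)) sums <- sums + stats::runif(length(sums), -1e-3, 1e-3)
  k <- sample(seq_len(n_bin - 1), 1)
  calibration_set(pancreas_sums = sums[seq_len(k)],
                  si_sums = sums[(k + 1):n_bin],
                  other_sums = sums[(n_bin + 1):(n_bin + n_other)])
}
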