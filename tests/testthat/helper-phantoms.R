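# Shared fixture builders. Everything is generated in code at test time.

# Small, fast B-scan phantom (defaults are the control-group thicknesses).
quick_bscan_spec <- function(...) {
  bscan_phantom_spec(n_columns = 128, ...)
}

# Cohort with a handful of eyes per group for structural tests.
quick_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_spec(
    n_subjects = c(control = 20, dr_normal = 20, dr_decreased = 20),
    seed = seed, ...))$records
}

# One synthetic eye record at the control means.
control_mean_record <- function() {
  m <- octaphen:::default_group_means()[, "control"]
  as.data.frame(as.list(m))
}

# Exhaustive enumeration oracle: minimum cost over all monotone
# left-to-right paths (row step in {-1, 0, +1}) through a gradient graph.
# Entry and exit rows are free. Only tractable for tiny images.
brute_force_min_path <- function(graph) {
  g <- graph$gradient
  nr <- graph$n_rows; nc <- graph$n_cols
  eps <- graph$eps
  best <- Inf
  recurse <- function(r, cc, cost) {
    if (cost >= best) return()
    if (cc == nc) {
      best <<- min(best, cost)
      return()
    }
    for (dr in -1:1) {
      r2 <- r + dr
      if (r2 < 1 || r2 > nr) next
      recurse(r2, cc + 1, cost + 2 - g[r, cc] - g[r2, cc + 1] + eps)
    }
  }
  for (r0 in seq_len(nr)) recurse(r0, 1, 0)
  best
}
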