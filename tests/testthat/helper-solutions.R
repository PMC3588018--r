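# Converged solutions reused across test files (each takes ~0.5 s to build,
# so they are computed once per test run).
.solution_cache <- new.env(parent = emptyenv())

cached_solution <- function(name) {
  if (is.null(.solution_cache[[name]])) {
    .solution_cache[[name]] <- switch(
      name,
      gel = solve_mlpb(mlpb_preset("dppc-gel")),
      liquid = solve_mlpb(mlpb_preset("dppc-liquid")),
      t298 = solve_mlpb(mlpb_parameters(T = 298, a0 = 0.48)),
      stop("unknown cached solution: ", name)
    )
  }
  .solution_cache[[name]]
}

# random but reproducible bounded potential profiles on [0, D], used for
# normalization/limit property checks
random_phi_profiles <- function(x, n = 5, scale = 0.08, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    a <- stats::runif(3, -1, 1)
    scale * (a[1] * x / max(x) + a[2] * sin(3 * pi * x / max(x)) +
               a[3] * (x / max(x))^2)
  })
}
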