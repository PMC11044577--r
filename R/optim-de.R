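# Minimal differential-evolution global optimizer (rand/1/bin) used for the
# multiexponential kernel fit.  Consumes the R RNG stream, so callers make
# it deterministic with set.seed().
de_optimize <- function(fn, lower, upper, np = NULL, maxiter = 250L,
                        f_weight = 0.7, cr = 0.9) {
  d <- length(lower)
  if (is.null(np)) np <- max(10L * d, 20L)
  pop <- matrix(runif(np * d, lower, upper), nrow = np, ncol = d, byrow = TRUE)
  cost <- apply(pop, 1L, fn)
  for (iter in seq_len(maxiter)) {
    for (i in seq_len(np)) {
      idx <- sample.int(np, 3L)
      mut <- pop[idx[1L], ] + f_weight * (pop[idx[2L], ] - pop[idx[3L], ])
      mut <- pmin(pmax(mut, lower), upper)
      cross <- runif(d) < cr
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mut, pop[i, ])
      tc <- fn(trial)
      if (tc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best])
}
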