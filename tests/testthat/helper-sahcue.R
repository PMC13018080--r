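# Shared fixtures: configs and random-schedule generators, all built in code.

cfg_default <- default_config()

# A degenerate config whose dynamics are the identity (no transitions, no
# mortality): useful for conservation/identity checks.
cfg_static <- local({
  cfg <- default_config()
  for (s in c("ci", "no_ci")) {
    d <- cfg$schedule[[s]]$dist_3mo
    for (k in c("dist_1y", "dist_2y", "dist_3y", "dist_5y"))
      cfg$schedule[[s]][[k]] <- d
    cfg$schedule[[s]]$mortality_post5y <- 0
  }
  cfg
})

# Random valid 3-state row-stochastic transition matrix (dead absorbing).
random_transition_matrix <- function() {
  rrow <- function() { p <- stats::runif(3); p / sum(p) }
  matrix(c(rrow(), rrow(), 0, 0, 1), nrow = 3, byrow = TRUE,
         dimnames = list(c("independent", "dependent", "dead"),
                         c("independent", "dependent", "dead")))
}

random_distribution <- function() {
  p <- stats::runif(3)
  p <- p / sum(p)
  c(independent = p[1], dependent = p[2], dead = p[3])
}

# Independent brute-force oracle: accumulate the product of the transition
# matrices first, then apply it to the start distribution once per step.
matrix_power_evolution <- function(dist0, matrices) {
  out <- matrix(NA_real_, nrow = length(matrices) + 1L, ncol = 3,
                dimnames = list(NULL, c("independent", "dependent", "dead")))
  out[1L, ] <- dist0
  P <- diag(3)
  for (k in seq_along(matrices)) {
    P <- P %*% matrices[[k]]
    out[k + 1L, ] <- as.numeric(dist0 %*% P)
  }
  out
}
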