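# small in-code fixtures shared across test files

toy_counts <- function() {
  m <- matrix(c(6L, 2L, 0L,
                2L, 2L, 1L,
                0L, 5L, 4L,
                1L, 0L, 2L), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("asv", 1:4),
                              c("2020-10-06", "2020-10-07", "2020-10-08")))
  m
}

toy_experiment <- function(discharge = c(0.25, 0.9, 1.8)) {
  m <- toy_counts()
  StormExperiment(m, as.Date(colnames(m)), discharge_cms = discharge)
}

default_sim <- function(seed = 1, ...) {
  simulateStormExperiment(simulationConfig(rng_seed = seed, ...))
}

# brute-force Mann-Whitney tail probability by enumerating all label
# arrangements (oracle for the exact path)
enumerate_mw_p <- function(x, y) {
  v <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(v), nx)
  u_of <- function(xi) {
    xs <- v[xi]; ys <- v[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_all <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(nx))
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  list(U = u_obs, p_one_sided = min(p_lo, p_hi),
       p_two_sided = min(1, 2 * min(p_lo, p_hi)))
}
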