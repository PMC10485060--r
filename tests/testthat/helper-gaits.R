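# The worked-example gait (s = 0.6 at v = 0.39) is used across tests; the
# solved stiffness is frozen as a regression value.
FIG2_S <- 0.6
FIG2_V <- 0.39
FIG2_K <- 0.1456116189  # derived once with periodic_gait(); regression fixture

fig2_gait <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- periodic_gait(FIG2_V, step_length = FIG2_S)
    cache
  }
})

# random section states within the walkable range
random_sections <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(theta = runif(n, -0.45, -0.05),
             theta_dot = runif(n, 0.1, 0.8))
}
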