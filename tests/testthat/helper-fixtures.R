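# Shared fixtures built in code.

e0_fC <- 1.602176634e-4

# Random 5-state linear scheme with rates spanning two decades; all chains
# are irreducible by construction.
random_scheme <- function(seed) {
  withr::with_seed(seed, {
    kinetic_scheme(
      transitions = lapply(1:4, function(i) {
        transition_params(alpha0 = 10^runif(1, -1.5, 0.5),
                          beta0 = 10^runif(1, -1.5, 0.5),
                          x = runif(1),
                          z_delta = runif(1, 0.2, 1.5))
      }),
      n_channels = 1e7
    )
  })
}

two_state_scheme <- function(alpha0 = 1, beta0 = 1, x = 0.5, z_delta = 1,
                             n_channels = 1e9) {
  kinetic_scheme(list(transition_params(alpha0, beta0, x, z_delta)),
                 n_channels = n_channels)
}

# Small frame series with two rigid residue groups a known COM distance
# apart; group b offset along x.
two_group_traj <- function(d = 5, n_frames = 12) {
  atoms <- data.frame(resno = c(1, 1, 1, 2, 2, 2, 2),
                      resid = c(rep("ASP", 3), rep("ARG", 4)),
                      elety = c("CG", "OD1", "OD2", "NE", "CZ", "NH1", "NH2"),
                      chain = "A")
  a <- rbind(c(0, 0, -0.8), c(0, 0.8, 0.4), c(0, -0.8, 0.4))
  b <- rbind(c(-0.7, 0.7, 0), c(-0.7, -0.7, 0), c(0.7, 0.7, 0), c(0.7, -0.7, 0))
  xyz <- rbind(a, sweep(b, 2, c(d, 0, 0), "+"))
  frame_series(replicate(n_frames, xyz, simplify = FALSE), atoms)
}
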