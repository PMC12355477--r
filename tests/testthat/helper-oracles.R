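# Independent fine-grid discretisation oracle for the relapse/remission toy
# model: stable -> relapse at constant hazard `lambda`, relapse resolves
# deterministically after `rem` years, utilities u_stable/u_relapse,
# continuous discounting at rate r. A deterministic cohort recursion over a
# daily grid; written independently of the event-driven engine.
markov_grid_oracle <- function(lambda, rem, horizon, u_stable, u_relapse,
                               r = 0, dt = 1 / 365) {
  n_steps <- round(horizon / dt)
  k_rem <- max(1L, round(rem / dt))
  p_rel <- 1 - exp(-lambda * dt)
  f_stable <- 1
  f_rel <- numeric(k_rem)       # remaining relapse duration in steps
  exp_relapses <- 0
  q_disc <- 0
  for (s in seq_len(n_steps)) {
    t_mid <- (s - 0.5) * dt
    w <- if (r == 0) dt else exp(-t_mid * log1p(r)) * dt
    q_disc <- q_disc + (f_stable * u_stable + sum(f_rel) * u_relapse) * w
    new_rel <- f_stable * p_rel
    exp_relapses <- exp_relapses + new_rel
    recovered <- f_rel[1]
    f_rel <- c(f_rel[-1], new_rel)
    f_stable <- f_stable - new_rel + recovered
  }
  list(expected_relapses = exp_relapses, expected_qalys_disc = q_disc)
}
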