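# straightforward event-based reference for the composite plasticity rule on
# one synapse: analytic trace decay between events, pre-before-post at ties;
# written directly from the update equations, independent of the package's
# integration code paths

pair_trajectory_oracle <- function(pre, post, params, w0) {
  ev <- rbind(cbind(pre, 0), cbind(post, 1))
  ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
  z_pre <- z_post <- z_slow <- 0
  w <- w0; tprev <- 0
  traj <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    d <- ev[i, 1] - tprev
    z_pre <- z_pre * exp(-d / params$tau_stdp)
    z_post <- z_post * exp(-d / params$tau_stdp)
    z_slow <- z_slow * exp(-d / params$tau_stdp_slow)
    tprev <- ev[i, 1]
    if (ev[i, 2] == 0) {
      w <- w - params$B * z_post + params$delta1
      w <- max(w, params$w_min)
      if (!is.na(params$w_max)) w <- min(w, params$w_max)
      z_pre <- z_pre + 1
    } else {
      w <- w + params$A * z_pre * z_slow -
        params$beta * z_post^3 * ((w - params$w_tilde) / params$w_tilde)^3
      w <- max(w, params$w_min)
      if (!is.na(params$w_max)) w <- min(w, params$w_max)
      z_post <- z_post + 1
      z_slow <- z_slow + 1
    }
    traj[i] <- w
  }
  traj
}

pair_update_oracle <- function(pre, post, params, w0) {
  traj <- pair_trajectory_oracle(pre, post, params, w0)
  traj[length(traj)]
}
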