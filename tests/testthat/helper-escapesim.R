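# Shared fixture builders: hand-constructed recordings and event logs small
# enough to reason about by eye.

# Recording with the participant moving along given head positions; forward
# vectors default to facing the fruit (0, 1). Threat columns NA unless given.
make_recording <- function(t, head_x, head_y,
                           head_fx = rep(0, length(t)),
                           head_fy = rep(1, length(t)),
                           pelvis_fx = head_fx, pelvis_fy = head_fy,
                           threat_x = rep(NA_real_, length(t)),
                           threat_y = rep(NA_real_, length(t))) {
  data.frame(t = t, head_x = head_x, head_y = head_y,
             head_fx = head_fx, head_fy = head_fy,
             pelvis_x = head_x, pelvis_y = head_y,
             pelvis_fx = pelvis_fx, pelvis_fy = pelvis_fy,
             threat_x = threat_x, threat_y = threat_y)
}

make_event_log <- function(threat_appearance_time = 1,
                           fruit_pick_times = numeric(0),
                           shelter_entry_time = NA_real_,
                           contact_time = NA_real_,
                           magical_force_time = NA_real_,
                           epoch_end_time = 15) {
  list(threat_appearance_time = threat_appearance_time,
       fruit_pick_times = fruit_pick_times,
       shelter_entry_time = shelter_entry_time,
       contact_time = contact_time,
       magical_force_time = magical_force_time,
       epoch_end_time = epoch_end_time,
       force_shield = FALSE, hands_up_signaled = FALSE,
       hands_up_time = NA_real_, medusa = FALSE,
       outcome = NA_character_, vocalized = FALSE,
       mode_switch_time = NA_real_, escape_start_commanded = NA_real_)
}

# 1-D constant-velocity forward-simulation oracle for the placement rules:
# steps both movers at `step` seconds and returns the time at which the
# threat reaches `target` (position on the escape axis).
oracle_arrival_time <- function(start, speed, target, step = 1e-3,
                                t_max = 60) {
  t <- 0; pos <- start
  dir_sign <- sign(target - start)
  while (t < t_max) {
    nxt <- pos + speed * step
    if (dir_sign * (nxt - target) >= 0) {
      # interpolate the crossing within the final step
      return(t + step * (target - pos) / (nxt - pos))
    }
    pos <- nxt
    t <- t + step
  }
  NA_real_
}

# dense-resampling trapezium oracle: integrates the piecewise-linear
# interpolant on a grid refined 100x AND containing the original knots
oracle_time_average <- function(t, v, win, n_fine = 6000) {
  a <- max(win[1], t[1]); b <- min(win[2], t[length(t)])
  tf <- sort(unique(c(seq(a, b, length.out = n_fine),
                      t[t >= a & t <= b])))
  vf <- approx(t, v, xout = tf)$y
  sum(diff(tf) * (vf[-1] + vf[-length(vf)]) / 2) / (b - a)
}
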