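# shared fixtures built in code

# match detected events to true onset times; returns index into events or NA
match_events <- function(events, true_onsets_s, tol_s = 0.5) {
  used <- rep(FALSE, nrow(events))
  vapply(true_onsets_s, function(t0) {
    j <- which(abs(events$onset_s - t0) < tol_s & !used)
    if (length(j) == 0) return(NA_integer_)
    used[j[1]] <<- TRUE
    j[1]
  }, integer(1))
}

# three well-separated Gaussian blobs in 2-D (sigma 0.1, centers >= 10 sigma)
make_blobs <- function(n_per = 60, seed = 0) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(3, 0), c(0, 3))
  pts <- do.call(rbind, lapply(1:3, function(i) {
    cbind(stats::rnorm(n_per, centers[i, 1], 0.1),
          stats::rnorm(n_per, centers[i, 2], 0.1))
  }))
  list(points = pts, labels = rep(1:3, each = n_per))
}

# aligned Vm waveform matrix for three planted spike classes
make_spike_classes <- function(n_per = 20, seed = 11) {
  classes <- rep(c("spikelet", "short", "long"), each = n_per)
  fs <- 10000
  mats <- lapply(seq_along(classes), function(i) {
    cfg <- if (classes[i] == "spikelet") {
      sim_config(duration = 0.6, spike_times = numeric(0),
                 shoulder_widths = numeric(0), spikelet_times = 0.2,
                 vm_noise_sd = 0.2, seed = seed + i)
    } else {
      sim_config(duration = 0.6, spike_times = 0.2,
                 shoulder_widths = if (classes[i] == "short") 5 else 18,
                 vm_noise_sd = 0.2, seed = seed + i)
    }
    v <- simulate_vm(cfg)$trace$vm
    v[(0.195 * fs):(0.25 * fs)]
  })
  list(waveforms = do.call(rbind, mats), labels = classes)
}
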