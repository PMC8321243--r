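# Canonical study conditions shared across tests: a multihour two-channel
# recording (60-s frames) with eight sequential agent applications, each
# followed by a washout return to basal conditions.

study_labels <- c("GLP-1 7-36 @ 1 pM", "GLP-1 7-36 @ 100 pM",
                  "GLP-1 7-36 @ 10 nM", "GIP @ 1 pM", "GIP @ 100 pM",
                  "GIP @ 10 nM", "adrenaline @ 10 uM", "forskolin+IBMX")

# n conditions of 20 frames separated by 50-frame basal regions,
# 40-frame lead-in: total = 70 n + 40 frames
study_schedule <- function(labels = study_labels) {
  n <- length(labels)
  starts <- 40 + (seq_len(n) - 1) * 70
  timestamp_schedule(labels, starts, starts + 20, 70 * n + 40, 60)
}

# exponential photobleaching, ~30 % donor / ~36 % acceptor loss over 600
# frames (9 % residual ratio drift)
study_drift <- function(noise_sd = 0.03) {
  drift_spec("exponential", c(-6e-4, -7.5e-4), noise_sd)
}

# simulate -> ratio -> normalize -> baseline-correct
correct_traces <- function(sim, schedule, method = "piecewise_linear") {
  nrm <- normalize_to_initial(compute_ratio(sim$acceptor, sim$donor))
  subtract_baseline(nrm, fit_baseline(nrm, schedule, method))
}

# a small two-condition schedule for unit tests
tiny_schedule <- function() {
  timestamp_schedule(c("A", "B"), c(20, 60), c(40, 80), 120, 60)
}

# non-overlapping random blob layout
random_blob_layout <- function(n, lo, hi, minsep) {
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n) {
    p <- stats::runif(2, lo, hi)
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums(sweep(pts, 2, p)^2))) > minsep) {
      pts <- rbind(pts, p)
    }
  }
  pts
}
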