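# Shared fixtures: observation designs and small synthetic series built in
# code at test time.

# Sparse physiological-style design on the 0-100 scale (observations before,
# during and after the challenge).
trout_phys_times <- c(0, 8, 16, 22, 30, 40, 50, 58, 62, 70, 80, 90, 100)

# Behavioural-style design: nothing observable during the challenge window.
trout_behav_times <- c(0, 5, 10, 15, 19, 61, 65, 70, 76, 84, 92, 100)

# Noiseless model output at the physiological design.
exact_series <- function(K, C, F_pert = 0.1, perc = 1,
                         times = trout_phys_times) {
  p <- kv_params(K = K, C = C, F_pert = F_pert, perc = perc)
  simulate_closed_form(p, times)$x
}

# Random parameter draws spanning all three damping regimes (log-uniform).
draw_params <- function(n, K_range = c(1e-3, 10), C_range = c(1e-3, 50),
                        F_range = c(0.01, 10)) {
  data.frame(
    K = exp(stats::runif(n, log(K_range[1]), log(K_range[2]))),
    C = exp(stats::runif(n, log(C_range[1]), log(C_range[2]))),
    F_pert = exp(stats::runif(n, log(F_range[1]), log(F_range[2]))))
}

# Minimal long-format cohort of noiseless model series for two individuals.
tiny_cohort_data <- function() {
  y1 <- exact_series(0.1, 2)
  y2 <- exact_series(0.2, 1)
  rbind(
    data.frame(individual_id = "a1", measure = "m1", line = "A",
               replicate = "rep1", time = trout_phys_times, value = y1),
    data.frame(individual_id = "a2", measure = "m1", line = "R",
               replicate = "rep1", time = trout_phys_times, value = y2))
}
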