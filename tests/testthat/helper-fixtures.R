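# Shared fixtures, built in code.

# Small random recording with in-range values.
random_recording <- function(n = 100L, seed = 42L, subject = "S01",
                             trial = "T1", rate = 128) {
  set.seed(seed)
  imu_recording(subject, trial, data.frame(
    ax = runif(n, -2, 2), ay = runif(n, -2, 2), az = runif(n, -2, 2),
    wx = runif(n, -300, 300), wy = runif(n, -300, 300),
    wz = runif(n, -300, 300)
  ), sampling_rate = rate)
}

default_profile <- function(...) subject_profile("S01", ...)

# Tiny cohort reused across tests (3 subjects x 2 trials), built once.
tiny_cohort <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- generate_cohort(
      protocol_script(n_subjects = 3L, trials = 2L), seed = 11L)
    ds
  }
})

# Independent textbook oracle for the eight window statistics of one
# numeric vector (population moments, non-excess kurtosis).
oracle_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(mean = mu, sd = sqrt(m2), variance = m2, max = max(x), min = min(x),
    range = max(x) - min(x),
    kurtosis = if (m2 <= 1e-20) 0 else m4 / m2^2,
    skewness = if (m2 <= 1e-20) 0 else m3 / m2^1.5)
}
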