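# shared fixtures: small synthetic movies and tables built in code

vm_movie <- function(apd30 = 134, apd80 = 220, upstroke = 10,
                     rows = 12, cols = 12, noise_sd = 0, seed = 1, ...) {
  simulate_movie(sim_config(
    ap_template(apd30, apd80, upstroke),
    rows = rows, cols = cols, noise_sd = noise_sd, seed = seed, ...))
}

ca_movie <- function(ttp = 98, tau = 400, rows = 12, cols = 12,
                     noise_sd = 0, seed = 4, ...) {
  simulate_movie(sim_config(
    ca_template(ttp, tau),
    rows = rows, cols = cols, noise_sd = noise_sd, seed = seed, ...))
}

# one normalized beat of a single sampled template trace (times relative to
# the stimulus, activation onset at t = onset)
template_beat <- function(template, dt = 1, onset = 20,
                          duration = NULL, noise_sd = 0, seed = NULL) {
  if (is.null(duration)) duration <- onset + template_span(template) + 50
  tr <- sample_template(template, dt, duration = duration, onset = onset)
  y <- tr$value
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(y), 0, noise_sd)
  }
  list(y = y, t = tr$time - onset + onset, time = tr$time, onset = onset)
}

dsg2_qpcr_design <- function(fold_change, groups = c("Ctrl1", "Mut"),
                             cq_noise_sd = 0, loading_sd = 0, seed = 1,
                             efficiency = 2) {
  qpcr_design(
    genes = data.frame(gene = c("DSG2", "GAPDH", "RNA18S"),
                       role = c("target", "reference", "reference")),
    groups = groups,
    fold_changes = data.frame(gene = "DSG2", group = groups[2],
                              fold_change = fold_change),
    cq_noise_sd = cq_noise_sd, loading_sd = loading_sd,
    efficiency = efficiency, seed = seed)
}
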