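# Fixtures are built in code; independent oracles used across test files.

# --- oracles ----------------------------------------------------------------

# exact two-sided rank-sum p by full enumeration over all rank assignments
enum_rank_sum_p <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  mu <- n1 * n2 / 2
  u_all <- apply(combos, 2, function(idx) sum(seq_len(n1 + n2)[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# brute-force binomial upper tail by pmf summation
brute_binom_tail <- function(k, n, p0) {
  i <- k:n
  sum(choose(n, i) * p0^i * (1 - p0)^(n - i))
}

# 2x2 within-subject effect F via the squared paired t of the per-subject
# contrast (closed form; independent of aov)
contrast_f <- function(data, effect) {
  wide <- tidyr::pivot_wider(data,
    names_from = c("condition", "phase"), values_from = "value"
  )
  cells <- as.matrix(wide[, setdiff(names(wide), "subject")])
  cond <- rep(sort(unique(data$condition)), each = 2)
  phase <- rep(sort(unique(data$phase)), times = 2)
  cn <- paste(cond, phase, sep = "_")
  cells <- cells[, cn] # fixed column order
  contrast <- switch(effect,
    condition = c(1, 1, -1, -1) / 2,
    phase = c(1, -1, 1, -1) / 2,
    interaction = c(1, -1, -1, 1)
  )
  d <- as.vector(cells %*% contrast)
  n <- length(d)
  (mean(d) / (sd(d) / sqrt(n)))^2
}

# --- fixtures ---------------------------------------------------------------

# minimal hand-built trial table: one run, one subject, 3 encoding words and
# 5 retrieval trials covering the outcome taxonomy
tiny_trials <- function() {
  tibble::tibble(
    trial_id = c("e1", "e2", "e3", "r1", "r2", "r3", "r4", "r5"),
    subject_id = "s01",
    run_id = "run1",
    phase = rep(c("encoding", "retrieval"), c(3, 5)),
    onset = c(10, 15, 20, 100, 106, 112, 118, 124),
    beat_condition = "binaural",
    stimulation_delivered = rep(c(TRUE, FALSE), c(3, 5)),
    source_category = "color",
    word = c("apple", "birch", "chalk", "apple", "birch", "chalk", "zebra", "quill"),
    novelty = rep(c("na", "old", "new"), c(3, 3, 2)),
    response = c("none", "none", "none",
                 "source_a", "unsure", "new", "source_b", "new"),
    source_truth = c("source_a", "source_b", "source_a",
                     "source_a", "source_b", "source_a", "na", "na")
  )
}

write_tiny_spikes_tsv <- function(path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(tibble::tibble(
    unit_id = "u1", subject_id = "s01", region = "hippocampus",
    hemisphere = "left", unit_class = "single",
    timestamp = c(2.5, 0.25, 1.0)
  ), path)
  path
}

# small but full-paradigm cohort for pipeline-level tests
tiny_config <- function(...) {
  simulation_config(n_subjects = 1, units_per_region_hemisphere = 2, ...)
}

# direct simulation of one unit's per-trial window rates under two flat
# Poisson rates, bypassing the generator (used for selection power/FWE)
two_condition_rates <- function(n_a, n_b, rate_a, rate_b, win_s = 0.5) {
  list(
    a = rpois(n_a, rate_a * win_s) / win_s,
    b = rpois(n_b, rate_b * win_s) / win_s
  )
}

# constructs a retrieval trial block with exact response counts so the
# percentage arithmetic is deterministic
make_retrieval_block <- function(subject = "s01", category = "color",
                                 n_old = 100, n_hits = 86, n_correct = 50,
                                 n_incorrect = 20, n_new = 100, n_fa = 19,
                                 condition = "binaural", run = "r1") {
  n_unsure <- n_hits - n_correct - n_incorrect
  stopifnot(n_unsure >= 0)
  old_resp <- c(rep("source_a", n_correct),   # truth is source_a below
                rep("source_b", n_incorrect),
                rep("unsure", n_unsure),
                rep("new", n_old - n_hits))
  new_resp <- c(rep("source_a", n_fa), rep("new", n_new - n_fa))
  n <- n_old + n_new
  tibble::tibble(
    trial_id = sprintf("%s_%s_%s_t%03d", subject, run, category, seq_len(n)),
    subject_id = subject,
    run_id = paste(subject, run, category, sep = "_"),
    phase = "retrieval",
    onset = seq_len(n) * 6,
    beat_condition = condition,
    stimulation_delivered = category == "scene",
    source_category = category,
    word = sprintf("w%03d", seq_len(n)),
    novelty = rep(c("old", "new"), c(n_old, n_new)),
    response = c(old_resp, new_resp),
    source_truth = rep(c("source_a", "na"), c(n_old, n_new))
  )
}
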