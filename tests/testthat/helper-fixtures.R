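# Shared fixtures, built once per test run and cached across test files.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small but informative dataset: 12 units, 50 stimuli, 6 trials
small_dataset <- function() get_fixture("small", function()
  synth_dataset(n_units = 12, n_renditions = 5, n_trials = 6, seed = 42,
                noise_sd = 0.5, purity = 0.6, gain_range = c(8, 20)))

# paper-scale stimulus count (110), moderate noise, for recovery tests
recovery_dataset <- function() get_fixture("recovery", function()
  synth_dataset(n_units = 20, n_renditions = 11, n_trials = 10, seed = 7,
                noise_sd = 0.5, purity = 0.7, gain_range = c(15, 30)))

# noiseless-drive variant sharing the recovery dataset's stimuli/units
recovery_dataset_noiseless <- function() get_fixture("recovery0", function()
  synth_dataset(n_units = 20, n_renditions = 11, n_trials = 10, seed = 7,
                noise_sd = 0, purity = 0.7, gain_range = c(15, 30)))

# independent brute-force ARI by pair enumeration (O(n^2) oracle)
ari_bruteforce <- function(p1, p2) {
  n <- length(p1)
  a <- b <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s1 <- p1[i] == p1[j]; s2 <- p2[i] == p2[j]
    if (s1 && s2) a <- a + 1L
    if (!s1 && !s2) b <- b + 1L
  }
  tot <- choose(n, 2)
  ri <- (a + b) / tot
  # expected RI under the permutation model, from the marginals
  n1 <- table(p1); n2 <- table(p2)
  sum1 <- sum(choose(n1, 2)); sum2 <- sum(choose(n2, 2))
  exp_idx <- sum1 * sum2 / tot
  max_idx <- (sum1 + sum2) / 2
  if (max_idx == exp_idx) return(0)
  ((a) - exp_idx) / (max_idx - exp_idx)
}
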