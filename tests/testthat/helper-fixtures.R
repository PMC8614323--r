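# small study configuration used by generator and pipeline tests; scaled
# down from the defaults so a full pipeline runs in seconds
small_config <- function(seed = 42L, ...) {
  generator_config(
    n_females = 30L, n_males = 30L, n_years = 3L,
    n_groups_per_sex = 2L, weeks_per_season = 4L,
    hier_n_hinds = 24L, hier_n_years = 2L, hier_n_groups = 3L,
    preg_n_hinds = 10L, preg_mean_pregnancies = 2, preg_events = 8L,
    interactions_per_dyad = 6,
    seed = seed, ...
  )
}

# strict transitive tournament: every higher-ranked animal beats every
# lower-ranked one `wins` times
transitive_matrix <- function(n, wins = 3L) {
  m <- matrix(0L, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  m[upper.tri(m)] <- wins
  m
}

random_dominance_matrix <- function(n, lambda = 2) {
  m <- matrix(stats::rpois(n * n, lambda), n, n,
              dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  diag(m) <- 0L
  storage.mode(m) <- "integer"
  m
}
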