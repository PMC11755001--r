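# Small fixture builders shared across test files. Everything is generated
# in code; no data files.

toy_stem_table <- function() {
  data.frame(
    tree_id = c("t1", "t1", "t2", "t2", "t3", "t3"),
    species = c("spA", "spA", "spA", "spA", "spB", "spB"),
    x = c(5, 5, 10, 10, 20, 20),
    y = c(5, 5, 10, 10, 20, 20),
    census_index = c(1L, 2L, 1L, 2L, 1L, 2L),
    census_date = c(2000, 2005, 2000, 2005, 2000, 2005),
    dbh = c(10, 15, 50, 60, 100, NA),
    status = c("alive", "alive", "alive", "alive", "alive", "dead"),
    stringsAsFactors = FALSE
  )
}

toy_seedling_table <- function() {
  data.frame(
    seedling_id = c("q1", "q1", "q2", "q2", "q3", "q3"),
    species = c("spA", "spA", "spA", "spA", "spB", "spB"),
    plot_id = c("p1", "p1", "p1", "p1", "p2", "p2"),
    plot_area = 1,
    census_date = c(2000, 2001, 2000, 2001, 2000, 2001),
    height = c(150, 260, 300, 380, 100, NA),
    status = c("alive", "alive", "alive", "alive", "alive", "dead"),
    stringsAsFactors = FALSE
  )
}

unit_allometry <- function() {
  data.frame(species = ".default", a = 1, b = 1, stringsAsFactors = FALSE)
}

# species x p matrix with an exact low-rank structure plus optional noise
low_rank_matrix <- function(n, p, rank, seed = 1, noise_sd = 0) {
  set.seed(seed)
  u <- matrix(rnorm(n * rank), n, rank)
  v <- matrix(rnorm(p * rank), p, rank)
  m <- u %*% t(v)
  if (noise_sd > 0) m <- m + matrix(rnorm(n * p, sd = noise_sd), n, p)
  m
}

# loadings matrix shaped like the 9 rate columns, for labeling tests
named_loadings <- function(values) {
  m <- matrix(values, ncol = length(values) / 9)
  rownames(m) <- rate_columns()$column
  colnames(m) <- paste0("PC", seq_len(ncol(m)))
  m
}

# quick survival observation generator from known annual rates
make_survival_obs <- function(s_true, n_obs, t_choices = c(1, 5), seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(s_true), function(j) {
    t <- sample(t_choices, n_obs[j], replace = TRUE)
    data.frame(species = sprintf("sp%03d", j),
               alive = as.integer(runif(n_obs[j]) < s_true[j]^t),
               t = t, stringsAsFactors = FALSE)
  }))
}

make_growth_obs <- function(g_true, sigma_true, n_obs, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(g_true), function(j) {
    data.frame(species = sprintf("sp%03d", j),
               y = rnorm(n_obs[j], g_true[j], sigma_true[j]),
               stringsAsFactors = FALSE)
  }))
}

fast_config <- function(...) {
  args <- list(...)
  defaults <- list(n_chains = 2L, n_iter = 500L, n_burnin = 250L,
                   n_permutations = 200L)
  defaults[names(args)] <- args
  do.call(pipeline_config, defaults)
}
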