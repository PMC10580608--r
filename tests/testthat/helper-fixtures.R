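# Shared fixtures built in code.

norm_cols <- function() paste0(acer_domains(), "_norm")

# A tibble of normalized profiles from a matrix/vector of values in [0,1].
profile_tbl <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  colnames(x) <- norm_cols()
  tibble::as_tibble(x)
}

# Diagonal profiles (v, v, v, v, v): every CHC saturation equals v.
diag_profiles <- function(v) profile_tbl(matrix(rep(v, 5), ncol = 5))

# Small cohort used across IO/CLI tests.
small_cohort <- function(n = 30, seed = 11) {
  simulate_cohort(
    n = n, male = n %/% 2, education = rep(c(n %/% 4), 4) + c(n %% 4, 0, 0, 0),
    seed = seed
  )
}

# One shared trained surrogate (training is fast but not free); built lazily.
trained_mlp <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      fit <<- mlp_train(mlp_training_set(1000, seed = 42), seed = 1)
    }
    fit
  }
})
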