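# Shared fixtures, built once per test run and memoised.

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(8, seed = 101)
    cache
  }
})

small_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ex <- apply_exclusion(small_cohort())
      cache <<- prepare_model_table(ex$trials)
    }
    cache
  }
})

# one MAP fit of the angular cell-means model on the shared cohort
small_vm_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- gewls(error_deg ~ 0 + emotion:mask:intensity,
                      data = small_table(), family = "vonmises",
                      method = "map", seed = 101)
    cache
  }
})

small_px_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- gewls(radius_px ~ 0 + emotion:mask:intensity,
                      data = small_table(), family = "gaussian",
                      method = "map", seed = 101)
    cache
  }
})

# power-series oracle for modified Bessel functions of the first kind
bessel_series <- function(x, nu, terms = 40) {
  m <- 0:terms
  sum((x / 2)^(2 * m + nu) / (factorial(m) * factorial(m + nu)))
}

# hand-built cell-posterior object for contrast unit tests
fake_cellpost <- function(mu_list, cv_list) {
  cells <- do.call(rbind, lapply(names(mu_list), function(k) {
    p <- strsplit(k, "\\.")[[1]]
    data.frame(emotion = p[1], mask = p[2], intensity = p[3])
  }))
  structure(list(cells = cells, family = "vonmises",
                 mu_deg = do.call(cbind, mu_list),
                 circvar = do.call(cbind, cv_list)),
            class = "gew_cellpost")
}
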