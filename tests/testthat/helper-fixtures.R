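# shared fixtures; everything generated in code

fix_harmonic <- function(omega = 2e-3, gap = 0.15, tdm = 0.2, mass = 2000)
  harmonic_fixture(omega = omega, gap = gap, tdm = tdm, mass = mass)

# cached NaI model (reading the YAML once is enough)
nai_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- nai_model()
    m
  }
})

# build a population_trace by hand from a matrix of populations
make_trace <- function(pops, dt_fs = 0.5, beta = 1L, id = 1L) {
  structure(list(geometry_id = id,
                 times_fs = dt_fs * (seq_len(nrow(pops)) - 1L),
                 coeff = NULL, pops = pops, beta = beta,
                 polarization_used = NULL),
            class = "population_trace")
}

# random two-state traces with weak, non-monotone transfer (valid populations)
random_traces <- function(n_traces, n_times, seed, scale = 1e-3) {
  set.seed(seed)
  lapply(seq_len(n_traces), function(k) {
    # smooth random excited population, non-negative, starting at 0
    x <- cumsum(stats::rnorm(n_times))
    x <- (x - x[1])^2
    p2 <- scale * x / max(x, 1)
    make_trace(cbind(1 - p2, p2), id = k)
  })
}

# small deterministic Wigner sample set for the NaI model
nai_small_samples <- local({
  cache <- NULL
  function(n = 2000, seed = 42) {
    if (is.null(cache)) {
      m <- nai_cached()
      wf <- qd_ground_state(m)
      wd <- wigner_distribution(wf)
      cache <<- list(wf = wf, wd = wd, model = m)
    }
    wigner_sample(cache$wd, n, cache$model$mass, seed)
  }
})
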