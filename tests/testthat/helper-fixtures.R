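# Shared fixtures, built in code. Expensive objects (trained models, the
# desk end-to-end run) are memoised for the session so several tests can
# share one training run.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# flat mid-gray test image
flat_image <- function(w = 120, h = 120, value = 50, spacing = 0.1) {
  ceph_image(matrix(value, h, w), spacing_mm = spacing)
}

# a bright/dark separable toy patch problem
toy_patches <- function(n = 200, side = 15, seed = 1) {
  set.seed(seed)
  X <- array(0, c(side, side, n))
  y <- rep(c(1L, 0L), length.out = n)
  for (i in seq_len(n)) {
    X[, , i] <- matrix(stats::rnorm(side^2, mean = if (y[i] == 1) 180 else 40,
                                    sd = 20), side, side)
  }
  X <- pmin(pmax(X, 0), 255)
  list(X = X, y = y)
}

# small trained model on the toy problem, shared across tests
toy_model <- function() {
  cache_fixture("toy_model", function() {
    tp <- toy_patches(n = 240, side = 15, seed = 42)
    m <- build_model(desk_architecture(), 15, seed = 3)
    m <- train_model(m, tp$X, desk_training_config(max_steps = 250,
                                                   rng_seed = 7),
                     labels = tp$y)
    list(model = m, data = tp)
  })
}

# small synthetic case set, shared
synth_cases <- function(n = 3, seed = 11) {
  cache_fixture(sprintf("synth_%d_%d", n, seed), function() {
    cfg <- desk_synthetic_config(rng_seed = seed)
    lapply(seq_len(n), generate_case, cfg = cfg)
  })
}

# the full desk-profile benchmark, shared between acceptance checks
desk_end_to_end <- function() {
  cache_fixture("desk_e2e", function() {
    bm <- desk_benchmark(n_train = 8, n_test = 3, seed = 1L)
    list(errors_mm = bm$results$error_mm, inside_roi = bm$results$inside_roi,
         fallbacks = bm$results$fallback, report = bm$report)
  })
}

expect_close <- function(object, expected, tol = 1e-9) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max dev %.3g <= %.3g",
                              max(abs(object - expected)), tol))
}
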