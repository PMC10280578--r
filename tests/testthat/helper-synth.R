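# Shared fixtures, all built in code.

# Two well-separated Gaussian clouds in 2-D.
two_clouds <- function(n_per = 20, sep = 6, seed = 1) {
  withr_seed <- function(s, f) hyperseed:::with_seed(s, f)
  withr_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * 2), n_per),
               matrix(rnorm(n_per * 2, mean = sep), n_per))
    list(X = X, y = factor(rep(c("a", "b"), each = n_per)))
  })
}

# Small multi-class spectra table from the generator.
small_table <- function(seed = 1, n_per_class = 12, n_bands = 40) {
  win <- seq(floor(n_bands * 0.4), ceiling(n_bands * 0.6))
  cfg <- synth_config(n_per_class = n_per_class, n_bands = n_bands,
                      window_idx = win, n_informative_extra = 4,
                      class_sep = 0.02, seed = seed)
  sample_dataset(cfg)$table
}

withr_local_tempdir <- function(env = parent.frame()) {
  dir <- tempfile("hyperseed")
  dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE), envir = env)
  dir
}

# Planted sparse design: the generator's null spectra (class_sep = 0)
# with a strong class signal added at n_inf bands. Sign patterns are
# class-discriminative (no constant-sign band) and pairwise distinct
# across bands and classes, so every planted band carries its own
# information.
planted_dataset <- function(seed, amp = 0.03, n_inf = 10) {
  cfg <- synth_config(class_sep = 0, seed = seed)
  ds <- sample_dataset(cfg)
  hyperseed:::with_seed(seed + 1000L, {
    inf <- sort(sample(cfg$n_bands, n_inf))
    K <- cfg$n_classes
    draw <- function() matrix(sample(c(-1, 1), K * n_inf, replace = TRUE),
                              K, n_inf)
    ok <- function(U) {
      all(abs(colSums(U)) < K) &&
        !anyDuplicated(apply(U, 2, paste, collapse = "")) &&
        !anyDuplicated(apply(U, 1, paste, collapse = ""))
    }
    U <- draw()
    while (!ok(U)) U <- draw()
    cls <- as.integer(ds$table$labels)
    X <- ds$table$X
    # the planted signal rides on the per-seed gain, like real
    # reflectance structure, so scatter correction preserves it
    X[, inf] <- X[, inf] + amp * U[cls, ] * ds$truth$gains
    list(table = spectra_table(X, labels = ds$table$labels),
         informative = inf)
  })
}

# Cube with two bright square seeds on a dark background.
two_seed_cube <- function(nr = 20, nc = 30, nb = 8, value = 0.8,
                          background = 0.01) {
  a <- array(background, c(nr, nc, nb))
  a[3:8, 3:8, ] <- value       # 36 pixels
  a[12:18, 20:26, ] <- value   # 49 pixels
  spectral_cube(a)
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
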