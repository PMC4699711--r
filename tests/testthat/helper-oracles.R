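# Independent oracles used across the suite. These are deliberately written
# as direct, slow implementations so they share no code with the package
# internals they check.

# brute-force O(N^2) SampEn pair counts: ordered pairs (i, j), i != j,
# templates starting at 1..N-m, Chebyshev distance strictly below r
oracle_sampen_counts <- function(x, m, r) {
  M <- length(x) - m
  B <- 0; A <- 0
  for (i in 1:(M - 1)) {
    for (j in (i + 1):M) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) < r) {
        B <- B + 2
        if (abs(x[i + m] - x[j + m]) < r) A <- A + 2
      }
    }
  }
  c(B = B, A = A)
}

oracle_sampen <- function(x, m = 3, r_frac = 0.6) {
  cnt <- oracle_sampen_counts(x, m, r_frac * sd(x))
  if (cnt["B"] == 0 || cnt["A"] == 0) return(NA_real_)
  -log(cnt[["A"]] / cnt[["B"]])
}

# recursive flood-fill component labeling on a 3D logical array
oracle_label <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & nz <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask & lab == 0)) {
    if (lab[start] != 0) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        p <- ijk + offs[o, ]
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
        if (mask[w] && lab[w] == 0) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# small cohort used by several tests; cheap enough to regenerate
tiny_cohort <- function(seed = 5, n_per_group = 3, grid = c(10, 10, 8),
                        t = 40, ...) {
  generate_cohort(cohort_config(n_patients = n_per_group,
                                n_controls = n_per_group,
                                grid_shape = grid, n_timepoints = t,
                                seed = seed, ...))
}

# random bold_series for operator-level tests
random_series <- function(dims = c(6, 5, 4), t = 30, tr = 2, seed = 1) {
  withr_seed <- seed
  set.seed(withr_seed)
  bold_series(array(rnorm(prod(dims) * t), c(dims, t)),
              voxel_size_mm = 3, tr_s = tr)
}
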