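# programmatic fixtures shared across test files

# crisp two-class stack: a rectangular habitat block with 0/1 memberships
# and zero variance everywhere
crisp_stack <- function(nr = 12, nc = 12, block_rows = 4:7, block_cols = 4:8,
                        cell_size = 2) {
  hab <- matrix(0, nr, nc)
  hab[block_rows, block_cols] <- 1
  membership <- array(c(hab, 1 - hab), dim = c(nr, nc, 2))
  class_stack(membership, array(0, dim = c(nr, nc, 2)),
              c("habitat", "matrix"), cell_size)
}

# random valid K-class stack: per-cell memberships from normalized uniforms,
# variance a seeded fraction of the Beta-feasible bound
random_stack <- function(seed, nr = 8, nc = 8, k = 4, cell_size = 1,
                         labels = c("woodland", "grassland", "wetland",
                                    "urban")[seq_len(k)]) {
  withr::with_seed(seed, {
    raw <- array(runif(nr * nc * k, 0.05, 1), dim = c(nr, nc, k))
    s <- apply(raw, c(1, 2), sum)
    membership <- raw / array(s, dim = dim(raw))
    frac <- array(runif(nr * nc * k, 0.05, 0.5), dim = dim(raw))
    variance <- frac * membership * (1 - membership)
    class_stack(membership, variance, labels, cell_size)
  })
}

# random strictly positive cost surface
random_cost <- function(seed, nr, nc, lo = 0.5, hi = 10) {
  withr::with_seed(seed, matrix(runif(nr * nc, lo, hi), nr, nc))
}

# profile for two-class (habitat/matrix) stacks
two_class_profile <- function(...) {
  species_profile(H = c(0.9, 0.1), F_ = c(0.8, 0.2), R = c(1, 5),
                  class_labels = c("habitat", "matrix"),
                  deleterious = character(0), ...)
}
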