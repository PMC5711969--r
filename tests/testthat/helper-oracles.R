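# Shared test helpers: brute-force oracles and tiny fixtures.

# Conditional P(Z_i = high | rest of z) computed from the enumerated PMF.
cond_from_pmf <- function(pmf, z, i, cod) {
  zv <- as.vector(z)
  rest <- apply(pmf$states[, -i, drop = FALSE], 1,
                function(r) all(r == zv[-i]))
  num <- sum(pmf$prob[rest & pmf$states[, i] == cod$high])
  den <- sum(pmf$prob[rest])
  num / den
}

# Random small design matrix for an n-pixel lattice.
rand_design <- function(n, r = 2) {
  cbind(1, matrix(runif(n * (r - 1), -1, 1), n, r - 1))
}

# A miniature labelled scene with class-dependent band means: spatially
# blocky truth (half-plane plus noise-free structure kept trivial).
tiny_scene <- function(nr = 8, nc = 8, delta = 1.2, seed = 1) {
  set.seed(seed)
  fg <- matrix(FALSE, nr, nc)
  fg[, seq_len(nc %/% 2)] <- TRUE
  img <- array(0, c(nr, nc, 3))
  for (ch in 1:3) {
    img[, , ch] <- antilogit(ifelse(fg, delta, -delta) + rnorm(nr * nc, 0, 0.5))
  }
  list(image = img, foreground = fg, split = "train", seed = seed,
       id = sprintf("tiny_%d", seed))
}

# Fast, small scene set for pipeline tests (shares the package generator).
small_scene_set <- function(size = 24, k = 2, seed = 99, sd = 1.2) {
  generate_scenes(size, n = 3 * k,
                  split = c(train = k, validation = k, test = k),
                  bg = gmrf_spec(c(0.75, 0.65, 0.55), sd = sd),
                  fg = gmrf_spec(c(0.6, 0.5, 0.7), sd = sd),
                  seed = seed)
}
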