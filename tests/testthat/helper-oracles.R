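# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths (scalar loops, base svd only).

# unaccelerated proximal gradient on the stable-decomposition objective,
# run to stagnation
ista_lrsd <- function(M, lambda, mu, max_iter = 20000, tol = 1e-12) {
  L <- S <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(max_iter)) {
    R <- M - L - S
    s <- svd(L + 0.5 * R)
    L_new <- s$u %*% (pmax(s$d - mu / 2, 0) * t(s$v))
    G <- S + 0.5 * R
    S_new <- sign(G) * pmax(abs(G) - lambda * mu / 2, 0)
    d <- sqrt(sum((L_new - L)^2) + sum((S_new - S)^2))
    L <- L_new
    S <- S_new
    if (d < tol) break
  }
  list(L = L, S = S, iterations = i)
}

# exhaustive queue-based flood fill with seed-relative admission
flood_fill_oracle <- function(block, seed_rc1, threshold) {
  nr <- nrow(block)
  nc <- ncol(block)
  sv <- block[seed_rc1[1], seed_rc1[2]]
  admissible <- abs(block - sv) <= threshold
  out <- matrix(0, nr, nc)
  if (!admissible[seed_rc1[1], seed_rc1[2]]) return(out)
  queue <- list(seed_rc1)
  out[seed_rc1[1], seed_rc1[2]] <- 1
  while (length(queue) > 0) {
    p <- queue[[1]]
    queue <- queue[-1]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- p[1] + dr
      cc <- p[2] + dc
      if (r < 1 || r > nr || cc < 1 || cc > nc) next
      if (out[r, cc] == 0 && admissible[r, cc]) {
        out[r, cc] <- 1
        queue[[length(queue) + 1]] <- c(r, cc)
      }
    }
  }
  out
}

# 8-connected component count by repeated scalar flood fill
count_components_oracle <- function(mask) {
  mask <- mask > 0
  n <- 0
  while (any(mask)) {
    n <- n + 1
    start <- which(mask, arr.ind = TRUE)[1, ]
    comp <- flood_fill_oracle((!mask) * 1, unname(start), threshold = 0.5)
    mask <- mask & !(comp > 0)
  }
  n
}

# small, fast phantom for unit tests (not the study-condition default)
small_phantom_spec <- function(seed = 1, n_vessels = 3, n_blobs = 2, ...) {
  phantom_spec(height = 192, width = 192, n_vessels = n_vessels,
               n_blobs = n_blobs, blob_sigma_px = c(5, 8),
               macula_radius_px = 35, rng_seed = seed, ...)
}

clamp_ref <- function(x) pmin(pmax(x, 0), 1)

# shared cache so expensive fixtures are built once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
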