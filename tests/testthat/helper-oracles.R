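# Independent oracles used across the suite. These deliberately do not share
# code paths with the package implementation.

# Generic n-receptor receptor-noise model in matrix form:
# dS^2 = df' A df with A = V^-1 - (V^-1 1 1' V^-1) / (1' V^-1 1), V = diag(e^2)
# (the quadratic form that projects out the achromatic direction).
rnl_matrix_oracle <- function(qA, qB, e) {
  df <- log(qA) - log(qB)
  Vinv <- diag(1 / e^2)
  one <- rep(1, length(e))
  A <- Vinv - (Vinv %*% one %*% t(one) %*% Vinv) / drop(t(one) %*% Vinv %*% one)
  sqrt(drop(t(df) %*% A %*% df))
}

# Tetrahedral coordinates from explicitly tabulated vertices (vertex
# distance 0.75), written out numerically rather than derived.
tetra_oracle_vertices <- rbind(
  uv = c(0.000000000000000, 0.000000000000000, 0.75),
  sw = c(0.000000000000000, 0.707106781186548, -0.25),
  mw = c(-0.612372435695794, -0.353553390593274, -0.25),
  lw = c(0.612372435695794, -0.353553390593274, -0.25))

tetra_oracle_norm <- function(rel) {
  p <- colSums(tetra_oracle_vertices * rel)
  sqrt(sum(p^2))
}

# Kruskal-Wallis H from first principles (tie-corrected).
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# A stack rendered with no pixel noise, for calibration round-trip checks.
noiseless_stack <- function(fish_level = 0.30, bg_level = 0.1897,
                            camera = camera_model(), side = 24) {
  render_stack(flat_spectrum(fish_level), flat_spectrum(bg_level),
               camera = camera, nrow = side, ncol = side)
}

fitted_curve_for <- function(camera) {
  std <- grey_standard_set()
  fit_linearization(photograph_standards(std, camera), std)
}

random_catch_set <- function() {
  q <- stats::runif(5, 0.05, 1)
  names(q) <- c("uv", "sw", "mw", "lw", "dbl")
  structure(q, class = "quantum_catch_set")
}
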