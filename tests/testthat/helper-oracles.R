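# Shared fixtures and independent brute-force oracles.  Oracles deliberately
# use naive loops / explicit arithmetic, never the package's own code path.

# small geometry used across tests: 2 rings (19 sites), bands assigned
tiny_geometry <- function(supra_fraction = 0.5) {
  assign_layer_bands(build_hex_geometry(2, 0.05), supra_fraction = supra_fraction)
}

# random raw recording for a given geometry
random_recording <- function(geometry, n_samples = 60, onset = 45,
                             base = 100) {
  n <- sum(geometry$active)
  mat <- matrix(base + runif(n * n_samples, -1, 1), nrow = n)
  vsd_recording(mat, geometry, onset)
}

# element-wise dI/I with its own baseline logic (percent)
oracle_dii <- function(mat, onset, dt = 1.274, window_ms = 50) {
  n_base <- floor(window_ms / dt)
  out <- matrix(NA_real_, nrow(mat), ncol(mat))
  for (i in seq_len(nrow(mat))) {
    rest <- mean(mat[i, (onset - n_base + 1):onset])
    for (j in seq_len(ncol(mat))) out[i, j] <- 100 * (rest - mat[i, j]) / rest
  }
  out
}

# amplitude/latency by explicit loop; onset is the 0-based stimulus sample
# (baseline = the 39 samples before it, search = the following 100 ms)
oracle_amp_lat <- function(trace, onset, dt = 1.274, search_ms = 100,
                           base_ms = 50) {
  n_base <- floor(base_ms / dt)
  baseline <- mean(trace[(onset - n_base + 1):onset])  # R idx of samples onset-39..onset-1
  n_search <- floor(search_ms / dt)
  best <- -Inf; best_j <- NA
  for (j in (onset + 2):min(length(trace), onset + 1 + n_search)) {
    v <- trace[j] - baseline
    if (v > best) { best <- v; best_j <- j }
  }
  list(amplitude = best, latency_ms = (best_j - 1 - onset) * dt)
}

# six nearest in-band diodes by exhaustive distance sort
oracle_six <- function(geometry, layer, exy) {
  sub <- geometry[geometry$active & geometry$layer_band == layer, ]
  d_el <- sqrt((sub$x - exy[1])^2 + (sub$y - exy[2])^2)
  seed <- sub[order(d_el, sub$site_id)[1], ]
  d_seed <- sqrt((sub$x - seed$x)^2 + (sub$y - seed$y)^2)
  sort(sub$site_id[order(d_seed, sub$site_id)[1:6]])
}

# F for one model term by explicit projection matrices: the effect SS is the
# RSS drop from X_reduced to X_term; the error MS comes from X_error (the
# full design).
oracle_projection_F <- function(y, X_term, X_reduced, df_effect,
                                X_error = X_term) {
  P <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  n <- length(y)
  rss_t <- sum(((diag(n) - P(X_term)) %*% y)^2)
  rss_r <- sum(((diag(n) - P(X_reduced)) %*% y)^2)
  rss_e <- sum(((diag(n) - P(X_error)) %*% y)^2)
  df_res <- n - qr(X_error)$rank
  ((rss_r - rss_t) / df_effect) / (rss_e / df_res)
}

# studentized range table values, alpha = 0.05 (standard published tables)
q_table_05 <- list(
  "16" = c("2" = 3.00, "3" = 3.65, "4" = 4.05),
  "12" = c("2" = 3.08, "3" = 3.77, "4" = 4.20),
  "20" = c("2" = 2.95, "3" = 3.58, "4" = 3.96)
)

# Newman-Keuls decisions by brute-force stepdown enumeration with tabulated
# critical values (independent of ptukey)
oracle_nk <- function(means, mse, n, df) {
  k <- length(means)
  qt <- q_table_05[[as.character(df)]]
  ord <- order(means); m <- means[ord]
  sig <- matrix(NA, k, k)
  for (r in k:2) for (i in 1:(k - r + 1)) {
    j <- i + r - 1
    blocked <- FALSE
    for (ii in 1:i) for (jj in j:k)
      if ((jj - ii) > (j - i) && isFALSE(sig[ii, jj])) blocked <- TRUE
    if (blocked) { sig[i, j] <- FALSE; next }
    q <- (m[j] - m[i]) / sqrt(mse / n)
    sig[i, j] <- q > qt[[as.character(r)]]
  }
  dimnames(sig) <- list(names(m), names(m))
  sig
}
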