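test_that("fractional fluorescence matches the defining arithmetic", {
  g <- tiny_geometry()
  n <- sum(g$active)
  # constant trace -> identically zero
  rec <- vsd_recording(matrix(250, n, 60), g, 45)
  expect_true(all(fractional_fluorescence(rec)$values == 0))
  # I_rest = 100, dip to 99.66 -> 0.34 %
  mat <- matrix(100, n, 60)
  mat[, 50] <- 99.66
  sig <- fractional_fluorescence(vsd_recording(mat, g, 45))
  expect_equal(sig$values[1, 50], 0.34, tolerance = 1e-10)
  expect_true(all(abs(sig$values[, 1:45]) < 1e-12))
})

test_that("fractional fluorescence equals the element-wise oracle", {
  set.seed(101)
  g <- tiny_geometry()
  for (rep in 1:5) {
    rec <- random_recording(g)
    got <- fractional_fluorescence(rec)$values
    expect_equal(got, oracle_dii(rec$intensities, rec$stimulus_onset),
                 tolerance = 1e-12)
  }
})

test_that("trial averaging is the element-wise mean", {
  g <- tiny_geometry()
  set.seed(7)
  sigs <- lapply(1:3, function(i) fractional_fluorescence(random_recording(g)))
  avg <- average_trials(sigs)
  brute <- (sigs[[1]]$values + sigs[[2]]$values + sigs[[3]]$values) / 3
  expect_equal(avg$values, brute, tolerance = 1e-12)
  expect_equal(avg$n_trials_averaged, 3L)
  # identical trials average to themselves
  same <- average_trials(list(sigs[[1]], sigs[[1]], sigs[[1]]))
  expect_equal(same$values, sigs[[1]]$values)
  # cancellation: x and -x average to 0 (plus a zero signal)
  s_pos <- sigs[[1]]; s_neg <- sigs[[1]]; s_neg$values <- -s_neg$values
  expect_true(all(abs(average_trials(list(s_pos, s_neg))$values) < 1e-12))
})

test_that("averaging rejects mismatched trials", {
  g <- tiny_geometry()
  s1 <- fractional_fluorescence(random_recording(g, n_samples = 60))
  s2 <- fractional_fluorescence(random_recording(g, n_samples = 50))
  expect_error(average_trials(list(s1, s2)), class = "vsdlamina_invalid_parameter")
})

test_that("dI/I of averaged raw trials equals averaged dI/I at common baseline", {
  g <- tiny_geometry()
  n <- sum(g$active)
  set.seed(12)
  for (rep in 1:5) {
    base <- matrix(100 + runif(n), n, 60)  # same baseline every trial
    trials <- lapply(1:3, function(i) {
      m <- base
      m[, 46:60] <- m[, 46:60] * (1 - matrix(runif(n * 15, 0, 0.01), n)) # evoked dips
      m
    })
    raw_avg <- Reduce(`+`, trials) / 3
    a <- fractional_fluorescence(vsd_recording(raw_avg, g, 45))$values
    b <- average_trials(lapply(trials, function(m)
      fractional_fluorescence(vsd_recording(m, g, 45))))$values
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("six-diode layer signal matches the exhaustive-sort oracle", {
  set.seed(33)
  g <- tiny_geometry()
  for (rep in 1:20) {
    sig <- fractional_fluorescence(random_recording(g))
    exy <- c(runif(1, -0.1, 0.1), runif(1, -0.1, 0.1))
    ly <- sample(c("supragranular", "infragranular"), 1)
    got <- layer_signal(sig, g, ly, electrode_xy = exy)
    ids <- oracle_six(g, ly, exy)
    expect_setequal(attr(got, "site_ids"), ids)
    act_ids <- g$site_id[g$active]
    brute <- colMeans(sig$values[match(ids, act_ids), ])
    expect_equal(as.numeric(got), brute, tolerance = 1e-12)
  }
})

test_that("an electrode exactly on a site selects that site", {
  g <- tiny_geometry()
  sub <- g[g$active & g$layer_band == "infragranular", ]
  target <- sub[3, ]
  sig <- fractional_fluorescence(random_recording(g))
  got <- layer_signal(sig, g, "infragranular", electrode_xy = c(target$x, target$y))
  expect_true(target$site_id %in% attr(got, "site_ids"))
})

test_that("layer signal requires six in-band sites", {
  g <- assign_layer_bands(build_hex_geometry(2, 0.05), supra_fraction = 0.12)
  sig <- fractional_fluorescence(random_recording(g))
  expect_error(layer_signal(sig, g, "supragranular"),
               class = "vsdlamina_config_error")
})

test_that("amplitude/latency match the argmax oracle on random traces", {
  set.seed(55)
  for (rep in 1:50) {
    trace <- rnorm(150)
    al <- amplitude_latency(trace, 60)
    or <- oracle_amp_lat(trace, 60)
    expect_equal(al$amplitude, or$amplitude, tolerance = 1e-12)
    expect_equal(al$latency_ms, or$latency_ms, tolerance = 1e-12)
  }
})

test_that("amplitude is offset-invariant and latency scale-invariant", {
  set.seed(56)
  trace <- c(rep(0, 60), dnorm(seq(-3, 5, length.out = 90))) + rnorm(150, 0, 0.01)
  a0 <- amplitude_latency(trace, 60)
  a_shift <- amplitude_latency(trace + 5.7, 60)
  expect_equal(a0$amplitude, a_shift$amplitude, tolerance = 1e-10)
  expect_equal(a0$latency_ms, a_shift$latency_ms)
  a_scaled <- amplitude_latency(trace * 3.1, 60)
  expect_equal(a_scaled$latency_ms, a0$latency_ms)
  expect_equal(a_scaled$amplitude, 3.1 * a0$amplitude, tolerance = 1e-10)
})

test_that("a flat trace reports zero amplitude with a flag", {
  al <- amplitude_latency(rep(2.5, 150), 60)
  expect_equal(al$amplitude, 0)
  expect_equal(al$flag, "flat")
})

test_that("reference normalisation is a pure rescale", {
  expect_equal(normalize_to_reference(0.17, 0.34), 0.5)
  expect_equal(normalize_to_reference(0.34, 0.34), 1.0)
  set.seed(3)
  x <- matrix(runif(20), 4)
  expect_equal(normalize_to_reference(x, 0.34), x / 0.34)
  expect_error(normalize_to_reference(x, 0), class = "vsdlamina_invalid_parameter")
})

test_that("activity maps scale to the session maximum", {
  g <- tiny_geometry()
  sig <- fractional_fluorescence(random_recording(g))
  am <- activity_map(sig, g, frame_samples = c(10, 50))
  expect_equal(nrow(am), 2 * sum(g$active))
  expect_lte(max(abs(am$value)), 1)
})

test_that("laminar heatmap separates a two-band input into two plateaus", {
  g <- tiny_geometry()
  n <- sum(g$active)
  mat <- matrix(100, n, 60)
  act <- g[g$active, ]
  supra_rows <- which(act$layer_band == "supragranular")
  infra_rows <- which(act$layer_band == "infragranular")
  mat[supra_rows, 46:60] <- 100 * (1 - 0.004)   # 0.4 %
  mat[infra_rows, 46:60] <- 100 * (1 - 0.002)   # 0.2 %
  sig <- fractional_fluorescence(vsd_recording(mat, g, 45))
  hm <- layer_time_heatmap(list(sig), g, n_depth_bins = 4)
  expect_equal(dim(hm), c(4, 60))
  # shallow bins at 0.4, deep bins at 0.2 during the response
  expect_equal(hm[1, 50], 0.4, tolerance = 1e-10)
  expect_equal(hm[4, 50], 0.2, tolerance = 1e-10)
  expect_true(all(abs(hm[, 1:45]) < 1e-12))
  expect_error(layer_time_heatmap(list(), g), class = "vsdlamina_invalid_parameter")
})

test_that("heatmap of a uniform field is constant across bins", {
  g <- tiny_geometry()
  n <- sum(g$active)
  mat <- matrix(200, n, 60); mat[, 50:60] <- 199
  sig <- fractional_fluorescence(vsd_recording(mat, g, 45))
  hm <- layer_time_heatmap(list(sig), g, n_depth_bins = 5)
  expect_true(all(abs(hm[, 55] - hm[1, 55]) < 1e-12))
})
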