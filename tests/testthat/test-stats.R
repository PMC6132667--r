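test_that("two-group one-way F equals the squared pooled t statistic", {
  set.seed(201)
  x <- rnorm(10, 0); y <- rnorm(12, 1)
  res <- anova_oneway(c(x, y), rep(c("a", "b"), c(10, 12)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-10)
})

test_that("one-way F matches the hand-computed closed form", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  # group means 2,3,4; SSB = 3*(1+0+1) = 6 on 2 df; SSW = 6 on 6 df; F = 3
  res <- anova_oneway(vals, grp)
  expect_equal(res$F[1], 3, tolerance = 1e-12)
  expect_equal(res$df_num[1], 2)
  expect_equal(res$df_den[1], 6)
  expect_equal(res$ss[1], 6, tolerance = 1e-12)
  expect_equal(res$p[1], pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("identical observations are flagged degenerate", {
  res <- anova_oneway(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(attr(res, "flag"), "degenerate")
})

test_that("one-way and factorial F match the projection-matrix oracle", {
  set.seed(202)
  for (rep in 1:20) {
    # one-way, 3 groups x 6
    g <- gl(3, 6)
    y <- rnorm(18)
    res <- anova_oneway(y, g)
    X_full <- model.matrix(~g); X_red <- matrix(1, 18, 1)
    expect_equal(res$F[1], oracle_projection_F(y, X_full, X_red, 2),
                 tolerance = 1e-10)
    # balanced 2x4 factorial
    a <- gl(2, 12); b <- gl(4, 3, 24)
    y2 <- rnorm(24)
    res2 <- anova_factorial(y2, a, b)
    Xf <- model.matrix(~a * b)
    Xab <- model.matrix(~a + b)
    FA <- oracle_projection_F(y2, Xab, model.matrix(~b), 1, X_error = Xf)
    FB <- oracle_projection_F(y2, Xab, model.matrix(~a), 3, X_error = Xf)
    FI <- oracle_projection_F(y2, Xf, Xab, 3)
    # balanced: sequential and marginal SS coincide
    expect_equal(res2$F[res2$effect == "A"], FA, tolerance = 1e-10)
    expect_equal(res2$F[res2$effect == "B"], FB, tolerance = 1e-10)
    expect_equal(res2$F[res2$effect == "A:B"], FI, tolerance = 1e-10)
  }
})

test_that("unbalanced factorials use Type II sums of squares", {
  set.seed(203)
  a <- factor(rep(c("x", "y"), c(16, 11)))
  b <- factor(c(rep(c("u", "v"), 8), rep(c("u", "v"), c(6, 5))))
  y <- rnorm(27) + (a == "y") * 0.8
  res <- anova_factorial(y, a, b)
  # Type II oracle: each main effect adjusted for the other, interaction last
  rss_ab <- sum(resid(lm(y ~ a + b))^2)
  rss_b <- sum(resid(lm(y ~ b))^2)
  rss_a <- sum(resid(lm(y ~ a))^2)
  rss_full <- sum(resid(lm(y ~ a * b))^2)
  df_res <- 27 - 4
  expect_equal(res$F[res$effect == "A"],
               (rss_b - rss_ab) / (rss_full / df_res), tolerance = 1e-10)
  expect_equal(res$F[res$effect == "B"],
               (rss_a - rss_ab) / (rss_full / df_res), tolerance = 1e-10)
  expect_equal(res$F[res$effect == "A:B"],
               (rss_ab - rss_full) / (rss_full / df_res), tolerance = 1e-10)
  expect_error(anova_factorial(y[1:4], factor(c("x", "x", "y", "y")),
                               factor(c("u", "v", "u", "u"))),
               class = "vsdlamina_invalid_parameter")
})

test_that("an additive zero-noise factorial has zero interaction SS", {
  a <- gl(2, 8); b <- gl(4, 2, 16)
  y <- 2 * as.numeric(a) + 0.5 * as.numeric(b) + rnorm(16, 0, 1e-8)
  res <- suppressWarnings(anova_factorial(y, a, b))
  expect_lt(res$ss[res$effect == "A:B"], 1e-12)
})

test_that("the split-plot ANOVA matches the contrast oracle on balanced designs", {
  set.seed(204)
  for (rep in 1:10) {
    G <- 3; npg <- 6
    subj <- rep(seq_len(G * npg), each = 2)
    grp <- rep(rep(letters[1:G], each = npg), each = 2)
    w <- rep(c("t1", "t2"), G * npg)
    y <- rnorm(2 * G * npg) + rep(rnorm(G * npg, 0, 1), each = 2) +
      (grp == "b") * 0.5 + (w == "t2") * 0.7
    res <- anova_mixed(y, grp, w, subj)
    # oracle: between from one-way ANOVA on subject means; within and
    # interaction from the per-subject difference contrasts
    sm <- tapply(y, subj, mean)
    sg <- factor(tapply(grp, subj, `[`, 1), levels = letters[1:G])
    f_between <- anova(lm(sm ~ sg))[1, "F value"]
    d <- tapply(y[w == "t2"], subj[w == "t2"], mean) -
      tapply(y[w == "t1"], subj[w == "t1"], mean)
    c_s <- d / sqrt(2)
    n_tot <- G * npg
    ss_w <- sum(c_s)^2 / n_tot
    gm <- tapply(c_s, sg, mean)
    ss_gw <- sum(npg * (gm - mean(c_s))^2)
    ss_res <- sum((c_s - gm[sg])^2)
    df_res <- n_tot - G
    expect_equal(res$F[res$effect == "between"], f_between, tolerance = 1e-10)
    expect_equal(res$F[res$effect == "within"],
                 ss_w / (ss_res / df_res), tolerance = 1e-10)
    expect_equal(res$F[res$effect == "between:within"],
                 (ss_gw / (G - 1)) / (ss_res / df_res), tolerance = 1e-10)
    expect_equal(res$df_den[res$effect == "within"], df_res)
  }
})

test_that("the split-plot ANOVA handles unbalanced groups and recovers effects", {
  set.seed(205)
  ns <- c(12, 10, 5, 9)
  subj <- unlist(lapply(seq_along(ns), function(g) paste0("g", g, "_", seq_len(ns[g]))))
  grp <- rep(paste0("g", seq_along(ns)), ns)
  df <- data.frame(subject = rep(subj, each = 2), group = rep(grp, each = 2),
                   w = rep(c("t1", "t2"), sum(ns)))
  df$y <- rnorm(nrow(df), 0, 1) + (df$w == "t2") * 3 +
    (df$w == "t2") * (df$group == "g2") * -3
  res <- anova_mixed(df$y, df$group, df$w, df$subject)
  expect_equal(res$df_num[res$effect == "within"], 1)
  expect_equal(res$df_den[res$effect == "within"], sum(ns) - length(ns))
  expect_lt(res$p[res$effect == "within"], 1e-6)
  expect_lt(res$p[res$effect == "between:within"], 1e-6)
})

test_that("a cohort with no within effect yields a non-significant frequency term", {
  set.seed(206)
  pvals <- sapply(1:20, function(i) {
    subj <- rep(1:20, each = 2)
    grp <- rep(rep(c("a", "b"), each = 10), each = 2)
    w <- rep(c("t1", "t2"), 20)
    y <- rnorm(40) + rep(rnorm(20), each = 2)
    anova_mixed(y, grp, w, subj)$p[2]
  })
  expect_gt(mean(pvals > 0.05), 0.7)  # ~nominal behaviour, no systematic effect
})

test_that("Newman-Keuls with two groups coincides with Tukey", {
  set.seed(207)
  for (rep in 1:10) {
    means <- c(a = rnorm(1), b = rnorm(1))
    nk <- newman_keuls(means, mse = 1, df = 16, n_per_group = 5)
    tk <- posthoc_tukey(means, mse = 1, df = 16, n_per_group = 5)
    expect_equal(nk$significant, tk$significant)
    expect_equal(nk$p, tk$p, tolerance = 1e-12)
  }
})

test_that("equal group means are never declared different", {
  nk <- newman_keuls(c(a = 10, b = 10, c = 10), mse = 2, df = 12, n_per_group = 4)
  expect_false(any(nk$significant))
})

test_that("Newman-Keuls decisions match the tabulated stepdown enumeration", {
  # four groups, n = 5 each, df = 16, MSE chosen so decisions span the table
  cases <- list(
    list(means = c(g1 = 20.0, g2 = 21.2, g3 = 23.0, g4 = 24.9), mse = 2.0),
    list(means = c(g1 = 10.0, g2 = 10.3, g3 = 10.5, g4 = 10.6), mse = 2.0),
    list(means = c(g1 = 5.0, g2 = 8.0, g3 = 11.0, g4 = 14.0), mse = 4.0))
  for (cs in cases) {
    nk <- newman_keuls(cs$means, mse = cs$mse, df = 16, n_per_group = 5)
    oracle <- oracle_nk(cs$means, cs$mse, n = 5, df = 16)
    for (i in seq_len(nrow(nk))) {
      expect_identical(nk$significant[i],
                       oracle[nk$group_a[i], nk$group_b[i]],
                       info = paste(cs$means, collapse = ","))
    }
  }
})

test_that("Newman-Keuls significance never increases for interior pairs", {
  set.seed(208)
  for (rep in 1:30) {
    k <- sample(3:6, 1)
    means <- rnorm(k, 0, 2); names(means) <- paste0("g", 1:k)
    nk <- newman_keuls(means, mse = 1.5, df = 20, n_per_group = 6)
    ord <- names(sort(means))
    pos <- setNames(seq_along(ord), ord)
    sig <- matrix(NA, k, k)
    for (i in seq_len(nrow(nk)))
      sig[pos[nk$group_a[i]], pos[nk$group_b[i]]] <- nk$significant[i]
    # if an inner stretch is significant, every enclosing stretch must be too
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (isTRUE(sig[i, j])) {
        for (ii in 1:i) for (jj in j:k) {
          if (!is.na(sig[ii, jj])) expect_true(sig[ii, jj])
        }
      }
    }
  }
})

test_that("Bonferroni adjustment multiplies and caps p-values", {
  p <- c(ab = 0.01, ac = 0.3, bc = 0.5)
  res <- posthoc_bonferroni(p)
  expect_equal(res$p_adjusted, pmin(1, p * 3), ignore_attr = TRUE)
  expect_equal(res$significant, c(TRUE, FALSE, FALSE))
  expect_equal(posthoc_bonferroni(c(0.6, 0.9))$p_adjusted, c(1, 1))
})

test_that("Tukey comparisons agree with TukeyHSD on a fitted model", {
  set.seed(209)
  y <- rnorm(24) + rep(c(0, 0.5, 2), each = 8)
  g <- gl(3, 8, labels = c("a", "b", "c"))
  fit <- aov(y ~ g)
  th <- TukeyHSD(fit)$g
  om <- anova_oneway(y, g)
  tk <- posthoc_tukey(attr(om, "group_means"), attr(om, "mse"),
                      om$df_den[1], 8)
  key <- paste(tk$group_b, tk$group_a, sep = "-")
  expect_equal(tk$p, unname(th[key, "p adj"]), tolerance = 1e-8)
})
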