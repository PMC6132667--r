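# Inferential layer: one-way, two-way factorial and mixed (split-plot)
# ANOVA, with Newman-Keuls, Bonferroni and Tukey post hoc procedures.
#
# The omnibus fits are delegated to the standard linear-model machinery
# (stats::aov; car::Anova for Type II sums of squares in unbalanced
# factorials); the Newman-Keuls stepdown is authored here on top of the
# studentized-range distribution (ptukey/qtukey).

anova_row <- function(effect, df_num, df_den, F, p, ss) {
  data.frame(effect = effect, df_num = df_num, df_den = df_den,
             F = F, p = p, ss = ss)
}

#' One-way ANOVA
#'
#' Classical between-groups F test (\eqn{F = MS_{between}/MS_{within}}).
#'
#' @param values Numeric response.
#' @param group Factor (or coercible) of group labels.
#' @return data.frame of class \code{anova_result} with rows for the group
#'   effect and residuals: \code{effect}, \code{df_num}, \code{df_den},
#'   \code{F}, \code{p}, \code{ss}; attribute \code{"mse"} and
#'   \code{"flag"} (\code{"degenerate"} when the residual SS is 0).
#' @export
anova_oneway <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) abort("need >= 2 groups", "invalid_parameter")
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  ss_res <- tab["Residuals", "Sum Sq"]
  flag <- if (ss_res <= 1e-10 * max(1, sum(values^2))) "degenerate" else "ok"
  out <- rbind(
    anova_row("group", tab[1, "Df"], tab["Residuals", "Df"],
              tab[1, "F value"], tab[1, "Pr(>F)"], tab[1, "Sum Sq"]),
    anova_row("residuals", tab["Residuals", "Df"], NA, NA, NA, ss_res))
  structure(out, class = c("anova_result", "data.frame"),
            mse = tab["Residuals", "Mean Sq"], flag = flag,
            group_means = tapply(values, group, mean),
            group_n = as.integer(table(group)))
}

#' Two-way factorial ANOVA
#'
#' Balanced designs use the textbook sums-of-squares decomposition;
#' unbalanced designs use Type II sums of squares (main effects adjusted for
#' each other, interaction last), which matches main-effect reporting when
#' group sizes differ mildly.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factors (or coercible).
#' @return \code{anova_result} with rows A, B, A:B, residuals.
#' @export
anova_factorial <- function(values, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  if (any(table(a, b) == 0)) abort("empty design cell", "invalid_parameter")
  balanced <- length(unique(table(a, b))) == 1
  fit <- stats::lm(values ~ a * b)
  if (balanced) {
    tab <- stats::anova(fit)
  } else {
    tab <- car::Anova(fit, type = 2)
  }
  rn <- rownames(tab)
  res_i <- which(rn == "Residuals")
  df_den <- tab$Df[res_i]
  eff <- setdiff(seq_len(nrow(tab)), res_i)
  labels <- c(a = "A", b = "B", `a:b` = "A:B")
  out <- do.call(rbind, lapply(eff, function(i)
    anova_row(labels[[rn[i]]], tab$Df[i], df_den,
              tab$`F value`[i], tab$`Pr(>F)`[i], tab$`Sum Sq`[i])))
  out <- rbind(out, anova_row("residuals", df_den, NA, NA, NA, tab$`Sum Sq`[res_i]))
  structure(out, class = c("anova_result", "data.frame"),
            mse = tab$`Sum Sq`[res_i] / df_den,
            type = if (balanced) "I (balanced)" else "II")
}

#' Mixed (split-plot) ANOVA
#'
#' One between-subjects factor and one within-subjects factor.  The
#' between-subjects effect is tested against subjects-within-groups; the
#' within effect and the interaction against the within x subjects error
#' stratum.  No sphericity correction is applied (none is needed for a
#' two-level within factor); this is noted in the result's metadata.
#'
#' @param values Numeric response.
#' @param between Between-subjects factor.
#' @param within Within-subjects factor.
#' @param subject Subject identifier.
#' @return \code{anova_result} with rows between, within,
#'   between:within and the two error strata.
#' @export
anova_mixed <- function(values, between, within, subject) {
  g <- factor(between); w <- factor(within); s <- factor(subject)
  df <- data.frame(y = values, g = g, w = w, s = s)
  fit <- stats::aov(y ~ g * w + Error(s/w), data = df)
  sm <- summary(fit)
  tab_b <- sm[["Error: s"]][[1]]
  tab_w <- sm[[grep("Error: s", names(sm), fixed = TRUE)[2]]][[1]]
  get <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    tab[i, , drop = FALSE]
  }
  gb <- get(tab_b, "g"); rb <- get(tab_b, "Residuals")
  gw <- get(tab_w, "w"); gi <- get(tab_w, "g:w"); rw <- get(tab_w, "Residuals")
  out <- rbind(
    anova_row("between", gb$Df, rb$Df, gb$`F value`, gb$`Pr(>F)`, gb$`Sum Sq`),
    anova_row("within", gw$Df, rw$Df, gw$`F value`, gw$`Pr(>F)`, gw$`Sum Sq`),
    anova_row("between:within", gi$Df, rw$Df, gi$`F value`, gi$`Pr(>F)`, gi$`Sum Sq`),
    anova_row("error:subjects", rb$Df, NA, NA, NA, rb$`Sum Sq`),
    anova_row("error:within", rw$Df, NA, NA, NA, rw$`Sum Sq`))
  structure(out, class = c("anova_result", "data.frame"),
            sphericity_correction = "none")
}

#' Newman-Keuls stepdown comparisons
#'
#' Group means are ordered; each pair is tested with the studentized range
#' statistic against the critical value for the stretch size \eqn{r} spanned
#' by the pair, stepping down from the full range.  Interior pairs of a
#' non-significant stretch are not tested (blocked), which is what makes the
#' procedure stepwise.  Unequal group sizes use the harmonic mean.
#'
#' @param group_means Named numeric vector of group means.
#' @param mse Residual mean square from the omnibus ANOVA.
#' @param df Residual degrees of freedom.
#' @param n_per_group Common group size, or vector matching
#'   \code{group_means}.
#' @param alpha Familywise level (default 0.05).
#' @return data.frame of class \code{posthoc_result}: \code{group_a},
#'   \code{group_b}, \code{statistic} (q), \code{p} (studentized-range p for
#'   the stretch; NA when blocked), \code{significant}; attribute
#'   \code{"method"}.
#' @export
newman_keuls <- function(group_means, mse, df, n_per_group, alpha = 0.05) {
  k <- length(group_means)
  if (k < 2) abort("need >= 2 groups", "invalid_parameter")
  if (is.null(names(group_means))) names(group_means) <- paste0("g", seq_len(k))
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, k)
  ord <- order(group_means)
  m <- group_means[ord]
  nn <- n_per_group[ord]
  sig <- matrix(NA, k, k)      # TRUE significant, FALSE not, over ordered idx
  pmat <- matrix(NA_real_, k, k)
  for (r in k:2) {             # stretch size, stepping down
    for (i in 1:(k - r + 1)) {
      j <- i + r - 1
      # blocked if contained in any wider non-significant stretch
      blocked <- FALSE
      for (ii in 1:i) for (jj in j:k) {
        if ((jj - ii) > (j - i) && isFALSE(sig[ii, jj])) blocked <- TRUE
      }
      if (blocked) { sig[i, j] <- FALSE; next }
      n_h <- 2 / (1 / nn[i] + 1 / nn[j])
      q <- (m[j] - m[i]) / sqrt(mse / n_h)
      p <- stats::ptukey(q, nmeans = r, df = df, lower.tail = FALSE)
      pmat[i, j] <- p
      sig[i, j] <- p < alpha
    }
  }
  pairs <- which(upper.tri(sig), arr.ind = TRUE)
  out <- data.frame(
    group_a = names(m)[pairs[, "row"]],
    group_b = names(m)[pairs[, "col"]],
    statistic = (m[pairs[, "col"]] - m[pairs[, "row"]]) /
      sqrt(mse / (2 / (1 / nn[pairs[, "row"]] + 1 / nn[pairs[, "col"]]))),
    p = pmat[pairs],
    significant = sig[pairs])
  rownames(out) <- NULL
  structure(out, class = c("posthoc_result", "data.frame"),
            method = "newman_keuls", alpha = alpha)
}

#' Bonferroni adjustment
#'
#' Standard single-step correction: p-values multiplied by the number of
#' comparisons, capped at 1.
#'
#' @param pvalues Numeric vector of raw p-values; names identify the pairs.
#' @param alpha Familywise level.
#' @return \code{posthoc_result} data.frame with \code{comparison},
#'   \code{p_raw}, \code{p_adjusted}, \code{significant}.
#' @export
posthoc_bonferroni <- function(pvalues, alpha = 0.05) {
  adj <- pmin(1, pvalues * length(pvalues))
  out <- data.frame(
    comparison = if (is.null(names(pvalues))) paste0("pair", seq_along(pvalues))
                 else names(pvalues),
    p_raw = as.numeric(pvalues), p_adjusted = as.numeric(adj),
    significant = as.numeric(adj) < alpha)
  structure(out, class = c("posthoc_result", "data.frame"),
            method = "bonferroni", alpha = alpha)
}

#' Tukey HSD comparisons from group summaries
#'
#' All pairwise comparisons with a single studentized-range critical value at
#' the full number of groups (honest significant difference).
#'
#' @inheritParams newman_keuls
#' @return \code{posthoc_result} with \code{group_a}, \code{group_b},
#'   \code{statistic}, \code{p} (Tukey-adjusted), \code{significant}.
#' @export
posthoc_tukey <- function(group_means, mse, df, n_per_group, alpha = 0.05) {
  k <- length(group_means)
  if (k < 2) abort("need >= 2 groups", "invalid_parameter")
  if (is.null(names(group_means))) names(group_means) <- paste0("g", seq_len(k))
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, k)
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    n_h <- 2 / (1 / n_per_group[i] + 1 / n_per_group[j])
    q <- abs(group_means[j] - group_means[i]) / sqrt(mse / n_h)
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group_a = names(group_means)[i], group_b = names(group_means)[j],
               statistic = q, p = p, significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("posthoc_result", "data.frame"),
            method = "tukey", alpha = alpha)
}
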