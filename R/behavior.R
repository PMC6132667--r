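# Conditioned-freezing quantification and tone discrimination.

#' Freezing percentage from an immobility series
#'
#' Freezing is the fraction of the scored observation window the animal
#' spends immobile (respiration movements excepted upstream, in scoring).
#'
#' @param immobility Binary (0/1 or logical) series sampled at a fixed rate.
#' @param scored_window Optional index vector restricting scoring to part of
#'   the series.
#' @return Percentage in [0, 100].
#' @export
freezing_percent <- function(immobility, scored_window = NULL) {
  if (!is.null(scored_window)) immobility <- immobility[scored_window]
  if (!length(immobility)) abort("empty scoring window", "invalid_parameter")
  if (!all(immobility %in% c(0, 1)))
    abort("immobility series must be binary", "invalid_parameter")
  100 * sum(immobility) / length(immobility)
}

#' Synthetic immobility series for a target freezing percentage
#'
#' Interface-completeness path: a 10 Hz binary series over the scored window
#' whose immobile fraction rounds to the given percentage.
#'
#' @param freezing Target freezing percentage.
#' @param duration_s Scored window length, s (default 180).
#' @param rate_hz Scoring rate (default 10 Hz).
#' @param seed Seed for the arrangement of immobile bins.
#' @return Integer 0/1 vector.
#' @export
generate_immobility <- function(freezing, duration_s = 180, rate_hz = 10,
                                seed = 1L) {
  n <- round(duration_s * rate_hz)
  k <- round(freezing / 100 * n)
  set.seed(seed)
  s <- integer(n)
  s[sample.int(n, k)] <- 1L
  s
}

#' Tone-discrimination summary for one condition
#'
#' Per-tone mean +/- SEM of freezing, the per-animal paired difference
#' (conditioned 10 kHz minus neutral 2.5 kHz), and the within-condition
#' CS+/CS- contrast (paired frequency effect) deciding whether the group
#' discriminates the tones.
#'
#' @param sessions data.frame with columns \code{animal_id}, \code{condition},
#'   \code{tone}, \code{freezing_percent} (both tones per animal).
#' @param condition Condition label to summarise.
#' @param alpha Significance level of the discrimination contrast.
#' @return List of class \code{discrimination_summary}: \code{condition},
#'   \code{per_tone} (data.frame tone/n/mean/sem), \code{paired_delta}
#'   (mean 10 kHz - 2.5 kHz), \code{p_value}, \code{discriminates},
#'   \code{flag} (\code{"too-few-animals"} when the SEM is undefined).
#' @export
discrimination_summary <- function(sessions, condition, alpha = 0.05) {
  df <- sessions[sessions$condition == condition, ]
  if (!nrow(df)) abort(sprintf("no sessions for condition '%s'", condition),
                       "config_error")
  wide <- merge(df[df$tone == "2.5kHz", c("animal_id", "freezing_percent")],
                df[df$tone == "10kHz", c("animal_id", "freezing_percent")],
                by = "animal_id", suffixes = c("_neutral", "_cs"))
  if (nrow(wide) < nrow(df) / 2)
    abort("each animal needs both tones", "invalid_parameter")
  per_tone <- do.call(rbind, lapply(c("2.5kHz", "10kHz"), function(tone) {
    x <- df$freezing_percent[df$tone == tone]
    data.frame(tone = tone, n = length(x), mean = mean(x),
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_)
  }))
  delta <- wide$freezing_percent_cs - wide$freezing_percent_neutral
  flag <- if (nrow(wide) < 2) "too-few-animals" else "ok"
  if (flag == "ok" && stats::sd(delta) > 0) {
    tt <- stats::t.test(wide$freezing_percent_cs, wide$freezing_percent_neutral,
                        paired = TRUE)
    p <- tt$p.value
  } else {
    p <- NA_real_
  }
  structure(list(condition = condition, per_tone = per_tone,
                 paired_delta = mean(delta), p_value = p,
                 discriminates = isTRUE(p < alpha), flag = flag),
            class = "discrimination_summary")
}

#' @export
print.discrimination_summary <- function(x, ...) {
  cat(sprintf("<discrimination_summary> %s\n", x$condition))
  print(x$per_tone, row.names = FALSE)
  cat(sprintf("  paired delta (10 kHz - 2.5 kHz): %.1f%%; p = %s; discriminates: %s\n",
              x$paired_delta,
              ifelse(is.na(x$p_value), "NA", format.pval(x$p_value, digits = 3)),
              x$discriminates))
  invisible(x)
}
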