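# Outlier removal, normalization and negative-value rules.
#
# Two normalization methods, one per project: "simple" (boxplot-free 2%/8%
# rule, recommended under ~300 nt) and "interquartile" (1.5 x IQR outlier
# removal, top-10% normalization, for longer molecules). Outliers — mostly
# intrinsic reverse-transcriptase stops — are set to the sentinel -10.

#' Normalization configuration
#'
#' @param method `"simple"` or `"interquartile"`. A project must use a
#'   single method throughout for consistency.
#' @param simple_outlier_fraction Fraction of the most reactive values
#'   removed as outliers by the simple method (default 0.02).
#' @param simple_norm_fraction Fraction of the next most reactive values
#'   averaged into the normalization factor (default 0.08).
#' @param iqr_multiplier Whisker multiplier for the interquartile method
#'   (default 1.5): values above `Q3 + iqr_multiplier * IQR` are outliers.
#' @param iqr_norm_fraction Fraction of the remaining top values averaged
#'   into the normalization factor (default 0.10).
#' @param zero_floor Negative values down to this floor (default -0.3) are
#'   set to zero; values below it become undetermined (-10).
#' @param length_guideline Advisory molecule length (300 nt) above which the
#'   interquartile method is recommended; the package warns, it never
#'   switches methods silently.
#' @return Object of class `normalization_config`.
#' @export
normalization_config <- function(method = c("simple", "interquartile"),
                                 simple_outlier_fraction = 0.02,
                                 simple_norm_fraction = 0.08,
                                 iqr_multiplier = 1.5,
                                 iqr_norm_fraction = 0.10,
                                 zero_floor = -0.3,
                                 length_guideline = 300L) {
  method <- match.arg(method)
  fr <- c(simple_outlier_fraction, simple_norm_fraction, iqr_norm_fraction)
  if (any(fr <= 0 | fr >= 1)) stop("fractions must lie in (0, 1)")
  structure(list(method = method,
                 simple_outlier_fraction = simple_outlier_fraction,
                 simple_norm_fraction = simple_norm_fraction,
                 iqr_multiplier = iqr_multiplier,
                 iqr_norm_fraction = iqr_norm_fraction,
                 zero_floor = zero_floor,
                 length_guideline = as.integer(length_guideline)),
            class = "normalization_config")
}

# Descending order of v, ties broken by position index (earlier positions
# rank as more reactive) for determinism.
.rank_desc <- function(v) order(-v, seq_along(v))

#' Simple (2%/8%) outlier removal and normalization
#'
#' The top `ceil(0.02 n)` of the valid (non-sentinel) values — empirically
#' intrinsic RT stops — are removed (set to -10); the next `ceil(0.08 n)`
#' are averaged and all remaining valid values are divided by that average.
#'
#' @param profile A [reactivity_profile()].
#' @param cfg A [normalization_config()].
#' @return The normalized profile.
#' @export
normalize_simple <- function(profile, cfg = normalization_config("simple")) {
  stopifnot(inherits(profile, "reactivity_profile"))
  v <- profile$values
  valid <- which(v != UNDETERMINED)
  if (!length(valid)) stop("profile has no valid values")
  ord <- valid[.rank_desc(v[valid])]
  n_out <- ceiling(cfg$simple_outlier_fraction * length(valid))
  outliers <- ord[seq_len(n_out)]
  rest <- ord[-seq_len(n_out)]
  n_ref <- ceiling(cfg$simple_norm_fraction * length(valid))
  if (!length(rest) || n_ref > length(rest))
    stop("too few valid values for normalization")
  A <- mean(v[rest[seq_len(n_ref)]])
  if (A <= 0) stop("normalization factor nonpositive")
  v[outliers] <- UNDETERMINED
  v[rest] <- v[rest] / A
  profile$values <- v
  profile
}

#' Interquartile outlier removal and normalization
#'
#' Values above `Q3 + 1.5 * IQR` of the valid values (type-7 linear
#' interpolation quartiles) are removed as outliers; the top `ceil(0.10 n)`
#' of the remaining values are averaged and all remaining values divided by
#' that average.
#'
#' @inheritParams normalize_simple
#' @return The normalized profile.
#' @export
normalize_interquartile <- function(profile,
                                    cfg = normalization_config("interquartile")) {
  stopifnot(inherits(profile, "reactivity_profile"))
  v <- profile$values
  valid <- which(v != UNDETERMINED)
  if (length(valid) < 4L) stop("need >= 4 valid values for quartiles")
  q <- stats::quantile(v[valid], c(0.25, 0.75), type = 7, names = FALSE)
  cutoff <- q[2L] + cfg$iqr_multiplier * (q[2L] - q[1L])
  outliers <- valid[v[valid] > cutoff]
  rest <- setdiff(valid, outliers)
  if (!length(rest)) stop("all values flagged as outliers")
  n_ref <- ceiling(cfg$iqr_norm_fraction * length(rest))
  ord <- rest[.rank_desc(v[rest])]
  A <- mean(v[ord[seq_len(n_ref)]])
  if (A <= 0) stop("normalization factor nonpositive")
  v[outliers] <- UNDETERMINED
  v[rest] <- v[rest] / A
  profile$values <- v
  profile
}

#' Apply the negative-value rules
#'
#' Negative values down to `zero_floor` (-0.3) are set to zero; inferior
#' negative values are considered undetermined and set to -10. Applied to
#' normalized values (the pipeline's final preprocessing step).
#'
#' @inheritParams normalize_simple
#' @return The profile with negative values resolved.
#' @export
apply_negative_rules <- function(profile, cfg = normalization_config()) {
  stopifnot(inherits(profile, "reactivity_profile"))
  v <- profile$values
  sent <- v == UNDETERMINED
  to_zero <- !sent & v < 0 & v >= cfg$zero_floor
  to_und <- !sent & v < cfg$zero_floor
  v[to_zero] <- 0
  v[to_und] <- UNDETERMINED
  profile$values <- v
  profile
}

#' Preprocess a raw reactivity profile
#'
#' Composition of outlier removal + normalization (per `cfg$method`) and the
#' negative-value rules, in that order: the -0.3 floor therefore applies to
#' *normalized* values. Sentinel positions are excluded from every
#' percentile and average and propagate unchanged. The profile records its
#' preprocessing state, and an already-preprocessed profile is returned
#' unchanged, making the operation idempotent within a pipeline run.
#'
#' @inheritParams normalize_simple
#' @param warn_length Warn when the profile length disagrees with the
#'   advisory method/length guideline (default `TRUE`).
#' @return The preprocessed profile (marked `preprocessed`).
#' @export
preprocess_profile <- function(profile, cfg = normalization_config(),
                               warn_length = TRUE) {
  stopifnot(inherits(profile, "reactivity_profile"))
  if (isTRUE(profile$preprocessed)) return(profile)
  if (warn_length) {
    if (cfg$method == "simple" && profile$length > cfg$length_guideline)
      warning("simple normalization is recommended for molecules shorter ",
              "than ", cfg$length_guideline, " nt (profile has ",
              profile$length, ")")
    if (cfg$method == "interquartile" && profile$length <= cfg$length_guideline)
      warning("interquartile normalization is typically reserved for ",
              "molecules longer than ", cfg$length_guideline, " nt")
  }
  out <- switch(cfg$method,
                simple = normalize_simple(profile, cfg),
                interquartile = normalize_interquartile(profile, cfg))
  out <- apply_negative_rules(out, cfg)
  out$preprocessed <- TRUE
  out
}
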