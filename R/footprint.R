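# Differential-reactivity footprinting between two probing conditions
# (e.g. +/- ligand): per position, the absolute difference of the mean
# reactivities, the relative difference (difference/sum), and a two-sided
# Welch t-test on the replicate values. A position is called significant
# only when all three criteria pass, which excludes both small changes
# between weakly reactive nucleotides and large-but-meaningless changes
# between highly reactive ones.

#' Footprinting configuration
#'
#' @param diff_threshold Threshold applied to both the absolute difference
#'   `deltaR = |R1 - R2|` and the relative difference
#'   `deltaR / (R1 + R2)` (default 0.2).
#' @param alpha Significance level for the two-sided Welch t-test (default
#'   0.05). No multiple-testing correction is applied by default — the dual
#'   0.2 thresholds act as the effect-size guard; set `adjust = "BH"` for
#'   Benjamini-Hochberg adjusted p-values.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Object of class `footprint_config`.
#' @export
footprint_config <- function(diff_threshold = 0.2, alpha = 0.05,
                             adjust = c("none", "BH")) {
  if (diff_threshold <= 0) stop("diff_threshold must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(diff_threshold = diff_threshold, alpha = alpha,
                 adjust = match.arg(adjust)),
            class = "footprint_config")
}

.replicate_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(is.list(x), length(x) >= 1L)
  stopifnot(all(vapply(x, inherits, logical(1), "reactivity_profile")))
  lens <- vapply(x, `[[`, integer(1), "length")
  if (length(unique(lens)) != 1L) stop("replicates differ in length")
  matrix(vapply(x, `[[`, numeric(lens[1L]), "values"), nrow = lens[1L])
}

.welch_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)$p.value
}

#' Differential-reactivity footprint between two conditions
#'
#' @param cond1,cond2 Replicates of the two conditions: each a list of
#'   (preprocessed) [reactivity_profile()]s or a positions x replicates
#'   numeric matrix (sentinel `-10` for missing values).
#' @param cfg A [footprint_config()].
#' @return Object of class `footprint_result` (a `data.frame`) with one
#'   row per position carrying valid data on both sides: `position`, `R1`,
#'   `R2` (mean reactivities), `delta` (`|R1 - R2|`), `relative`
#'   (`delta / (R1 + R2)`, 0 when the sum is 0), `p_value` (`NA` with
#'   `no_test = TRUE` when either side has fewer than 2 valid replicates),
#'   `significant`, `direction` (`up_in_2`, `down_in_2`, `none`).
#'   Positions undetermined on either side are excluded.
#' @export
footprint <- function(cond1, cond2, cfg = footprint_config()) {
  m1 <- .replicate_matrix(cond1)
  m2 <- .replicate_matrix(cond2)
  if (nrow(m1) != nrow(m2))
    stop("conditions cover different RNA lengths (", nrow(m1), " vs ",
         nrow(m2), ")")
  rows <- list()
  for (p in seq_len(nrow(m1))) {
    x <- m1[p, ]; x <- x[x != UNDETERMINED]
    y <- m2[p, ]; y <- y[y != UNDETERMINED]
    if (!length(x) || !length(y)) next
    R1 <- mean(x); R2 <- mean(y)
    delta <- abs(R1 - R2)
    relative <- if (R1 + R2 == 0) 0 else delta / (R1 + R2)
    no_test <- length(x) < 2L || length(y) < 2L
    p_value <- if (no_test) NA_real_ else .welch_p(x, y)
    rows[[length(rows) + 1L]] <-
      data.frame(position = p, R1 = R1, R2 = R2, delta = delta,
                 relative = relative, p_value = p_value, no_test = no_test)
  }
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(position = integer(0), R1 = numeric(0),
                     R2 = numeric(0), delta = numeric(0),
                     relative = numeric(0), p_value = numeric(0),
                     no_test = logical(0))
  p_eff <- if (cfg$adjust == "BH") stats::p.adjust(df$p_value, "BH")
           else df$p_value
  df$significant <- !is.na(p_eff) & df$delta > cfg$diff_threshold &
    df$relative > cfg$diff_threshold & p_eff < cfg$alpha
  df$direction <- ifelse(!df$significant, "none",
                         ifelse(df$R2 > df$R1, "up_in_2", "down_in_2"))
  class(df) <- c("footprint_result", "data.frame")
  attr(df, "config") <- cfg
  df
}

#' @export
print.footprint_result <- function(x, ...) {
  cat(sprintf("Footprint: %d positions tested, %d significant (%d up, %d down in condition 2)\n",
              nrow(x), sum(x$significant),
              sum(x$direction == "up_in_2"),
              sum(x$direction == "down_in_2")))
  if (sum(x$significant))
    cat("  positions:",
        paste(x$position[x$significant], collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.footprint_result <- function(x, ...) {
  diff <- x$R1 - x$R2
  col <- ifelse(!x$significant, "grey70",
                ifelse(x$direction == "down_in_2", "blue", "red"))
  graphics::barplot(diff, names.arg = x$position, col = col, border = NA,
                    xlab = "position", ylab = "R1 - R2", ...)
  invisible(x)
}

#' Write footprint output files
#'
#' Emits `footprint.tsv` (the full record table), `histogram.tsv`
#' (position, signed difference `R1 - R2`, significance and direction —
#' the data behind the differential-reactivity histogram, blue for less
#' reactive in condition 2, red for more reactive) and, when a structure
#' model is given, `colors_footprint.txt` marking significant positions on
#' the model.
#'
#' @param records A [footprint()] result.
#' @param dir Output directory.
#' @param structure Optional [secondary_structure()] of the probed RNA.
#' @return The directory, invisibly.
#' @export
footprint_outputs <- function(records, dir, structure = NULL) {
  stopifnot(inherits(records, "footprint_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- "position\tR1\tR2\tdelta\trelative\tp_value\tno_test\tsignificant\tdirection"
  writeLines(c(hdr, sprintf("%d\t%.10g\t%.10g\t%.10g\t%.10g\t%s\t%s\t%s\t%s",
                            records$position, records$R1, records$R2,
                            records$delta, records$relative,
                            ifelse(is.na(records$p_value), "NA",
                                   sprintf("%.10g", records$p_value)),
                            records$no_test, records$significant,
                            records$direction)),
             file.path(dir, "footprint.tsv"))
  writeLines(c("position\tdiff\tsignificant\tdirection",
               sprintf("%d\t%.10g\t%s\t%s", records$position,
                       records$R1 - records$R2, records$significant,
                       records$direction)),
             file.path(dir, "histogram.tsv"))
  if (!is.null(structure)) {
    stopifnot(inherits(structure, "secondary_structure"))
    mark <- rep("none", structure$length)
    mark[records$position[records$significant]] <-
      records$direction[records$significant]
    writeLines(c("position\tfootprint",
                 sprintf("%d\t%s", seq_len(structure$length), mark)),
               file.path(dir, "colors_footprint.txt"))
  }
  invisible(dir)
}
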