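# Replicate aggregation with position-wise consistency flagging, replicate
# correlation QC, and concatenation of multi-primer segments.

#' Consistency-check configuration for replicate aggregation
#'
#' @param min_std Maximal sample standard deviation for a position to be
#'   accepted outright (default 0.15).
#' @param min_ndata Minimal number of valid replicate values at a position
#'   (default 2; clamped to 1 when the condition has a single replicate).
#' @param scheme [class_scheme()] used by the pairwise-mean agreement
#'   criterion.
#' @return Object of class `consistency_config`.
#' @export
consistency_config <- function(min_std = 0.15, min_ndata = 2L,
                               scheme = class_scheme()) {
  if (min_std <= 0) stop("min_std must be > 0")
  structure(list(min_std = min_std, min_ndata = as.integer(min_ndata),
                 scheme = scheme),
            class = "consistency_config")
}

#' Aggregate replicate reactivity profiles
#'
#' Position by position: positions with fewer than `min_ndata` valid
#' (non-sentinel) values are `undetermined`. Otherwise the mean and sample
#' standard deviation (n-1 denominator) of the valid values are computed,
#' and the position is `accepted` when either (a) the standard deviation is
#' at most `min_std`, or (b) all pairwise means of replicate values fall in
#' the same reactivity class as the total mean. Failing both, the position
#' is flagged `warning` when the pairwise means still agree on a single
#' class among themselves (one differing from the total mean's class), and
#' `nonconsistent` when they span multiple classes. With exactly two
#' replicates the single pairwise mean equals the total mean, so criterion
#' (b) degenerates; a guard applies instead: accepted only if the standard
#' deviation passes or the two replicate values themselves share a class
#' (failing pairs are `nonconsistent`).
#'
#' Only `accepted` positions feed structure modeling; `warning` and
#' `nonconsistent` positions are excluded downstream (like `undetermined`)
#' but rendered distinctly in annotations.
#'
#' @param profiles List of [reactivity_profile()]s of the same RNA,
#'   condition and length.
#' @param cfg A [consistency_config()].
#' @return Object of class `aggregated_profile`: `rna_id`, `condition_id`
#'   and a data.frame `table` with columns `position`, `mean`, `std`,
#'   `flag`, `n_valid`. `flag = undetermined` reports `mean = -10`.
#' @export
aggregate_replicates <- function(profiles, cfg = consistency_config()) {
  if (!length(profiles)) stop("no profiles to aggregate")
  stopifnot(all(vapply(profiles, inherits, logical(1), "reactivity_profile")))
  lens <- vapply(profiles, `[[`, integer(1), "length")
  if (length(unique(lens)) != 1L)
    stop("profiles have different lengths: ", paste(unique(lens), collapse = ", "))
  n <- lens[1L]
  n_rep <- length(profiles)
  min_ndata <- if (n_rep == 1L) 1L else cfg$min_ndata
  vals <- vapply(profiles, `[[`, numeric(n), "values")
  vals <- matrix(vals, nrow = n)
  m_out <- numeric(n); s_out <- numeric(n)
  flag <- character(n); nv_out <- integer(n)
  for (p in seq_len(n)) {
    x <- vals[p, ]
    x <- x[x != UNDETERMINED]
    nv_out[p] <- length(x)
    if (length(x) < min_ndata) {
      m_out[p] <- UNDETERMINED; s_out[p] <- NA_real_
      flag[p] <- "undetermined"
      next
    }
    m <- mean(x)
    s <- if (length(x) >= 2L) stats::sd(x) else 0
    m_out[p] <- m; s_out[p] <- s
    if (s <= cfg$min_std) {
      flag[p] <- "accepted"
    } else if (length(x) == 2L) {
      cls <- reactivity_class(x, cfg$scheme)
      flag[p] <- if (cls[1L] == cls[2L]) "accepted" else "nonconsistent"
    } else {
      pm <- utils::combn(x, 2L, mean)
      pc <- reactivity_class(pm, cfg$scheme)
      mc <- reactivity_class(m, cfg$scheme)
      if (all(pc == mc)) {
        flag[p] <- "accepted"
      } else if (length(unique(pc)) == 1L) {
        flag[p] <- "warning"
      } else {
        flag[p] <- "nonconsistent"
      }
    }
  }
  structure(list(rna_id = profiles[[1L]]$rna_id,
                 condition_id = profiles[[1L]]$condition_id,
                 length = n,
                 table = data.frame(position = seq_len(n), mean = m_out,
                                    std = s_out, flag = flag,
                                    n_valid = nv_out)),
            class = "aggregated_profile")
}

#' @export
print.aggregated_profile <- function(x, ...) {
  tab <- table(factor(x$table$flag, levels = c("accepted", "warning",
                                               "nonconsistent",
                                               "undetermined")))
  cat(sprintf("Aggregated profile [%s/%s]: %d nt\n", x$rna_id,
              x$condition_id, x$length))
  cat(sprintf("  %s: %d\n", names(tab), as.integer(tab)), sep = "")
  invisible(x)
}

#' Reactivities usable for structure modeling
#'
#' @param x An [aggregate_replicates()] result.
#' @return Numeric vector: the mean at `accepted` positions, the sentinel
#'   `-10` everywhere else.
#' @export
modeling_reactivities <- function(x) {
  stopifnot(inherits(x, "aggregated_profile"))
  out <- rep(UNDETERMINED, x$length)
  acc <- x$table$flag == "accepted"
  out[acc] <- x$table$mean[acc]
  out
}

#' Write an aggregated profile to TSV
#' @param x An `aggregated_profile`.
#' @param path Output path.
#' @export
write_aggregated_tsv <- function(x, path) {
  stopifnot(inherits(x, "aggregated_profile"))
  t <- x$table
  writeLines(c("position\tmean\tstd\tflag\tn_valid",
               sprintf("%d\t%.10g\t%s\t%s\t%d", t$position, t$mean,
                       ifelse(is.na(t$std), "NA", sprintf("%.10g", t$std)),
                       t$flag, t$n_valid)),
             path)
  invisible(path)
}

#' Pairwise replicate correlations (QC)
#'
#' Pairwise Pearson and Spearman correlation coefficients over positions
#' valid in both replicates — a fast check for failed experiments. The
#' results are reported only; they have no automated consequences
#' (excluding a replicate is the user's decision via the samples table).
#'
#' @param profiles List of >= 2 [reactivity_profile()]s of equal length.
#' @param min_common Minimal number of common valid positions below which
#'   the correlation is reported as `NA` (default 3).
#' @return List with symmetric matrices `pearson` and `spearman` and a
#'   data.frame `pairs` (rep1, rep2, n_common, pearson, spearman).
#' @export
replicate_correlations <- function(profiles, min_common = 3L) {
  if (length(profiles) < 2L) stop("need >= 2 profiles")
  lens <- vapply(profiles, `[[`, integer(1), "length")
  if (length(unique(lens)) != 1L) stop("profiles have different lengths")
  k <- length(profiles)
  ids <- vapply(seq_len(k), function(i) {
    id <- profiles[[i]]$replicate_id
    if (nzchar(id)) id else paste0("rep", i)
  }, character(1))
  pe <- sp <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(pe) <- diag(sp) <- 1
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    vi <- profiles[[i]]$values; vj <- profiles[[j]]$values
    ok <- vi != UNDETERMINED & vj != UNDETERMINED
    if (sum(ok) >= min_common) {
      pe[i, j] <- pe[j, i] <- stats::cor(vi[ok], vj[ok], method = "pearson")
      sp[i, j] <- sp[j, i] <- stats::cor(vi[ok], vj[ok], method = "spearman")
    }
    rows[[length(rows) + 1L]] <-
      data.frame(rep1 = ids[i], rep2 = ids[j], n_common = sum(ok),
                 pearson = pe[i, j], spearman = sp[i, j])
  }
  list(pearson = pe, spearman = sp, pairs = do.call(rbind, rows))
}

.flag_severity <- c(accepted = 0L, undetermined = 1L, warning = 2L,
                    nonconsistent = 3L)

#' Concatenate multi-primer segments into one profile
#'
#' Long RNAs are probed with several primers, each covering a range of the
#' molecule; the per-primer aggregated profiles are merged into a single
#' full-length profile. Uncovered positions are `undetermined`. Where
#' ranges overlap: both accepted — the means are averaged (standard
#' deviation combined conservatively as the maximum); exactly one accepted —
#' that one is kept; neither accepted — the position keeps the more severe
#' flag (nonconsistent > warning > undetermined) and reports no mean.
#'
#' @param segments List of `list(profile =` [aggregate_replicates()]
#'   result`, start =, end =)`. Segment tables use local coordinates
#'   `1..(end - start + 1)`; `start`/`end` place them on the RNA.
#' @param total_length Full RNA length (default: the maximal `end`).
#' @return A full-length `aggregated_profile`.
#' @export
concatenate_primers <- function(segments, total_length = NULL) {
  if (!length(segments)) stop("no segments")
  rna <- unique(vapply(segments, function(s) s$profile$rna_id, character(1)))
  if (length(rna) != 1L)
    stop("segments belong to different RNAs: ", paste(rna, collapse = ", "))
  cond <- segments[[1L]]$profile$condition_id
  ends <- vapply(segments, function(s) as.integer(s$end), integer(1))
  if (is.null(total_length)) total_length <- max(ends)
  n <- as.integer(total_length)
  m_out <- rep(UNDETERMINED, n); s_out <- rep(NA_real_, n)
  flag <- rep("undetermined", n); nv <- integer(n)
  covered <- logical(n)
  for (seg in segments) {
    start <- as.integer(seg$start); end <- as.integer(seg$end)
    prof <- seg$profile
    stopifnot(inherits(prof, "aggregated_profile"))
    if (start < 1L || end > n || end < start)
      stop("primer range ", start, "..", end, " outside RNA of length ", n)
    if (prof$length != end - start + 1L)
      stop("segment profile length ", prof$length,
           " does not match range ", start, "..", end)
    for (k in seq_len(prof$length)) {
      p <- start + k - 1L
      newf <- prof$table$flag[k]; newm <- prof$table$mean[k]
      news <- prof$table$std[k]; newn <- prof$table$n_valid[k]
      oldf <- flag[p]
      if (!covered[p]) {
        covered[p] <- TRUE
        m_out[p] <- newm; s_out[p] <- news; flag[p] <- newf; nv[p] <- newn
      } else if (oldf == "accepted" && newf == "accepted") {
        m_out[p] <- (m_out[p] + newm) / 2
        s_out[p] <- max(s_out[p], news, na.rm = TRUE)
        nv[p] <- nv[p] + newn
      } else if (oldf == "accepted") {
        # keep existing accepted value
      } else if (newf == "accepted") {
        m_out[p] <- newm; s_out[p] <- news; flag[p] <- newf; nv[p] <- newn
      } else {
        worse <- if (.flag_severity[[newf]] > .flag_severity[[oldf]]) newf
                 else oldf
        flag[p] <- worse
        m_out[p] <- UNDETERMINED
        s_out[p] <- NA_real_
        nv[p] <- max(nv[p], newn)
      }
    }
  }
  structure(list(rna_id = rna, condition_id = cond, length = n,
                 table = data.frame(position = seq_len(n), mean = m_out,
                                    std = s_out, flag = flag, n_valid = nv)),
            class = "aggregated_profile")
}
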