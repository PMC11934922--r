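# Multi-condition structure prediction: pool per-condition Boltzmann
# samples, cluster them by base-pair distance (average-linkage agglomerative
# clustering, k chosen by mean silhouette), score clusters multiplicatively
# by cross-condition occupancy, and emit best and second-best cluster
# centroids.
#
# Clustering operates on the deduplicated set of distinct structures
# (weighted by multiplicity) and orders them canonically, so results are
# invariant under permutation of the pool.

.sample_keys <- function(pool) {
  vapply(pool, function(s) as_dotbracket(s$structure), character(1))
}

# Pairwise bp-distance matrix between distinct structures, via an indicator
# matrix over the union of observed pairs: d = |A| + |B| - 2 |A inter B|.
.bp_distance_matrix <- function(structs) {
  u <- length(structs)
  keysets <- lapply(structs, .pair_keys)
  allk <- sort(unique(unlist(keysets)))
  if (!length(allk)) return(matrix(0, u, u))
  U <- matrix(0, u, length(allk))
  for (k in seq_len(u)) U[k, match(keysets[[k]], allk)] <- 1
  sz <- rowSums(U)
  D <- outer(sz, sz, "+") - 2 * tcrossprod(U)
  D[D < 0] <- 0
  D
}

# Weighted mean silhouette over all samples for an assignment of the
# distinct structures (weights = multiplicities). Duplicates of a point sit
# at distance 0 from each other and are counted in the within-cluster mean.
.mean_silhouette <- function(D, w, cl) {
  ks <- sort(unique(cl))
  if (length(ks) < 2L) return(-Inf)
  Wk <- vapply(ks, function(k) sum(w[cl == k]), numeric(1))
  # sumd[i, k] = total (weighted) distance from point i to cluster k
  sumd <- vapply(ks, function(k) as.numeric(D %*% (w * (cl == k))),
                 numeric(length(w)))
  sumd <- matrix(sumd, nrow = length(w))
  s <- numeric(length(w))
  for (i in seq_along(w)) {
    own <- match(cl[i], ks)
    if (Wk[own] - 1 <= 0) { s[i] <- 0; next }
    a <- sumd[i, own] / (Wk[own] - 1)
    b <- min(sumd[i, -own] / Wk[-own])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  sum(s * w) / sum(w)
}

#' Cluster a pool of sampled structures
#'
#' Agglomerative clustering with average linkage on [bp_distance()]. The
#' number of clusters maximizes the mean silhouette width over
#' `k = 2..max_k`, except that a near-degenerate pool (mean pairwise
#' distance below 2) forms a single cluster. Deterministic: distinct
#' structures are ordered canonically before clustering, so permuting the
#' pool changes nothing; silhouette ties go to the smallest k.
#'
#' @param pool Nonempty list of `structure_sample` objects (see
#'   [sample_structures()]).
#' @param max_k Maximal number of clusters considered (default 10).
#' @param seed Unused by the (deterministic) clustering; accepted for
#'   interface stability.
#' @return List of `cluster_result` objects: `members` (indices into the
#'   pool), `size`, `occupancy` (named per-condition fractions),
#'   `centroid` ([secondary_structure()]), `mean_energy`.
#' @export
cluster_pool <- function(pool, max_k = 10L, seed = NULL) {
  if (!length(pool)) stop("empty sample pool")
  keys <- .sample_keys(pool)
  ukeys <- sort(unique(keys))
  idx <- match(keys, ukeys)
  u <- length(ukeys)
  structs <- lapply(split(seq_along(pool), idx),
                    function(ii) pool[[ii[1L]]]$structure)
  w <- as.numeric(tabulate(idx, nbins = u))
  D <- .bp_distance_matrix(structs)
  N <- length(pool)
  if (u == 1L) {
    cl <- rep(1L, u)
  } else {
    # weighted mean pairwise distance over all sample pairs (duplicates at
    # distance zero included)
    mpd <- as.numeric(t(w) %*% D %*% w) / (N * (N - 1))
    if (mpd < 2) {
      cl <- rep(1L, u)
    } else {
      hc <- stats::hclust(stats::as.dist(D), method = "average")
      best_k <- 2L; best_s <- -Inf
      for (k in 2L:min(max_k, u)) {
        ck <- stats::cutree(hc, k = k)
        sk <- .mean_silhouette(D, w, ck)
        if (sk > best_s + 1e-12) { best_s <- sk; best_k <- k }
      }
      cl <- stats::cutree(hc, k = best_k)
    }
  }
  conds <- vapply(pool, `[[`, character(1), "condition_id")
  cond_tot <- table(conds)
  energies <- vapply(pool, `[[`, numeric(1), "energy")
  lapply(sort(unique(cl)), function(k) {
    members <- which(idx %in% which(cl == k))
    occ <- table(factor(conds[members], levels = names(cond_tot))) /
      as.numeric(cond_tot)
    cent <- centroid(lapply(members, function(i) pool[[i]]$structure))
    structure(list(members = members, size = length(members),
                   occupancy = stats::setNames(as.numeric(occ),
                                               names(cond_tot)),
                   centroid = cent,
                   mean_energy = mean(energies[members])),
              class = "cluster_result")
  })
}

#' Score a cluster by cross-condition support
#'
#' `score = prod over conditions c of (occupancy_c + epsilon)`: a cluster
#' well-populated under every condition scores higher than one dominating a
#' single condition, mirroring the rationale that structures supported by
#' several probes/conditions are the credible ones. `epsilon` (default
#' 0.01) keeps absence in one condition a penalty rather than a veto.
#'
#' @param cluster A `cluster_result` from [cluster_pool()].
#' @param epsilon Additive smoothing per condition (default 0.01).
#' @return The score (positive real).
#' @export
score_cluster <- function(cluster, epsilon = 0.01) {
  stopifnot(inherits(cluster, "cluster_result"))
  if (!length(cluster$occupancy)) stop("cluster carries no condition labels")
  prod(cluster$occupancy + epsilon)
}

#' Centroid structure of a set of structures
#'
#' The structure formed by every base pair present in more than half of the
#' members (strictly; frequency exactly 0.5 is excluded). Among nested
#' structures two conflicting pairs cannot both exceed 50%, so the result
#' is guaranteed conflict-free.
#'
#' @param structures Nonempty list of [secondary_structure()]s of equal
#'   length.
#' @return A [secondary_structure()].
#' @export
centroid <- function(structures) {
  if (!length(structures)) stop("empty cluster")
  n <- structures[[1L]]$length
  keys <- unlist(lapply(structures, .pair_keys))
  if (!length(keys))
    return(secondary_structure(n, NULL,
                               sequence = structures[[1L]]$sequence))
  tab <- table(keys)
  sel <- as.integer(names(tab)[tab / length(structures) > 0.5])
  pairs <- cbind((sel - 1L) %/% n + 1L, (sel - 1L) %% n + 1L)
  secondary_structure(n, pairs, sequence = structures[[1L]]$sequence,
                      min_hairpin = 0L)
}

#' Predict secondary structures from multiple probing conditions
#'
#' The integrative prediction core. Per condition, accepted aggregated
#' reactivities are converted to pseudo-energies (non-accepted positions
#' carry the sentinel and contribute nothing) and `n_samples` structures
#' are drawn from the constrained Boltzmann ensemble. An optional MSA
#' contributes consensus samples as one more pseudo-condition, weighted
#' equally. The pooled samples are clustered by base-pair distance, each
#' cluster scored by cross-condition occupancy, and the centroids of the
#' two top-ranked clusters returned as best and second-best models
#' (guaranteed to come from different clusters when two or more exist).
#'
#' @param sequence RNA sequence string.
#' @param conditions Named list; each element an `aggregated_profile`, a
#'   `reactivity_profile`, or a plain numeric reactivity vector (sentinel
#'   `-10` for missing). May be empty if `aln` is given.
#' @param aln Optional [msa()] whose reference matches `sequence`.
#' @param n_samples Samples drawn per condition (default 1000).
#' @param model An [energy_model()].
#' @param pe_params [pseudo_energy_params()] for the reactivity conversion.
#' @param covariation_bonus,inconsistency_penalty Consensus-scorer
#'   parameters, see [consensus_energy_matrix()].
#' @param max_k Maximal cluster count (default 10).
#' @param epsilon Occupancy smoothing of [score_cluster()].
#' @param seed Master seed; each condition samples from its own stream
#'   derived deterministically from it.
#' @return Object of class `probefold_prediction`: `best`, `second`
#'   ([secondary_structure()] or `NULL`), `clusters` (ranked, each with
#'   `score`), `conditions` (names), `reactivities` (per-condition
#'   modeling vectors), `config` snapshot.
#' @export
predict_structures <- function(sequence, conditions = list(), aln = NULL,
                               n_samples = 1000L, model = energy_model(),
                               pe_params = pseudo_energy_params(),
                               covariation_bonus = -1.0,
                               inconsistency_penalty = 0.5,
                               max_k = 10L, epsilon = 0.01, seed = 1L) {
  sequence <- toupper(gsub("T", "U", sequence))
  n <- nchar(sequence)
  if (!length(conditions) && is.null(aln))
    stop("need at least one probing condition or an MSA")
  if (length(conditions) &&
      (is.null(names(conditions)) || any(!nzchar(names(conditions)))))
    stop("conditions must be named")
  react <- lapply(conditions, function(x) {
    v <- if (inherits(x, "aggregated_profile")) modeling_reactivities(x)
         else if (inherits(x, "reactivity_profile")) x$values
         else as.numeric(x)
    if (length(v) != n)
      stop("condition length ", length(v), " does not match sequence (", n, ")")
    v
  })
  if (length(react) &&
      all(vapply(react, function(v) all(v == UNDETERMINED), logical(1))))
    warning("no accepted reactivities in any condition; ",
            "folding is unconstrained")
  pool <- list()
  for (ci in seq_along(react)) {
    nm <- names(react)[ci]
    pseudo <- pseudo_energy(react[[ci]], pe_params)
    smp <- sample_structures(sequence, pseudo, model, n = n_samples,
                             seed = derive_seed(seed, nm),
                             condition_id = nm)
    pool <- c(pool, smp)
  }
  if (!is.null(aln)) {
    smp <- consensus_sample_from_msa(aln, model, covariation_bonus,
                                     inconsistency_penalty, n = n_samples,
                                     seed = derive_seed(seed, "MSA"),
                                     condition_id = "MSA")
    if (smp[[1L]]$structure$length != n)
      stop("MSA reference length does not match sequence")
    pool <- c(pool, smp)
  }
  clusters <- cluster_pool(pool, max_k = max_k)
  scores <- vapply(clusters, score_cluster, numeric(1), epsilon = epsilon)
  tot_occ <- vapply(clusters, function(cl) sum(cl$occupancy), numeric(1))
  men <- vapply(clusters, `[[`, numeric(1), "mean_energy")
  rank <- order(-scores, -tot_occ, men)
  clusters <- clusters[rank]
  scores <- scores[rank]
  for (k in seq_along(clusters)) clusters[[k]]$score <- scores[k]
  best <- clusters[[1L]]$centroid
  best$sequence <- sequence
  second <- if (length(clusters) >= 2L) {
    s2 <- clusters[[2L]]$centroid
    s2$sequence <- sequence
    s2
  } else NULL
  structure(list(best = best, second = second, clusters = clusters,
                 conditions = c(names(react), if (!is.null(aln)) "MSA"),
                 reactivities = react,
                 config = list(n_samples = n_samples, model = model,
                               pe_params = pe_params, max_k = max_k,
                               epsilon = epsilon, seed = seed,
                               covariation_bonus = covariation_bonus,
                               inconsistency_penalty = inconsistency_penalty)),
            class = "probefold_prediction")
}

#' Derive a reproducible stream seed from a master seed and a label
#'
#' @param seed Master integer seed.
#' @param tag Character label (e.g. a condition name).
#' @return An integer below 2^31, a deterministic function of both inputs.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) *
             (seq_len(nchar(as.character(tag))) %% 31L + 1L))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

#' @export
print.probefold_prediction <- function(x, ...) {
  cat("Probing-informed structure prediction\n")
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  clusters:", length(x$clusters), "\n")
  cat("  best model  :", as_dotbracket(x$best), "\n")
  if (!is.null(x$second))
    cat("  second model:", as_dotbracket(x$second), "\n")
  invisible(x)
}

#' @export
summary.probefold_prediction <- function(object, ...) {
  df <- do.call(rbind, lapply(seq_along(object$clusters), function(k) {
    cl <- object$clusters[[k]]
    occ <- as.list(cl$occupancy)
    names(occ) <- paste0("occ_", names(occ))
    cbind(data.frame(cluster = k, size = cl$size, score = cl$score,
                     mean_energy = cl$mean_energy),
          as.data.frame(occ, check.names = FALSE))
  }))
  cat("Ranked structural clusters:\n")
  print(df, row.names = FALSE)
  invisible(df)
}

#' @export
plot.probefold_prediction <- function(x, ...) {
  occ <- t(vapply(x$clusters,
                  function(cl) cl$occupancy,
                  numeric(length(x$clusters[[1L]]$occupancy))))
  graphics::barplot(t(occ), beside = TRUE,
                    names.arg = paste0("C", seq_len(nrow(occ))),
                    legend.text = names(x$clusters[[1L]]$occupancy),
                    xlab = "cluster (ranked by score)",
                    ylab = "per-condition occupancy", ...)
  invisible(x)
}

#' Write prediction outputs
#'
#' Emits `best.dbn`, `second.dbn` (when a second cluster exists),
#' `clusters.tsv` (id, size, per-condition occupancy, score) and one color
#' annotation file per probing condition.
#'
#' @param x A [predict_structures()] result.
#' @param dir Output directory (created if needed).
#' @param name Run name used in file headers.
#' @param scheme [class_scheme()] for the annotations.
#' @return The directory, invisibly.
#' @export
write_prediction <- function(x, dir, name = "prediction",
                             scheme = class_scheme()) {
  stopifnot(inherits(x, "probefold_prediction"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dotbracket(x$best, file.path(dir, "best.dbn"),
                   name = paste0(name, "_best"))
  if (!is.null(x$second))
    write_dotbracket(x$second, file.path(dir, "second.dbn"),
                     name = paste0(name, "_second"))
  conds <- names(x$clusters[[1L]]$occupancy)
  lines <- c(paste(c("cluster", "size", "score",
                     paste0("occ_", conds)), collapse = "\t"))
  for (k in seq_along(x$clusters)) {
    cl <- x$clusters[[k]]
    lines <- c(lines, paste(c(k, cl$size, sprintf("%.10g", cl$score),
                              sprintf("%.10g", cl$occupancy)),
                            collapse = "\t"))
  }
  writeLines(lines, file.path(dir, "clusters.tsv"))
  for (nm in names(x$reactivities))
    write_color_annotation(x$reactivities[[nm]],
                           file.path(dir, paste0("colors_", nm, ".txt")),
                           scheme = scheme)
  invisible(dir)
}
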