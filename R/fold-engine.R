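# Probing-constrained folding machinery.
#
# Reactivities are converted to per-nucleotide pseudo-energies (Deigan-style
# m*ln(r+1)+b soft constraints) and added to a base-pair energy model with a
# helix-cooperativity (stacking) term. An exact O(n^3) dynamic program
# computes the partition function over all nested structures; stochastic
# traceback of its tables draws i.i.d. Boltzmann samples. A
# covariation-scored consensus folder turns a multiple sequence alignment
# into an extra "pseudo-condition" sampled the same way.
#
# The engine is pluggable: anything returning the same sample objects (see
# sample_structures) can stand behind the prediction stage, which depends
# only on the returned samples. The built-in model is a simplified
# pair+stack energy model — pair energies by type plus a constant bonus per
# stacked adjacency (the minimal helix-cooperativity a nearest-neighbor
# model provides; without it, isolated lone pairs are unrealistically
# favorable). Every property tested here is engine-agnostic rather than
# tied to a particular nearest-neighbor parameter set.

#' Pseudo-energy parameters
#'
#' The reactivity of a nucleotide contributes `m * ln(r + 1) + b` kcal/mol
#' to the energy of every structure in which it is paired (once per paired
#' nucleotide). With `m > 0`, reactive (likely unpaired) positions penalize
#' pairing; the negative intercept `b` mildly rewards pairing unreactive
#' positions.
#'
#' @param m Slope in kcal/mol (default 2.6).
#' @param b Intercept in kcal/mol (default -0.8).
#' @return Object of class `pseudo_energy_params`.
#' @export
pseudo_energy_params <- function(m = 2.6, b = -0.8) {
  if (m <= 0) stop("m must be > 0 (reactive positions penalize pairing)")
  structure(list(m = m, b = b), class = "pseudo_energy_params")
}

#' Base-pair energy model
#'
#' A simplified pair+stack energy model over Watson-Crick and wobble
#' pairs: each pair contributes its type energy, and each stacked
#' adjacency — pairs `(i, j)` and `(i+1, j-1)` both present — contributes
#' the `stack` bonus. The stacking term provides helix cooperativity:
#' without it, isolated lone pairs are as favorable as helix-terminal
#' pairs, which no physical model permits.
#'
#' @param gc,au,gu Pair energies in kcal/mol (defaults -3, -2, -1; must be
#'   <= 0).
#' @param stack Energy bonus per stacked adjacency in kcal/mol (default
#'   -1.5; must be <= 0).
#' @param min_hairpin Minimal hairpin loop size (default 3).
#' @param RT Thermal energy in kcal/mol (default 0.616, 37 C).
#' @return Object of class `energy_model`.
#' @export
energy_model <- function(gc = -3.0, au = -2.0, gu = -1.0, stack = -1.5,
                         min_hairpin = 3L, RT = 0.616) {
  if (any(c(gc, au, gu, stack) > 0))
    stop("pair and stack energies must be <= 0")
  structure(list(gc = gc, au = au, gu = gu, stack = stack,
                 min_hairpin = as.integer(min_hairpin), RT = RT),
            class = "energy_model")
}

#' Convert reactivities to pseudo-energies
#'
#' @param reactivity Numeric vector; the sentinel `-10` (missing data)
#'   contributes 0. Non-sentinel values must be > -1.
#' @param params A [pseudo_energy_params()].
#' @return Numeric vector of per-nucleotide pseudo-energies (kcal/mol).
#' @export
pseudo_energy <- function(reactivity, params = pseudo_energy_params()) {
  out <- numeric(length(reactivity))
  sent <- reactivity == UNDETERMINED
  if (any(!sent & reactivity <= -1))
    stop("reactivity <= -1 is not interpretable (and not the sentinel)")
  out[!sent] <- params$m * log(reactivity[!sent] + 1) + params$b
  out
}

.pair_type_energy <- function(a, b, model) {
  # NA when the two bases cannot pair
  key <- paste0(a, b)
  switch(key,
         GC = , CG = model$gc,
         AU = , UA = model$au,
         GU = , UG = model$gu,
         NA_real_)
}

# n x n matrix of pair energies, NA where pairing is disallowed (non-WC/GU
# or hairpin constraint violated).
.pair_energy_matrix <- function(sequence, model) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (any(!bases %in% c("A", "C", "G", "U")))
    stop("sequence must be over the alphabet A, C, G, U")
  n <- length(bases)
  E <- matrix(NA_real_, n, n)
  if (n >= model$min_hairpin + 2L) {
    for (i in seq_len(n - model$min_hairpin - 1L)) {
      for (j in (i + model$min_hairpin + 1L):n) {
        E[i, j] <- .pair_type_energy(bases[i], bases[j], model)
      }
    }
  }
  E
}

# Boltzmann pair weights q[i,j] = exp(-(E[i,j] + psi_i + psi_j)/RT), 0 where
# disallowed.
.pair_weights <- function(E, pseudo, RT) {
  n <- nrow(E)
  q <- matrix(0, n, n)
  ok <- which(!is.na(E), arr.ind = TRUE)
  if (nrow(ok)) {
    e <- E[ok] + pseudo[ok[, 1L]] + pseudo[ok[, 2L]]
    q[ok] <- exp(-e / RT)
  }
  q
}

# Inside tables (two-table recursion with stacking).
#   Zb[i,j]: partition function over structures of [i,j] with (i,j) paired
#     = q(i,j) * ( Z(i+1,j-1) + (sigma-1) * Zb(i+1,j-1) )
#     (the second term upgrades configurations whose interior starts with
#      the stacked pair (i+1,j-1) to total weight sigma * Zb)
#   Z(i,j) = Z(i+1,j) + sum_k Zb(i,k) * Z(k+1,j)
# Zm/Zbm are stored with a column offset: Zm[i, j+1] = Z(i..j), so the
# empty interval j = i-1 is addressable and equals 1 (Zb: 0).
.inside_tables <- function(q, min_hairpin, sigma) {
  n <- nrow(q)
  Zm <- matrix(1, n + 1L, n + 1L)
  Zb <- matrix(0, n, n)
  if (n >= min_hairpin + 2L) {
    for (i in n:1) {
      kmin <- i + min_hairpin + 1L
      if (kmin > n) next
      for (j in kmin:n) {
        if (q[i, j] > 0) {
          inner <- Zm[i + 1L, j]   # Z(i+1, j-1)
          if (i + 1L <= n && j - 1L >= 1L && j - 1L - (i + 1L) >= min_hairpin + 1L &&
              Zb[i + 1L, j - 1L] > 0)
            inner <- inner + (sigma - 1) * Zb[i + 1L, j - 1L]
          Zb[i, j] <- q[i, j] * inner
        }
        ks <- kmin:j
        zb <- Zb[i, ks]
        nz <- which(zb > 0)
        acc <- Zm[i + 1L, j + 1L]
        if (length(nz)) {
          kk <- ks[nz]
          acc <- acc + sum(zb[nz] * Zm[kk + 1L, j + 1L])
        }
        Zm[i, j + 1L] <- acc
      }
    }
  }
  list(Zm = Zm, Zb = Zb)
}

# Outside values Ob[i,j]: total weight of everything outside the
# pair-rooted subproblem (i,j), so that P(i,j) = Zb[i,j] * Ob[i,j] / Z.
# Three contributions: (i,j) exterior; (i,j) a component inside its closest
# enclosing pair (k,l); (i,j) the forced-stack continuation of (i-1,j+1).
# Computed by decreasing span; only run when probabilities are requested.
.pair_probabilities <- function(q, tabs, min_hairpin, sigma) {
  Zm <- tabs$Zm; Zb <- tabs$Zb
  n <- nrow(q)
  P <- matrix(0, n, n)
  if (n < min_hairpin + 2L) return(P)
  Ztot <- Zm[1L, n + 1L]
  Ob <- matrix(0, n, n)
  M <- matrix(0, n, n) # q * Ob of already-computed (larger-span) pairs
  for (d in (n - 1L):(min_hairpin + 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      if (Zb[i, j] == 0) next
      acc <- Zm[1L, i] * Zm[j + 1L, n + 1L]
      if (i > 1L && j < n) {
        ks <- 1L:(i - 1L); ls <- (j + 1L):n
        Zl <- Zm[ks + 1L, i]          # Z(k+1, i-1)
        Zr <- Zm[j + 1L, ls]          # Z(j+1, l-1)
        sub <- M[ks, ls, drop = FALSE]
        if (any(sub > 0)) acc <- acc + as.numeric(Zl %*% sub %*% Zr)
        # forced-stack continuation under the directly enclosing pair
        if (q[i - 1L, j + 1L] > 0 && Ob[i - 1L, j + 1L] > 0)
          acc <- acc + q[i - 1L, j + 1L] * (sigma - 1) * Ob[i - 1L, j + 1L]
      }
      Ob[i, j] <- acc
      M[i, j] <- q[i, j] * acc
      P[i, j] <- Zb[i, j] * acc / Ztot
    }
  }
  P
}

#' Partition function over nested structures
#'
#' Exact dynamic programming over all nested secondary structures:
#' `Z = sum over structures of exp(-E/RT)` with `E = sum of pair energies
#' + stack bonus per stacked adjacency + sum of pseudo-energies over
#' paired positions`, and the Boltzmann probability `p(i,j)` that
#' positions `i` and `j` are paired.
#'
#' @param sequence RNA string over `A`, `C`, `G`, `U`.
#' @param pseudo Per-position pseudo-energies (kcal/mol); default all zero.
#'   See [pseudo_energy()].
#' @param model An [energy_model()].
#' @param probabilities Compute the pair-probability matrix (default
#'   `TRUE`; the inside pass alone suffices for sampling).
#' @return List of class `fold_tables` with `Z` (total partition
#'   function), `pair_probabilities` (n x n matrix, zero where pairing is
#'   impossible; `NULL` if not requested), and the internal tables reused
#'   by [sample_structures()].
#' @export
partition_function <- function(sequence, pseudo = NULL,
                               model = energy_model(),
                               probabilities = TRUE) {
  sequence <- toupper(gsub("T", "U", sequence))
  n <- nchar(sequence)
  if (n < 1L) stop("empty sequence")
  if (is.null(pseudo)) pseudo <- numeric(n)
  if (length(pseudo) != n) stop("pseudo-energy vector length mismatch")
  E <- .pair_energy_matrix(sequence, model)
  q <- .pair_weights(E, pseudo, model$RT)
  sigma <- exp(-model$stack / model$RT)
  tabs <- .inside_tables(q, model$min_hairpin, sigma)
  P <- if (probabilities)
    .pair_probabilities(q, tabs, model$min_hairpin, sigma)
  else NULL
  structure(list(Z = tabs$Zm[1L, n + 1L], pair_probabilities = P,
                 q = q, Zm = tabs$Zm, Zb = tabs$Zb, E = E, pseudo = pseudo,
                 sigma = sigma, sequence = sequence, n = n, model = model),
            class = "fold_tables")
}

# Stochastic traceback of one structure. The work stack holds either open
# intervals c(0, i, j) or pair-rooted subproblems c(1, i, j).
.traceback_one <- function(q, Zm, Zb, min_hairpin, sigma, n) {
  pairs <- matrix(integer(0), ncol = 2L)
  stack <- list(c(0L, 1L, n))
  while (length(stack)) {
    it <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (it[1L] == 1L) {
      # pair-rooted (i,j): record the pair, choose the interior branch
      i <- it[2L]; j <- it[3L]
      pairs <- rbind(pairs, c(i, j))
      w_stack <- if (j - 1L - (i + 1L) >= min_hairpin + 1L &&
                     Zb[i + 1L, j - 1L] > 0)
        (sigma - 1) * Zb[i + 1L, j - 1L] else 0
      w_free <- Zm[i + 1L, j]   # Z(i+1, j-1)
      if (w_stack > 0 && stats::runif(1L) * (w_stack + w_free) < w_stack) {
        stack[[length(stack) + 1L]] <- c(1L, i + 1L, j - 1L)
      } else if (j - 1L >= i + 1L) {
        stack[[length(stack) + 1L]] <- c(0L, i + 1L, j - 1L)
      }
      next
    }
    i <- it[2L]; j <- it[3L]
    while (j - i >= min_hairpin + 1L) {
      Ztot <- Zm[i, j + 1L]
      u <- stats::runif(1L) * Ztot
      if (u < Zm[i + 1L, j + 1L]) {
        i <- i + 1L
        next
      }
      u <- u - Zm[i + 1L, j + 1L]
      ks <- (i + min_hairpin + 1L):j
      w <- Zb[i, ks] * Zm[ks + 1L, j + 1L]
      nz <- which(w > 0)
      if (!length(nz)) { # numerically degenerate draw: i stays unpaired
        i <- i + 1L
        next
      }
      cw <- cumsum(w[nz])
      sel <- which(u <= cw)
      k <- if (length(sel)) ks[nz[sel[1L]]] else ks[nz[length(nz)]]
      stack[[length(stack) + 1L]] <- c(1L, i, k)
      if (k + 1L <= j) {
        i <- k + 1L
      } else {
        break
      }
    }
  }
  pairs
}

# Energy of a pair set: pair energies + pseudo terms + stack bonus per
# adjacency (i,j) & (i+1,j-1).
.structure_energy <- function(pairs, E, pseudo, stack_energy, n) {
  if (!NROW(pairs)) return(0)
  en <- sum(E[cbind(pairs[, 1L], pairs[, 2L])]) +
    sum(pseudo[pairs[, 1L]]) + sum(pseudo[pairs[, 2L]])
  keys <- (pairs[, 1L] - 1L) * n + pairs[, 2L]
  inner <- pairs[, 1L] * n + (pairs[, 2L] - 1L) # key of (i+1, j-1)
  en + stack_energy * sum(inner %in% keys)
}

#' Draw structures from the Boltzmann ensemble
#'
#' I.i.d. samples from the Boltzmann distribution over nested structures
#' via stochastic traceback of the partition-function tables; reproducible
#' given `seed`.
#'
#' @param sequence RNA string, or a precomputed `fold_tables` object from
#'   [partition_function()] (reused without refilling).
#' @param pseudo Per-position pseudo-energies; ignored when tables are
#'   passed.
#' @param model An [energy_model()]; ignored when tables are passed.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param condition_id Label stored on each sample.
#' @return List of `structure_sample` objects: `structure`
#'   ([secondary_structure()]), `energy` (model + pseudo terms, kcal/mol),
#'   `condition_id`, `sample_index`.
#' @export
sample_structures <- function(sequence, pseudo = NULL,
                              model = energy_model(), n = 1000L,
                              seed = NULL, condition_id = "") {
  if (n < 1L) stop("n must be >= 1")
  ft <- if (inherits(sequence, "fold_tables")) sequence
        else partition_function(sequence, pseudo, model,
                                probabilities = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  min_h <- ft$model$min_hairpin
  lapply(seq_len(n), function(k) {
    pr <- .traceback_one(ft$q, ft$Zm, ft$Zb, min_h, ft$sigma, ft$n)
    s <- secondary_structure(ft$n, pr, sequence = ft$sequence,
                             min_hairpin = min_h)
    en <- .structure_energy(pr, ft$E, ft$pseudo, ft$model$stack, ft$n)
    structure(list(structure = s, energy = en, condition_id = condition_id,
                   sample_index = k),
              class = "structure_sample")
  })
}

# ---- MSA consensus pseudo-condition ----------------------------------------

#' Covariation-scored consensus energies for an alignment
#'
#' For every column pair `(i, j)` satisfying the hairpin constraint, the
#' score is the mean pair energy over sequences whose residues at the two
#' columns form a WC/GU pair, plus `covariation_bonus` for every distinct
#' observed pair type beyond the first (compensatory mutations preserving
#' pairing are evidence for a conserved pair), plus `inconsistency_penalty`
#' for every sequence that cannot pair there (including gapped residues).
#' Column pairs where no sequence can pair are disallowed.
#'
#' @param aln A [msa()] object.
#' @param model An [energy_model()].
#' @param covariation_bonus Energy bonus per extra observed pair type
#'   (default -1.0 kcal/mol).
#' @param inconsistency_penalty Energy penalty per non-pairing sequence
#'   (default +0.5 kcal/mol).
#' @return n_columns x n_columns matrix of consensus energies (NA where
#'   disallowed).
#' @export
consensus_energy_matrix <- function(aln, model = energy_model(),
                                    covariation_bonus = -1.0,
                                    inconsistency_penalty = 0.5) {
  stopifnot(inherits(aln, "probefold_msa"))
  rows <- lapply(aln$sequences, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  nc <- aln$n_columns
  E <- matrix(NA_real_, nc, nc)
  if (nc < model$min_hairpin + 2L) return(E)
  for (i in seq_len(nc - model$min_hairpin - 1L)) {
    for (j in (i + model$min_hairpin + 1L):nc) {
      es <- vapply(rows, function(r) {
        a <- r[i]; b <- r[j]
        if (a == "-" || b == "-") return(NA_real_)
        .pair_type_energy(a, b, model)
      }, numeric(1))
      ok <- !is.na(es)
      if (!any(ok)) next
      types <- vapply(rows[ok], function(r) paste0(r[i], r[j]), character(1))
      E[i, j] <- mean(es[ok]) +
        covariation_bonus * max(0L, length(unique(types)) - 1L) +
        inconsistency_penalty * sum(!ok)
    }
  }
  E
}

#' Sample consensus structures from an alignment
#'
#' Folds the alignment's columns with [consensus_energy_matrix()] scores
#' using the same partition-function machinery, samples `n` structures,
#' and maps column indices to reference coordinates by deleting
#' reference-gap columns (pairs touching a reference gap are dropped). The
#' result is a "pseudo-condition": consensus samples treated exactly like
#' samples from an additional probing condition.
#'
#' @inheritParams consensus_energy_matrix
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param condition_id Label stored on the samples (default `"MSA"`).
#' @return List of `structure_sample` objects on reference coordinates.
#' @export
consensus_sample_from_msa <- function(aln, model = energy_model(),
                                      covariation_bonus = -1.0,
                                      inconsistency_penalty = 0.5,
                                      n = 1000L, seed = NULL,
                                      condition_id = "MSA") {
  stopifnot(inherits(aln, "probefold_msa"))
  E <- consensus_energy_matrix(aln, model, covariation_bonus,
                               inconsistency_penalty)
  nc <- aln$n_columns
  q <- .pair_weights(E, numeric(nc), model$RT)
  sigma <- exp(-model$stack / model$RT)
  tabs <- .inside_tables(q, model$min_hairpin, sigma)
  ref <- strsplit(aln$sequences[[aln$reference]], "", fixed = TRUE)[[1L]]
  keep <- ref != "-"
  col2ref <- integer(nc)
  col2ref[keep] <- seq_len(sum(keep))
  ref_seq <- paste(ref[keep], collapse = "")
  if (!is.null(seed)) set.seed(as.integer(seed))
  lapply(seq_len(n), function(k) {
    pr <- .traceback_one(q, tabs$Zm, tabs$Zb, model$min_hairpin, sigma, nc)
    en <- .structure_energy(pr, E, numeric(nc), model$stack, nc)
    if (NROW(pr)) {
      ok <- keep[pr[, 1L]] & keep[pr[, 2L]]
      pr <- pr[ok, , drop = FALSE]
      pr <- cbind(col2ref[pr[, 1L]], col2ref[pr[, 2L]])
    }
    s <- secondary_structure(sum(keep), pr, sequence = ref_seq,
                             min_hairpin = 0L)
    structure(list(structure = s, energy = en, condition_id = condition_id,
                   sample_index = k),
              class = "structure_sample")
  })
}
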