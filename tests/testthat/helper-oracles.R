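# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration instead of dynamic programming,
# literal rule transcription instead of the vectorized implementations.

# All nested structures of a length-n molecule, given an allowed-pair
# indicator matrix (hairpin >= 4 enforced as j - i >= 5 would be wrong:
# the default minimal hairpin loop is 3, i.e. j - i - 1 >= 3).
oracle_enum_structures <- function(n, allowed, min_hairpin = 3L) {
  rec <- function(i, j) {
    if (j - i < min_hairpin + 1L)
      return(list(matrix(integer(0), ncol = 2L)))
    out <- rec(i + 1L, j)
    for (k in seq(i + min_hairpin + 1L, j)) {
      if (!allowed[i, k]) next
      left <- rec(i + 1L, k - 1L)
      right <- if (k + 1L <= j) rec(k + 1L, j)
               else list(matrix(integer(0), ncol = 2L))
      for (L in left) for (R in right)
        out <- c(out, list(rbind(c(i, k), L, R)))
    }
    out
  }
  rec(1L, n)
}

# Energy of a pair set: pair energies + pseudo at paired positions + stack
# bonus per adjacency, counted by direct pair-set lookup.
oracle_energy <- function(pairs, E, pseudo, model) {
  if (!nrow(pairs)) return(0)
  e <- sum(E[pairs]) + sum(pseudo[c(pairs)])
  for (r in seq_len(nrow(pairs)))
    if (any(pairs[, 1L] == pairs[r, 1L] + 1L &
            pairs[, 2L] == pairs[r, 2L] - 1L))
      e <- e + model$stack
  e
}

# Exhaustive-enumeration partition function, pair probabilities and
# structure distribution.
oracle_partition <- function(sequence, pseudo = NULL,
                             model = energy_model()) {
  n <- nchar(sequence)
  if (is.null(pseudo)) pseudo <- numeric(n)
  E <- probefold:::.pair_energy_matrix(sequence, model)
  structs <- oracle_enum_structures(n, !is.na(E), model$min_hairpin)
  w <- vapply(structs,
              function(p) exp(-oracle_energy(p, E, pseudo, model) / model$RT),
              numeric(1))
  Z <- sum(w)
  P <- matrix(0, n, n)
  for (s in seq_along(structs)) {
    p <- structs[[s]]
    if (nrow(p)) P[p] <- P[p] + w[s]
  }
  keys <- vapply(structs, function(p) {
    db <- rep(".", n)
    if (nrow(p)) { db[p[, 1L]] <- "("; db[p[, 2L]] <- ")" }
    paste(db, collapse = "")
  }, character(1))
  list(Z = Z, P = P / Z, prob = stats::setNames(w / Z, keys))
}

# Literal transcription of the aggregation flag rule for one position.
oracle_aggregate_flag <- function(values, min_std = 0.15, min_ndata = 2L,
                                  med = 0.4, high = 0.7) {
  cls <- function(v) {
    ifelse(v == -10, "undefined",
           ifelse(v < med, "low", ifelse(v <= high, "medium", "high")))
  }
  x <- values[values != -10]
  if (length(x) < min_ndata) return("undetermined")
  m <- mean(x)
  s <- if (length(x) >= 2) sd(x) else 0
  if (s <= min_std) return("accepted")
  if (length(x) == 2) {
    return(if (cls(x[1]) == cls(x[2])) "accepted" else "nonconsistent")
  }
  pm <- combn(x, 2, mean)
  if (all(cls(pm) == cls(m))) return("accepted")
  if (length(unique(cls(pm))) == 1) return("warning")
  "nonconsistent"
}

# Literal per-position three-category classifier for structure comparison.
oracle_compare_category <- function(s1, s2) {
  p1 <- partner_vector(s1); p2 <- partner_vector(s2)
  vapply(seq_len(s1$length), function(i) {
    if (p1[i] == p2[i]) return("same")
    if (p1[i] > 0 && p2[i] > 0) return("paired_both_different_partner")
    "different_status"
  }, character(1))
}

# Random nested structure by sequential greedy pairing (independent of the
# package's samplers).
random_structure <- function(n, density = 0.3, min_hairpin = 3L) {
  avail <- rep(TRUE, n)
  pairs <- matrix(integer(0), ncol = 2L)
  intervals <- list(c(1L, n))
  while (length(intervals)) {
    iv <- intervals[[1L]]; intervals <- intervals[-1L]
    i <- iv[1L]; j <- iv[2L]
    if (j - i < min_hairpin + 1L) next
    if (stats::runif(1) < density) {
      rng <- (i + min_hairpin + 1L):j
      k <- rng[sample.int(length(rng), 1L)]
      pairs <- rbind(pairs, c(i, k))
      intervals <- c(intervals, list(c(i + 1L, k - 1L)))
      if (k + 1L <= j) intervals <- c(intervals, list(c(k + 1L, j)))
    } else {
      intervals <- c(intervals, list(c(i + 1L, j)))
    }
  }
  secondary_structure(n, pairs, min_hairpin = min_hairpin)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

make_sample <- function(db, condition_id = "c1", energy = 0) {
  structure(list(structure = parse_dotbracket(db), energy = energy,
                 condition_id = condition_id, sample_index = 1L),
            class = "structure_sample")
}
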