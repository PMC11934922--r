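test_that("pseudo-energy conversion follows m*ln(r+1)+b with a neutral sentinel", {
  expect_equal(pseudo_energy(-10), 0)
  expect_equal(pseudo_energy(0), -0.8)
  expect_equal(pseudo_energy(exp(1) - 1), 1.8)
  expect_equal(pseudo_energy(c(-10, 0, exp(1) - 1)), c(0, -0.8, 1.8))
  expect_error(pseudo_energy(-1.5), "not interpretable")
})

test_that("degenerate sequences have a single-structure ensemble", {
  f <- partition_function("AAAA")
  expect_equal(f$Z, 1)
  expect_true(all(f$pair_probabilities == 0))
  # a pairable duo is geometrically forbidden by the hairpin constraint
  f <- partition_function("GC")
  expect_equal(f$Z, 1)
  expect_error(partition_function("ACGX"), "alphabet")
})

test_that("partition function and pair probabilities match exhaustive enumeration", {
  set.seed(51)
  cases <- c("GGGAAACCC", "GGGGAAAACCCC", "GCGCAAAAGCGC",
             replicate(8, random_rna(sample(6:12, 1))))
  for (seq in cases) {
    n <- nchar(seq)
    pseudo <- round(stats::runif(n, -0.5, 1.5), 2)
    o <- oracle_partition(seq, pseudo)
    f <- partition_function(seq, pseudo)
    expect_equal(f$Z, o$Z, tolerance = 1e-12)
    expect_equal(f$pair_probabilities, o$P, tolerance = 1e-12)
  }
})

test_that("an all-sentinel pseudo vector reproduces the unconstrained ensemble exactly", {
  seq <- "GGGGAAAACCCC"
  f0 <- partition_function(seq)
  f1 <- partition_function(seq, pseudo_energy(rep(-10, nchar(seq))))
  expect_identical(f1$Z, f0$Z)
  expect_identical(f1$pair_probabilities, f0$pair_probabilities)
})

test_that("sampling is reproducible under a fixed seed", {
  a <- sample_structures("GGGGAAAACCCC", n = 200, seed = 7)
  b <- sample_structures("GGGGAAAACCCC", n = 200, seed = 7)
  expect_identical(vapply(a, function(s) as_dotbracket(s$structure), ""),
                   vapply(b, function(s) as_dotbracket(s$structure), ""))
})

test_that("empirical pair frequencies converge to the exact pair probabilities", {
  seq <- "GGGAAACCC"
  n <- 4000
  f <- partition_function(seq)
  smp <- sample_structures(seq, n = n, seed = 99)
  emp <- matrix(0, nchar(seq), nchar(seq))
  for (s in smp) {
    pr <- s$structure$pairs
    if (NROW(pr)) emp[pr] <- emp[pr] + 1 / n
  }
  p <- f$pair_probabilities
  bound <- 3 * sqrt(p * (1 - p) / n) + 1e-9
  expect_true(all(abs(emp - p) <= bound))
})

test_that("sample energies are recomputable from the model", {
  set.seed(52)
  seq <- random_rna(20)
  pseudo <- stats::runif(20, -0.5, 1)
  smp <- sample_structures(seq, pseudo, n = 50, seed = 5)
  E <- probefold:::.pair_energy_matrix(seq, energy_model())
  for (s in smp[1:10]) {
    expect_equal(s$energy,
                 oracle_energy(s$structure$pairs, E, pseudo, energy_model()))
  }
})

test_that("raising a position's reactivity never raises its paired probability", {
  seq <- "GGCGAAAACGCC"
  n <- nchar(seq)
  for (pos in c(1, 3, 6, 10)) {
    r_lo <- rep(0.2, n)
    r_hi <- r_lo; r_hi[pos] <- 2.0
    p_lo <- partition_function(seq, pseudo_energy(r_lo))$pair_probabilities
    p_hi <- partition_function(seq, pseudo_energy(r_hi))$pair_probabilities
    marg <- function(P, i) sum(P[i, ]) + sum(P[, i])
    expect_lte(marg(p_hi, pos), marg(p_lo, pos) + 1e-12)
  }
})

test_that("a gap-free identical-sequence MSA folds like the single sequence", {
  seq <- "GGCGCAAAAGCGCC"
  aln <- msa(c(ref = seq, s1 = seq, s2 = seq))
  E <- consensus_energy_matrix(aln)
  Es <- probefold:::.pair_energy_matrix(seq, energy_model())
  expect_equal(E, Es)
  smp <- consensus_sample_from_msa(aln, n = 500, seed = 3)
  sngl <- sample_structures(seq, n = 500, seed = 3)
  freq <- function(ss) {
    t <- table(vapply(ss, function(s) as_dotbracket(s$structure), ""))
    sort(t / sum(t), decreasing = TRUE)
  }
  f1 <- freq(smp); f2 <- freq(sngl)
  expect_equal(names(f1)[1], names(f2)[1])
  expect_lt(abs(f1[1] - f2[1]), 0.1)
})

test_that("a compensatory mutation earns exactly one covariation bonus", {
  # GC in the reference is CG in the second row at the same columns
  aln <- msa(c(ref = "GAAAAC", s1 = "CAAAAG"))
  E <- consensus_energy_matrix(aln, covariation_bonus = -1,
                               inconsistency_penalty = 0.5)
  # mean pair energy of {GC, CG} = -3; two distinct pair types -> one bonus
  expect_equal(E[1, 6], -3 + (-1) * 1)
  # same-type alignment: no bonus
  aln2 <- msa(c(ref = "GAAAAC", s1 = "GAAAAC"))
  expect_equal(consensus_energy_matrix(aln2)[1, 6], -3)
  # one sequence that cannot pair: penalty, no bonus
  aln3 <- msa(c(ref = "GAAAAC", s1 = "GAAAAA"))
  expect_equal(consensus_energy_matrix(aln3)[1, 6], -3 + 0.5)
})

test_that("pairs touching a reference gap column are dropped on mapping", {
  # reference has a gap at the paired 3' column; the partner column pairs in
  # the other rows only
  aln <- msa(c(ref = "GGAAAAC-C", s1 = "GGAAAACCC", s2 = "GGAAAACCC"))
  smp <- consensus_sample_from_msa(aln, n = 300, seed = 11)
  expect_equal(smp[[1]]$structure$length, 8L)
  # column 8 is a reference gap: no mapped pair may involve ref position 8
  # incorrectly; every pair must lie within 1..8 and respect the mapping
  for (s in smp) {
    pr <- s$structure$pairs
    if (NROW(pr)) expect_true(all(pr >= 1 & pr <= 8))
  }
  expect_error(msa(c(a = "ACGUA", b = "ACGUA"), reference = "zz"), "absent")
})
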