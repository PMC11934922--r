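test_that("base-pair distance is the symmetric-difference metric", {
  s1 <- parse_dotbracket("((...))")
  s2 <- parse_dotbracket(".......")
  expect_equal(bp_distance(s1, s1), 0L)
  expect_equal(bp_distance(s1, s2), 2L)
  expect_error(bp_distance(s1, parse_dotbracket("....")), "different lengths")

  set.seed(61)
  for (k in 1:30) {
    n <- sample(15:40, 1)
    a <- random_structure(n); b <- random_structure(n); c <- random_structure(n)
    expect_equal(bp_distance(a, b), bp_distance(b, a))
    expect_lte(bp_distance(a, c), bp_distance(a, b) + bp_distance(b, c))
    expect_equal(bp_distance(a, a), 0L)
  }
})

test_that("clustering groups identical samples and separates distant sets", {
  pool <- replicate(20, make_sample("((((....))))"), simplify = FALSE)
  cl <- cluster_pool(pool)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$size, 20L)
  expect_equal(as_dotbracket(cl[[1]]$centroid), "((((....))))")

  # two tight sets at mutual distance >= 10
  a <- "((((((((((....))))))))))......"
  b <- "......((((((((((....))))))))))"
  pool <- c(replicate(15, make_sample(a), simplify = FALSE),
            replicate(10, make_sample(b), simplify = FALSE))
  cl <- cluster_pool(pool)
  expect_length(cl, 2L)
  sizes <- sort(vapply(cl, `[[`, integer(1), "size"))
  expect_equal(sizes, c(10L, 15L))
  cents <- sort(vapply(cl, function(x) as_dotbracket(x$centroid), ""))
  expect_equal(cents, sort(c(a, b)))
})

test_that("cluster memberships are invariant under pool permutation", {
  set.seed(62)
  base <- c("((((....))))........", "....((((....))))....",
            "........((((....))))", "....................")
  pool <- lapply(sample(rep(base, times = c(8, 6, 4, 2))), make_sample)
  key_sets <- function(clusters, pool) {
    sets <- lapply(clusters, function(cl)
      sort(vapply(cl$members, function(i) as_dotbracket(pool[[i]]$structure),
                  "")))
    sets[order(vapply(sets, paste, "", collapse = "|"))]
  }
  cl1 <- cluster_pool(pool)
  perm <- sample(length(pool))
  cl2 <- cluster_pool(pool[perm])
  expect_equal(key_sets(cl1, pool), key_sets(cl2, pool[perm]))
})

test_that("cluster scores multiply smoothed per-condition occupancies", {
  # single condition, 60% occupancy -> 0.61
  pool <- c(replicate(6, make_sample("((((....))))"), simplify = FALSE),
            replicate(4, make_sample("............"), simplify = FALSE))
  cl <- cluster_pool(pool)
  big <- cl[[which.max(vapply(cl, `[[`, integer(1), "size"))]]
  expect_equal(score_cluster(big), 0.61)

  # cross-condition support beats single-condition dominance:
  # (0.5+0.01)^2 = 0.2601 > (1+0.01)(0+0.01) = 0.0101
  shared <- "((((((((((....))))))))))......"
  solo <- "......((((((((((....))))))))))"
  pool <- c(replicate(5, make_sample(shared, "c1"), simplify = FALSE),
            replicate(5, make_sample(solo, "c1"), simplify = FALSE),
            replicate(10, make_sample(shared, "c2"), simplify = FALSE))
  cl <- cluster_pool(pool)
  scores <- vapply(cl, score_cluster, numeric(1))
  cents <- vapply(cl, function(x) as_dotbracket(x$centroid), "")
  expect_equal(unname(scores[cents == shared]), 1.01 * 0.51)
  expect_equal(unname(scores[cents == solo]), 0.51 * 0.01)
})

test_that("centroids keep exactly the pairs above half intra-cluster frequency", {
  s <- list(parse_dotbracket("((...))"), parse_dotbracket("(.....)"),
            parse_dotbracket("......."))
  cen <- centroid(s)
  expect_equal(cen$pairs, rbind(c(1L, 7L)))
  # frequency exactly 0.5 is excluded
  s4 <- c(s, list(parse_dotbracket("((...))")))
  cen <- centroid(s4) # (1,7): 3/4; (2,6): 2/4
  expect_equal(cen$pairs, rbind(c(1L, 7L)))
  # identical structures return that structure
  cen <- centroid(list(parse_dotbracket("((...))"), parse_dotbracket("((...))")))
  expect_equal(as_dotbracket(cen), "((...))")
})

test_that("prediction is deterministic and separates best from second cluster", {
  bs <- benchmark_structure()
  set.seed(63)
  shape <- simulate_profiles(bs, probe_model("shape_like"), 3, seed = 100)
  agg <- aggregate_replicates(lapply(shape, preprocess_profile,
                                     warn_length = FALSE))
  p1 <- predict_structures(bs$sequence, list(shape = agg), n_samples = 150,
                           seed = 17)
  p2 <- predict_structures(bs$sequence, list(shape = agg), n_samples = 150,
                           seed = 17)
  expect_equal(as_dotbracket(p1$best), as_dotbracket(p2$best))
  expect_equal(vapply(p1$clusters, `[[`, numeric(1), "score"),
               vapply(p2$clusters, `[[`, numeric(1), "score"))
  if (length(p1$clusters) >= 2) {
    expect_false(identical(sort(p1$clusters[[1]]$members),
                           sort(p1$clusters[[2]]$members)))
    expect_false(is.null(p1$second))
  }
  # scores are ranked
  sc <- vapply(p1$clusters, `[[`, numeric(1), "score")
  expect_true(all(diff(sc) <= 1e-12))
})

test_that("prediction warns but proceeds when no reactivity is accepted", {
  seq <- "GGGCAAAAGCCC"
  expect_warning(
    p <- predict_structures(seq, list(c1 = rep(-10, nchar(seq))),
                            n_samples = 100, seed = 2),
    "unconstrained")
  expect_s3_class(p$best, "secondary_structure")
})

test_that("prediction outputs are written in the documented layout", {
  bs <- benchmark_structure()
  shape <- simulate_profiles(bs, probe_model("shape_like"), 2, seed = 5)
  agg <- aggregate_replicates(lapply(shape, preprocess_profile,
                                     warn_length = FALSE))
  p <- predict_structures(bs$sequence, list(shape = agg), n_samples = 100,
                          seed = 3)
  d <- withr::local_tempdir()
  write_prediction(p, d, name = "run1")
  expect_true(file.exists(file.path(d, "best.dbn")))
  expect_true(file.exists(file.path(d, "clusters.tsv")))
  expect_true(file.exists(file.path(d, "colors_shape.txt")))
  best <- read_dotbracket(file.path(d, "best.dbn"))
  expect_equal(best$pairs, p$best$pairs)
  tsv <- read.delim(file.path(d, "clusters.tsv"))
  expect_equal(nrow(tsv), length(p$clusters))
  expect_true(all(c("cluster", "size", "score", "occ_shape") %in% names(tsv)))
})
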