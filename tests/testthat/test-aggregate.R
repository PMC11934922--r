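make_reps <- function(...) {
  vals <- list(...)
  lapply(seq_along(vals), function(i)
    reactivity_profile(vals[[i]], rna_id = "r", condition_id = "c",
                       replicate_id = paste0("rep", i)))
}

test_that("aggregation reproduces the worked flag examples", {
  # tight replicates: sd ~0.02 <= 0.15, accepted
  a <- aggregate_replicates(make_reps(0.50, 0.52, 0.48))
  expect_equal(a$table$flag, "accepted")
  expect_equal(a$table$mean, 0.5)

  # wide spread: pairwise means 0.30/0.50/0.70 span {low, medium}
  a <- aggregate_replicates(make_reps(0.10, 0.50, 0.90))
  expect_equal(a$table$flag, "nonconsistent")

  # a single replicate runs with min_ndata clamped to 1
  a <- aggregate_replicates(make_reps(0.6))
  expect_equal(a$table$flag, "accepted")
  expect_equal(a$table$mean, 0.6)
  expect_equal(a$table$std, 0)
})

test_that("the flag rule matches an independently coded evaluator on a grid", {
  grid <- expand.grid(a = seq(0, 1.2, by = 0.3), b = seq(0, 1.2, by = 0.3),
                      c = seq(0, 1.2, by = 0.3))
  profs <- make_reps(grid$a, grid$b, grid$c)
  agg <- aggregate_replicates(profs)
  expected <- vapply(seq_len(nrow(grid)),
                     function(i) oracle_aggregate_flag(as.numeric(grid[i, ])),
                     character(1))
  expect_equal(agg$table$flag, expected)
})

test_that("aggregation is symmetric under replicate permutation", {
  set.seed(41)
  vals <- lapply(1:4, function(i) round(stats::rexp(30), 2))
  a <- aggregate_replicates(do.call(make_reps, vals))
  b <- aggregate_replicates(do.call(make_reps, rev(vals)))
  expect_equal(a$table, b$table)
})

test_that("two-replicate positions use the same-class guard", {
  # sd > 0.15 but both values in class low: accepted
  a <- aggregate_replicates(make_reps(0.05, 0.39))
  expect_gt(a$table$std, 0.15)
  expect_equal(a$table$flag, "accepted")
  # sd > 0.15 and classes differ: nonconsistent
  a <- aggregate_replicates(make_reps(0.1, 0.45))
  expect_equal(a$table$flag, "nonconsistent")
})

test_that("positions with too few valid values are undetermined with mean -10", {
  a <- aggregate_replicates(make_reps(c(0.5, -10), c(-10, -10), c(-10, 0.4)))
  expect_equal(a$table$flag, c("undetermined", "undetermined"))
  expect_equal(a$table$mean, c(-10, -10))
  expect_equal(a$table$n_valid, c(1L, 1L))
  expect_equal(modeling_reactivities(a), c(-10, -10))
})

test_that("the warning flag is unreachable for replicate triples (a convexity fact)", {
  # The total mean is the average of the pairwise means, and reactivity
  # classes are intervals: if every pairwise mean falls in one class, the
  # total mean falls in it too, satisfying the acceptance criterion. The
  # category is kept in the schema, but no value triple can produce it —
  # confirmed on a fine grid by both the implementation and the oracle.
  grid <- expand.grid(a = seq(0, 1.2, by = 0.1), b = seq(0, 1.2, by = 0.1),
                      c = seq(0, 1.2, by = 0.1))
  fl <- vapply(seq_len(nrow(grid)),
               function(i) oracle_aggregate_flag(as.numeric(grid[i, ])),
               character(1))
  expect_equal(sum(fl == "warning"), 0L)
  profs <- make_reps(grid$a, grid$b, grid$c)
  expect_equal(sum(aggregate_replicates(profs)$table$flag == "warning"), 0L)
})

test_that("replicate correlations report Pearson and Spearman over common positions", {
  set.seed(42)
  v <- sort(stats::runif(30))
  p <- make_reps(v, v, rev(v))
  rc <- replicate_correlations(p)
  expect_equal(rc$pearson["rep1", "rep2"], 1)
  expect_equal(rc$spearman["rep1", "rep2"], 1)
  expect_equal(rc$spearman["rep1", "rep3"], -1)
  expect_true(isSymmetric(rc$pearson))

  # disjoint valid positions -> undefined
  a <- c(0.1, 0.2, 0.3, -10, -10, -10)
  b <- c(-10, -10, -10, 0.1, 0.2, 0.3)
  rc <- replicate_correlations(make_reps(a, b))
  expect_true(is.na(rc$pearson["rep1", "rep2"]))
  expect_equal(rc$pairs$n_common, 0L)
})

test_that("primer concatenation places segments and resolves overlaps", {
  agg_from <- function(vals) aggregate_replicates(make_reps(vals, vals + 0.01))
  s1 <- agg_from(rep(0.4, 50))
  s2 <- agg_from(rep(0.6, 50))
  # disjoint 1..50 and 51..100
  cc <- concatenate_primers(list(list(profile = s1, start = 1, end = 50),
                                 list(profile = s2, start = 51, end = 100)))
  expect_equal(cc$length, 100L)
  expect_equal(cc$table$mean[1:50], rep(0.405, 50))
  expect_equal(cc$table$mean[51:100], rep(0.605, 50))

  # overlap 45..50: both accepted -> average of the means
  cc <- concatenate_primers(list(list(profile = s1, start = 1, end = 50),
                                 list(profile = s2, start = 45, end = 94)))
  expect_equal(cc$table$mean[45:50], rep((0.405 + 0.605) / 2, 6))
  expect_equal(cc$table$flag[45:50], rep("accepted", 6))

  # overlap where one side is undetermined -> the other side is kept
  v <- rep(0.4, 50); v[50] <- -10
  s3 <- aggregate_replicates(make_reps(v, ifelse(v == -10, -10, v)))
  expect_equal(s3$table$flag[50], "undetermined")
  cc <- concatenate_primers(list(list(profile = s3, start = 1, end = 50),
                                 list(profile = s2, start = 50, end = 99)))
  expect_equal(cc$table$mean[50], 0.605)
  expect_equal(cc$table$flag[50], "accepted")

  # uncovered positions stay undetermined
  cc <- concatenate_primers(list(list(profile = s1, start = 11, end = 60)),
                            total_length = 70)
  expect_equal(cc$table$flag[1:10], rep("undetermined", 10))
  expect_equal(cc$table$flag[61:70], rep("undetermined", 10))

  # conflicting RNA ids are refused
  s4 <- s2; s4$rna_id <- "other"
  expect_error(concatenate_primers(list(list(profile = s1, start = 1, end = 50),
                                        list(profile = s4, start = 51, end = 100))),
               "different RNAs")
})

test_that("aggregation rejects mismatched or empty inputs", {
  expect_error(aggregate_replicates(list()), "no profiles")
  p1 <- reactivity_profile(rep(0.5, 10))
  p2 <- reactivity_profile(rep(0.5, 12))
  expect_error(aggregate_replicates(list(p1, p2)), "different lengths")
})
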