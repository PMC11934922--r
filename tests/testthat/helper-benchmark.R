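# The desk-scale recovery benchmark shared by the multi-condition and MSA
# acceptance checks: the designed three-hairpin RNA probed by synthetic
# SHAPE-like and DMS-like conditions (3 replicates each, log-normal noise
# sigma 0.3), predictions from each condition alone, both together, and
# both plus a simulated compensatory-mutation alignment. Computed once per
# test run and cached.
.benchmark_cache <- new.env(parent = emptyenv())

benchmark_f1_matrix <- function(n_seeds = 20L, n_samples = 500L) {
  key <- paste0("f1_", n_seeds, "_", n_samples)
  if (!is.null(.benchmark_cache[[key]])) return(.benchmark_cache[[key]])
  bs <- benchmark_structure()
  res <- vapply(seq_len(n_seeds), function(sd) {
    shape <- simulate_profiles(bs, probe_model("shape_like"), 3,
                               seed = derive_seed(sd, "shape"))
    dms <- simulate_profiles(bs, probe_model("dms_like"), 3,
                             seed = derive_seed(sd, "dms"))
    pre <- function(ps) lapply(ps, preprocess_profile, warn_length = FALSE)
    agg_s <- aggregate_replicates(pre(shape))
    agg_d <- aggregate_replicates(pre(dms))
    aln <- simulate_msa(bs, n_seqs = 10, mutation_rate = 0.1,
                        seed = derive_seed(sd, "msa"))
    conds <- list(shape = agg_s, dms = agg_d)
    f1 <- function(p) f1_score(p$best, bs)
    c(shape = f1(predict_structures(bs$sequence, conds["shape"],
                                    n_samples = n_samples, seed = sd)),
      dms = f1(predict_structures(bs$sequence, conds["dms"],
                                  n_samples = n_samples, seed = sd)),
      both = f1(predict_structures(bs$sequence, conds,
                                   n_samples = n_samples, seed = sd)),
      with_msa = f1(predict_structures(bs$sequence, conds, aln = aln,
                                       n_samples = n_samples, seed = sd)))
  }, numeric(4))
  .benchmark_cache[[key]] <- res
  res
}
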