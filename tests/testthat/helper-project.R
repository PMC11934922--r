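# Build a small self-contained demo project around the benchmark RNA:
# two probing conditions (SHAPE-like and DMS-like), three replicates each,
# one prediction run combining both, and one footprint comparison.
build_demo_project <- function(dir, n_samples = 80L, seed = 1L,
                               extra_discarded_row = FALSE) {
  bs <- benchmark_structure()
  init_project(dir, name = "demo")
  rows <- list()
  for (probe in c("shape", "dms")) {
    pm <- probe_model(if (probe == "shape") "shape_like" else "dms_like")
    reps <- simulate_profiles(bs, pm, n_replicates = 3,
                              seed = derive_seed(seed, probe))
    for (r in seq_along(reps)) {
      fn <- sprintf("raw/%s_%s_rep%d.tsv", "bench", probe, r)
      write_reactivity_tsv(reps[[r]], file.path(dir, "resources", fn))
      rows[[length(rows) + 1L]] <-
        data.frame(rna_id = "bench", probe = probe, condition = "native",
                   replicate = as.character(r), primer_start = 1L,
                   primer_end = bs$length, file_path = fn,
                   experimentalist = "qa", discarded = FALSE)
    }
  }
  samples <- do.call(rbind, rows)
  if (extra_discarded_row) {
    fake <- samples[1, ]
    fake$replicate <- "99"
    fake$file_path <- "raw/does_not_exist.tsv"
    fake$discarded <- TRUE
    samples <- rbind(samples, fake)
  }
  write_samples_table(samples, file.path(dir, "samples.tsv"))
  write_fasta_sequences(c(bench = bs$sequence),
                        file.path(dir, "resources", "sequences", "bench.fa"))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$seed <- as.integer(seed)
  cfg$engine$n_samples <- as.integer(n_samples)
  cfg$runs <- list(list(name = "integrated", rna = "bench",
                        conditions = list("shape:native", "dms:native")))
  cfg$footprints <- list(list(name = "probe_vs_probe", rna = "bench",
                              cond1 = "shape:native", cond2 = "dms:native"))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(bs)
}

# Hashes of every result file (manifest and log excluded), for
# byte-identity comparisons.
results_digest <- function(dir) {
  files <- sort(list.files(file.path(dir, "results"), recursive = TRUE,
                           full.names = TRUE))
  files <- files[!grepl("\\.manifest", files)]
  stats::setNames(as.character(tools::md5sum(files)),
                  sub(paste0("^", dir, "/?"), "", files))
}
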