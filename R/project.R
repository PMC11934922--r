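# Project lifecycle: initialization, YAML configuration, samples-table
# management, and stage orchestration with content-hash staleness checks so
# re-runs only recompute what changed. Every result file is reproducible
# from the project directory, the config and the seed alone.

.project_dirs <- c("resources/raw", "resources/sequences", "resources/msa",
                   "results/1-preprocess", "results/2-aggregate",
                   "results/3-predict", "results/4-footprint",
                   "results/5-compare", "results/.manifest")

.default_config <- function(name) {
  list(
    project = name,
    seed = 42L,
    normalization = list(method = "simple"),
    aggregation = list(min_std = 0.15, min_ndata = 2L),
    classes = list(reactivity_medium = 0.4, reactivity_high = 0.7),
    engine = list(n_samples = 1000L, m = 2.6, b = -0.8,
                  covariation_bonus = -1.0, inconsistency_penalty = 0.5,
                  max_k = 10L),
    footprint = list(diff_threshold = 0.2, alpha = 0.05),
    runs = list(),        # e.g. list(name=, rna=, conditions=list(...), msa=)
    footprints = list()   # e.g. list(name=, rna=, cond1=, cond2=)
  )
}

#' Initialize a project directory
#'
#' Creates the resources folders (raw reactivity files, sequences, MSAs),
#' per-stage results folders, a samples.tsv template, a config file with
#' documented defaults, and the run log. Refuses to initialize into a
#' nonempty directory.
#'
#' @param dir Target directory.
#' @param name Project name (default: the directory's base name).
#' @return The project directory, invisibly.
#' @export
init_project <- function(dir, name = basename(normalizePath(dir,
                                                            mustWork = FALSE))) {
  if (dir.exists(dir) && length(list.files(dir, all.files = TRUE,
                                           no.. = TRUE)))
    stop("refusing to initialize into nonempty directory: ", dir)
  for (d in .project_dirs)
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(.default_config(name), file.path(dir, "config.yaml"))
  empty <- data.frame(rna_id = character(0), probe = character(0),
                      condition = character(0), replicate = character(0),
                      primer_start = integer(0), primer_end = integer(0),
                      file_path = character(0),
                      experimentalist = character(0),
                      discarded = logical(0))
  write_samples_table(empty, file.path(dir, "samples.tsv"))
  writeLines(character(0), file.path(dir, "project.log"))
  invisible(dir)
}

#' Load a project
#'
#' @param dir Project directory created by [init_project()].
#' @return List with `dir`, `config` and `samples`.
#' @export
load_project <- function(dir) {
  cfg_path <- file.path(dir, "config.yaml")
  if (!file.exists(cfg_path)) stop("not a project directory: ", dir)
  list(dir = dir, config = yaml::read_yaml(cfg_path),
       samples = read_samples_table(file.path(dir, "samples.tsv")))
}

# md5 of a canonical serialization of any R object (used for config and
# input hashing; content-based, robust to file copying).
.object_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(x), tmp)
  unname(tools::md5sum(tmp))
}

.file_hash <- function(path) unname(tools::md5sum(path))

# Stage-output staleness: outputs are regenerated unless their recorded
# input/config hash matches.
.is_fresh <- function(proj_dir, key, hash, outputs) {
  man <- file.path(proj_dir, "results", ".manifest", paste0(key, ".txt"))
  file.exists(man) && identical(readLines(man, warn = FALSE), hash) &&
    all(file.exists(outputs))
}

.mark_fresh <- function(proj_dir, key, hash) {
  man <- file.path(proj_dir, "results", ".manifest", paste0(key, ".txt"))
  writeLines(hash, man)
}

.log_line <- function(proj_dir, ...) {
  cat(paste0(paste(..., sep = " "), "\n"),
      file = file.path(proj_dir, "project.log"), append = TRUE)
}

.preproc_name <- function(row) {
  sprintf("%s_%s_%s_%s_%d-%d.tsv", row$rna_id, row$probe, row$condition,
          row$replicate, row$primer_start, row$primer_end)
}

#' Run pipeline stages of a project
#'
#' Executes the configured stages in order: `preprocess` (outlier removal
#' and normalization of every non-discarded sample), `aggregate`
#' (replicate aggregation + correlation QC per RNA x probe x condition,
#' with multi-primer concatenation), `predict` (each configured prediction
#' run), `footprint` (each configured comparison). Intermediate results
#' live in identified per-stage folders; every stage records the config
#' hash and seed in the run log, and nothing outside the project directory
#' is written. Outputs whose inputs and configuration are unchanged (by
#' content hash) are reused, so adding an experiment later only recomputes
#' what it affects.
#'
#' @param dir Project directory.
#' @param stages Subset of `c("preprocess", "aggregate", "predict",
#'   "footprint")` (default: all, in order).
#' @param seed Master seed; default from the config.
#' @return The project directory, invisibly.
#' @export
run_pipeline <- function(dir,
                         stages = c("preprocess", "aggregate", "predict",
                                    "footprint"),
                         seed = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  proj <- load_project(dir)
  cfg <- proj$config
  if (is.null(seed)) seed <- cfg$seed
  seed <- as.integer(seed)
  cfg_hash <- .object_hash(cfg)
  samples <- active_samples(proj$samples)
  norm_cfg <- normalization_config(method = cfg$normalization$method)
  scheme <- class_scheme(cfg$classes$reactivity_medium,
                         cfg$classes$reactivity_high)
  cons_cfg <- consistency_config(min_std = cfg$aggregation$min_std,
                                 min_ndata = cfg$aggregation$min_ndata,
                                 scheme = scheme)

  if ("preprocess" %in% stages) {
    for (r in seq_len(nrow(samples))) {
      row <- samples[r, ]
      src <- file.path(dir, "resources", row$file_path)
      if (!file.exists(src))
        stop("preprocess: expected reactivity file missing: ", src)
      out <- file.path(dir, "results", "1-preprocess", .preproc_name(row))
      h <- .object_hash(list(.file_hash(src), cfg$normalization))
      if (.is_fresh(dir, paste0("pre_", .preproc_name(row)), h, out)) next
      prof <- read_reactivity_tsv(src, row$rna_id,
                                  paste(row$probe, row$condition, sep = ":"),
                                  row$replicate)
      prof <- preprocess_profile(prof, norm_cfg, warn_length = FALSE)
      write_reactivity_tsv(prof, out)
      .mark_fresh(dir, paste0("pre_", .preproc_name(row)), h)
      .log_line(dir, "preprocess", .preproc_name(row), "config", cfg_hash,
                "seed", seed)
    }
  }

  if ("aggregate" %in% stages) {
    groups <- split(seq_len(nrow(samples)),
                    paste(samples$rna_id, samples$probe, samples$condition,
                          sep = "_"))
    for (g in names(groups)) {
      rows <- samples[groups[[g]], ]
      ins <- file.path(dir, "results", "1-preprocess",
                       vapply(seq_len(nrow(rows)),
                              function(i) .preproc_name(rows[i, ]),
                              character(1)))
      if (!all(file.exists(ins)))
        stop("aggregate: expected preprocessed file missing: ",
             ins[!file.exists(ins)][1L])
      out_prof <- file.path(dir, "results", "2-aggregate",
                            paste0(g, ".tsv"))
      out_qc <- file.path(dir, "results", "2-aggregate",
                          paste0(g, "_qc.tsv"))
      h <- .object_hash(list(unname(vapply(ins, .file_hash, character(1))),
                             cfg$aggregation, cfg$classes))
      if (.is_fresh(dir, paste0("agg_", g), h, c(out_prof, out_qc))) next
      ranges <- unique(rows[, c("primer_start", "primer_end")])
      segs <- list()
      qc_lines <- "primer_range\trep1\trep2\tn_common\tpearson\tspearman"
      for (k in seq_len(nrow(ranges))) {
        sel <- rows$primer_start == ranges$primer_start[k] &
          rows$primer_end == ranges$primer_end[k]
        profs <- lapply(which(sel), function(i)
          read_reactivity_tsv(ins[i], rows$rna_id[i],
                              paste(rows$probe[i], rows$condition[i],
                                    sep = ":"),
                              rows$replicate[i]))
        for (pp in seq_along(profs)) profs[[pp]]$preprocessed <- TRUE
        agg <- aggregate_replicates(profs, cons_cfg)
        segs[[k]] <- list(profile = agg, start = ranges$primer_start[k],
                          end = ranges$primer_end[k])
        if (length(profs) >= 2L) {
          qc <- replicate_correlations(profs)$pairs
          qc_lines <- c(qc_lines,
                        sprintf("%d-%d\t%s\t%s\t%d\t%.10g\t%.10g",
                                ranges$primer_start[k], ranges$primer_end[k],
                                qc$rep1, qc$rep2, qc$n_common, qc$pearson,
                                qc$spearman))
        }
      }
      merged <- if (length(segs) == 1L && segs[[1L]]$start == 1L)
        segs[[1L]]$profile
      else concatenate_primers(segs)
      write_aggregated_tsv(merged, out_prof)
      writeLines(qc_lines, out_qc)
      .mark_fresh(dir, paste0("agg_", g), h)
      .log_line(dir, "aggregate", g, "config", cfg_hash, "seed", seed)
    }
  }

  if ("predict" %in% stages && length(cfg$runs)) {
    model <- energy_model()
    pe <- pseudo_energy_params(m = cfg$engine$m, b = cfg$engine$b)
    for (run in cfg$runs) {
      seq_path <- file.path(dir, "resources", "sequences",
                            paste0(run$rna, ".fa"))
      if (!file.exists(seq_path))
        stop("predict: expected sequence file missing: ", seq_path)
      sequence <- unname(read_fasta_sequences(seq_path)[1L])
      ins <- file.path(dir, "results", "2-aggregate",
                       paste0(run$rna, "_",
                              gsub(":", "_", unlist(run$conditions)),
                              ".tsv"))
      if (!all(file.exists(ins)))
        stop("predict: expected aggregated file missing: ",
             ins[!file.exists(ins)][1L])
      out_dir <- file.path(dir, "results", "3-predict", run$name)
      hash_in <- list(unname(vapply(ins, .file_hash, character(1))),
                      cfg$engine, seed)
      aln <- NULL
      if (!is.null(run$msa)) {
        msa_path <- file.path(dir, "resources", "msa", run$msa)
        if (!file.exists(msa_path))
          stop("predict: expected MSA file missing: ", msa_path)
        aln <- read_msa_fasta(msa_path)
        hash_in <- c(hash_in, .file_hash(msa_path))
      }
      h <- .object_hash(hash_in)
      if (.is_fresh(dir, paste0("run_", run$name), h,
                    file.path(out_dir, "best.dbn"))) next
      conds <- lapply(ins, .read_aggregated_tsv_values)
      names(conds) <- unlist(run$conditions)
      pred <- predict_structures(sequence, conds, aln = aln,
                                 n_samples = cfg$engine$n_samples,
                                 model = model, pe_params = pe,
                                 covariation_bonus =
                                   cfg$engine$covariation_bonus,
                                 inconsistency_penalty =
                                   cfg$engine$inconsistency_penalty,
                                 max_k = cfg$engine$max_k, seed = seed)
      write_prediction(pred, out_dir, name = run$name, scheme = scheme)
      .mark_fresh(dir, paste0("run_", run$name), h)
      .log_line(dir, "predict", run$name, "config", cfg_hash, "seed", seed)
    }
  }

  if ("footprint" %in% stages && length(cfg$footprints)) {
    fp_cfg <- footprint_config(cfg$footprint$diff_threshold,
                               cfg$footprint$alpha)
    for (fp in cfg$footprints) {
      reps <- function(cond) {
        sel <- samples$rna_id == fp$rna &
          paste(samples$probe, samples$condition, sep = ":") == cond
        if (!any(sel))
          stop("footprint: no samples for condition ", cond)
        lapply(which(sel), function(i)
          read_reactivity_tsv(file.path(dir, "results", "1-preprocess",
                                        .preproc_name(samples[i, ]))))
      }
      p1 <- reps(fp$cond1); p2 <- reps(fp$cond2)
      out_dir <- file.path(dir, "results", "4-footprint", fp$name)
      h <- .object_hash(list(lapply(p1, `[[`, "values"),
                             lapply(p2, `[[`, "values"), cfg$footprint))
      if (.is_fresh(dir, paste0("fp_", fp$name), h,
                    file.path(out_dir, "footprint.tsv"))) next
      rec <- footprint(p1, p2, fp_cfg)
      footprint_outputs(rec, out_dir)
      .mark_fresh(dir, paste0("fp_", fp$name), h)
      .log_line(dir, "footprint", fp$name, "config", cfg_hash, "seed", seed)
    }
  }
  invisible(dir)
}

# Modeling reactivity vector from an aggregated TSV (accepted means; the
# sentinel everywhere else).
.read_aggregated_tsv_values <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- rep(UNDETERMINED, max(df$position))
  acc <- df$flag == "accepted"
  out[df$position[acc]] <- df$mean[acc]
  out
}
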