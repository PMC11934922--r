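# Synthetic probing data: reactivity profiles with probe-specific
# observability and realistic noise, and compensatory-mutation alignments.
# Every pipeline stage is testable against a known ground-truth structure
# with data built by this module alone.

#' Probe model for simulated reactivities
#'
#' Emulates the two probe chemistries: SHAPE-like reagents report on every
#' nucleotide, DMS-like reagents only on A and C (the Watson-Crick face);
#' other positions are emitted as undetermined. Unpaired positions draw
#' from a Gamma(shape 3, scale 0.27) (mean ~0.8), paired positions from a
#' Gamma(shape 2, scale 0.05) (mean 0.1); both are nonnegative and
#' right-skewed like real normalized reactivities. Replicates multiply the
#' base value by mean-one log-normal noise; occasional x10 spikes emulate
#' the intrinsic RT stops that outlier removal targets, and dropouts emit
#' the sentinel.
#'
#' @param name `"shape_like"` or `"dms_like"`.
#' @param unpaired_shape,unpaired_scale Gamma parameters for unpaired
#'   positions (defaults 3, 0.27).
#' @param paired_shape,paired_scale Gamma parameters for paired positions
#'   (defaults 2, 0.05).
#' @param noise_sigma Log-normal sdlog of the multiplicative replicate
#'   noise (default 0.3); the meanlog is `-noise_sigma^2/2`, so the noise
#'   has mean one.
#' @param outlier_rate Per-value probability of a x10 spike (default
#'   0.01).
#' @param dropout_rate Per-value probability of an undetermined sentinel
#'   (default 0.02).
#' @return Object of class `probe_model`.
#' @export
probe_model <- function(name = c("shape_like", "dms_like"),
                        unpaired_shape = 3, unpaired_scale = 0.27,
                        paired_shape = 2, paired_scale = 0.05,
                        noise_sigma = 0.3, outlier_rate = 0.01,
                        dropout_rate = 0.02) {
  name <- match.arg(name)
  structure(list(name = name, unpaired_shape = unpaired_shape,
                 unpaired_scale = unpaired_scale,
                 paired_shape = paired_shape, paired_scale = paired_scale,
                 noise_sigma = noise_sigma, outlier_rate = outlier_rate,
                 dropout_rate = dropout_rate),
            class = "probe_model")
}

#' Simulate replicate reactivity profiles from a known structure
#'
#' A base reactivity is drawn once per position from the paired/unpaired
#' distribution dictated by the structure; each replicate multiplies it by
#' log-normal noise, then spikes and dropouts are applied independently.
#' DMS-like probes report only A/C positions; all others are sentinel.
#'
#' @param truth A [secondary_structure()] with its sequence.
#' @param probe A [probe_model()].
#' @param n_replicates Number of replicates (default 3).
#' @param seed Integer seed.
#' @param rna_id,condition_id Identifiers stored on the profiles.
#' @return List of `n_replicates` [reactivity_profile()]s.
#' @export
simulate_profiles <- function(truth, probe = probe_model(),
                              n_replicates = 3L, seed = NULL,
                              rna_id = "synthetic", condition_id = probe$name) {
  stopifnot(inherits(truth, "secondary_structure"))
  if (is.null(truth$sequence)) stop("structure must carry its sequence")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- truth$length
  paired <- partner_vector(truth) > 0L
  base <- numeric(n)
  base[paired] <- stats::rgamma(sum(paired), shape = probe$paired_shape,
                                scale = probe$paired_scale)
  base[!paired] <- stats::rgamma(sum(!paired), shape = probe$unpaired_shape,
                                 scale = probe$unpaired_scale)
  bases <- strsplit(truth$sequence, "", fixed = TRUE)[[1L]]
  observable <- if (probe$name == "dms_like") bases %in% c("A", "C")
                else rep(TRUE, n)
  lapply(seq_len(n_replicates), function(r) {
    v <- base * stats::rlnorm(n, meanlog = -probe$noise_sigma^2 / 2,
                              sdlog = probe$noise_sigma)
    spike <- stats::runif(n) < probe$outlier_rate
    v[spike] <- v[spike] * 10
    drop <- stats::runif(n) < probe$dropout_rate
    v[drop | !observable] <- UNDETERMINED
    reactivity_profile(v, rna_id = rna_id, condition_id = condition_id,
                       replicate_id = paste0("rep", r),
                       sequence = truth$sequence)
  })
}

.wc_pairs <- c(GC = "GC", CG = "CG", AU = "AU", UA = "UA", GU = "GU",
               UG = "UG")

#' Simulate a compensatory-mutation alignment from a known structure
#'
#' Each non-reference row mutates positions independently at
#' `mutation_rate`. A mutation at a paired position is compensatory with
#' probability `compensation` (default 0.9): the pair is replaced by a
#' random WC/GU pair type, co-mutating the partner so pairing is
#' preserved — the covariation signal a consensus folder exploits.
#' Non-compensated and unpaired mutations draw a random different base.
#' Gaps are introduced per row at `gap_rate`. The reference row is the
#' original (ungapped) sequence.
#'
#' @param truth A [secondary_structure()] with sequence.
#' @param n_seqs Total number of rows including the reference (default
#'   10).
#' @param mutation_rate Per-position mutation probability (default 0.1).
#' @param compensation Probability that a paired-position mutation
#'   preserves pairing (default 0.9).
#' @param gap_rate Per-position gap probability in non-reference rows
#'   (default 0.01).
#' @param seed Integer seed.
#' @return A [msa()] with reference row `"ref"`.
#' @export
simulate_msa <- function(truth, n_seqs = 10L, mutation_rate = 0.1,
                         compensation = 0.9, gap_rate = 0.01, seed = NULL) {
  stopifnot(inherits(truth, "secondary_structure"))
  if (is.null(truth$sequence)) stop("structure must carry its sequence")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ref <- strsplit(truth$sequence, "", fixed = TRUE)[[1L]]
  n <- truth$length
  partner <- partner_vector(truth)
  alphabet <- c("A", "C", "G", "U")
  rows <- list(ref = paste(ref, collapse = ""))
  for (s in seq_len(n_seqs - 1L)) {
    row <- ref
    mutate <- which(stats::runif(n) < mutation_rate)
    done <- logical(n)
    for (p in mutate) {
      if (done[p]) next
      if (partner[p] > 0L) {
        if (stats::runif(1L) < compensation) {
          pt <- sample(.wc_pairs, 1L)
          i <- min(p, partner[p]); j <- max(p, partner[p])
          row[i] <- substr(pt, 1L, 1L)
          row[j] <- substr(pt, 2L, 2L)
          done[partner[p]] <- TRUE
        } else {
          row[p] <- sample(setdiff(alphabet, row[p]), 1L)
        }
      } else {
        row[p] <- sample(setdiff(alphabet, row[p]), 1L)
      }
      done[p] <- TRUE
    }
    gaps <- stats::runif(n) < gap_rate
    row[gaps] <- "-"
    rows[[paste0("seq", s)]] <- paste(row, collapse = "")
  }
  msa(unlist(rows), reference = "ref")
}

#' Benchmark RNA with a designed stable structure
#'
#' A 62-nt three-hairpin RNA used throughout the package's recovery
#' benchmarks: GC-rich 7-bp stems with mutually non-complementary
#' sequences, GAAA-type loops and oligo-A linkers, so the designed fold is
#' strongly favored and registers are unambiguous. Loops and linkers
#' contain A and C, keeping the structure informative for DMS-like probes
#' as well.
#'
#' @return A [secondary_structure()] with sequence.
#' @export
benchmark_structure <- function() {
  h <- function(stem5, loop) {
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    stem3 <- paste(rev(comp[strsplit(stem5, "")[[1L]]]), collapse = "")
    list(seq = paste0(stem5, loop, stem3), nstem = nchar(stem5),
         nloop = nchar(loop))
  }
  h1 <- h("GGCGCUC", "GCAA")
  h2 <- h("GGGCACC", "CAAA")
  h3 <- h("GCCGUGG", "GACA")
  link <- "AACA"
  seqs <- c(h1$seq, link, h2$seq, link, h3$seq)
  seq <- paste(seqs, collapse = "")
  offs <- cumsum(c(0, nchar(seqs)))[c(1, 3, 5)]
  pairs <- do.call(rbind, Map(function(hp, off) {
    i <- off + seq_len(hp$nstem)
    j <- off + nchar(hp$seq) + 1L - seq_len(hp$nstem)
    cbind(i, j)
  }, list(h1, h2, h3), as.list(offs)))
  secondary_structure(nchar(seq), pairs, sequence = seq)
}
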