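# File formats: reactivity TSV, FASTA/MSA, dot-bracket files, samples table,
# color annotations. All coordinates are 1-based and inclusive.

#' Sentinel value marking an undetermined reactivity
#' @export
UNDETERMINED <- -10

#' Construct a reactivity profile
#'
#' One RNA x condition x replicate vector of per-nucleotide reactivities.
#' Positions are contiguous `1..length`; the sentinel `-10` marks positions
#' with no usable signal ("undetermined"), which every downstream stage
#' treats as missing.
#'
#' @param values Numeric vector of reactivities, position `i` at index `i`.
#' @param rna_id,condition_id,replicate_id Identifiers (free text).
#' @param sequence Optional nucleotide string of the same length.
#' @return Object of class `reactivity_profile`.
#' @export
reactivity_profile <- function(values, rna_id = "", condition_id = "",
                               replicate_id = "", sequence = NULL) {
  values <- as.numeric(values)
  if (!length(values)) stop("profile must contain at least one position")
  if (anyNA(values)) stop("reactivity values must not be NA; use -10")
  if (!is.null(sequence)) {
    sequence <- toupper(gsub("T", "U", as.character(sequence)[1L]))
    if (nchar(sequence) != length(values))
      stop("sequence length does not match profile length")
  }
  structure(list(rna_id = as.character(rna_id),
                 condition_id = as.character(condition_id),
                 replicate_id = as.character(replicate_id),
                 length = length(values),
                 values = values, sequence = sequence, preprocessed = FALSE),
            class = "reactivity_profile")
}

#' @export
print.reactivity_profile <- function(x, ...) {
  nv <- sum(x$values != UNDETERMINED)
  cat(sprintf("Reactivity profile%s: %d nt, %d determined (%s)\n",
              if (nzchar(x$rna_id))
                sprintf(" [%s/%s/%s]", x$rna_id, x$condition_id,
                        x$replicate_id) else "",
              x$length, nv,
              if (isTRUE(x$preprocessed)) "preprocessed" else "raw"))
  invisible(x)
}

#' Read a per-nucleotide reactivity file
#'
#' Tab-delimited text with the nucleotide number in the first column and its
#' reactivity in the second; lines starting with `#` are comments. Positions
#' absent from the file within `1..max(position)` are filled with the
#' undetermined sentinel `-10` (probing data routinely lacks primer-proximal
#' positions); values present in the file are returned unmodified.
#'
#' @param path Path to the file.
#' @param rna_id,condition_id,replicate_id Identifiers stored on the profile.
#' @return A [reactivity_profile()].
#' @export
read_reactivity_tsv <- function(path, rna_id = "", condition_id = "",
                                replicate_id = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  pos <- integer(0); val <- numeric(0)
  for (ln in which(keep)) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L)
      stop("malformed row at line ", ln, " of ", path, ": expected 2 columns")
    p <- suppressWarnings(as.integer(fields[1L]))
    v <- suppressWarnings(as.numeric(fields[2L]))
    if (is.na(p) || is.na(v))
      stop("malformed row at line ", ln, " of ", path, ": '", lines[ln], "'")
    pos <- c(pos, p); val <- c(val, v)
  }
  if (!length(pos)) stop("no data rows in ", path)
  if (anyDuplicated(pos))
    stop("duplicate position ", pos[duplicated(pos)][1L], " in ", path)
  if (any(pos < 1L)) stop("positions must be >= 1 in ", path)
  values <- rep(UNDETERMINED, max(pos))
  values[pos] <- val
  reactivity_profile(values, rna_id, condition_id, replicate_id)
}

#' Write a reactivity profile to TSV
#'
#' Inverse of [read_reactivity_tsv()]; values are written with enough
#' precision to round-trip (`%.10g`).
#'
#' @param profile A [reactivity_profile()].
#' @param path Output path.
#' @export
write_reactivity_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "reactivity_profile"))
  lines <- sprintf("%d\t%.10g", seq_len(profile$length), profile$values)
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (`.fa`/`.fas`/`.fasta`); `T` is converted to `U`.
#' @return Named character vector of uppercase sequences (gaps `-` kept).
#' @export
read_fasta_sequences <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = FALSE)
  out <- vapply(recs, function(r) toupper(gsub("T", "U", as.character(r))),
                character(1L))
  names(out) <- names(recs)
  out
}

#' Write sequences to a FASTA file
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta_sequences <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(paste0(">", nm), con)
    writeLines(as.character(sequences[[nm]]), con)
  }
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' @param sequences Named character vector of aligned sequences (equal
#'   lengths, gaps `-`). The reference row must be gap-containing or not; its
#'   ungapped sequence is the molecule being modeled.
#' @param reference Name of the reference row (default: the first row).
#' @return Object of class `probefold_msa`.
#' @export
msa <- function(sequences, reference = names(sequences)[1L]) {
  if (length(sequences) < 2L) stop("an MSA needs at least 2 sequences")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("MSA sequences must be named")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("aligned sequences differ in length")
  if (!reference %in% names(sequences))
    stop("reference row '", reference, "' absent from alignment")
  sequences <- toupper(gsub("T", "U", sequences))
  structure(list(sequences = sequences, reference = reference,
                 n_columns = unname(lens[1L])),
            class = "probefold_msa")
}

#' Read an MSA from FASTA
#' @param path FASTA file with aligned (gapped) sequences.
#' @param reference Reference row name; default the first record.
#' @return A [msa()] object.
#' @export
read_msa_fasta <- function(path, reference = NULL) {
  seqs <- read_fasta_sequences(path)
  if (is.null(reference)) reference <- names(seqs)[1L]
  msa(seqs, reference = reference)
}

#' @export
print.probefold_msa <- function(x, ...) {
  cat("MSA:", length(x$sequences), "sequences x", x$n_columns,
      "columns; reference:", x$reference, "\n")
  invisible(x)
}

#' Write a structure to a dot-bracket (.dbn) file
#'
#' Three lines: `>name`, sequence (or `N` run when unknown), structure.
#'
#' @param x A [secondary_structure()].
#' @param path Output path.
#' @param name Record name.
#' @export
write_dotbracket <- function(x, path, name = "structure") {
  stopifnot(inherits(x, "secondary_structure"))
  seq <- if (is.null(x$sequence)) strrep("N", x$length) else x$sequence
  writeLines(c(paste0(">", name), seq, as_dotbracket(x)), path)
  invisible(path)
}

#' Read a dot-bracket (.dbn) file
#' @param path File with lines `>name`, sequence, structure.
#' @return A [secondary_structure()].
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("malformed dot-bracket file: ", path)
  if (startsWith(lines[1L], ">")) lines <- lines[-1L]
  if (length(lines) == 1L) return(parse_dotbracket(lines[1L]))
  seq <- lines[1L]
  s <- parse_dotbracket(lines[2L])
  if (grepl("^N+$", toupper(seq))) return(s)
  secondary_structure(s$length, s$pairs, sequence = seq, min_hairpin = 0L)
}

#' Reactivity class scheme
#'
#' Reactivities are binned into four classes: `undefined` for the sentinel
#' `-10`, `low` below `reactivity_medium`, `medium` in the closed interval
#' `[reactivity_medium, reactivity_high]`, and `high` above
#' `reactivity_high`.
#'
#' @param reactivity_medium Lower class boundary (default 0.4).
#' @param reactivity_high Upper class boundary (default 0.7).
#' @return Object of class `class_scheme`.
#' @export
class_scheme <- function(reactivity_medium = 0.4, reactivity_high = 0.7) {
  if (!(reactivity_medium > 0 && reactivity_medium < reactivity_high))
    stop("need 0 < reactivity_medium < reactivity_high")
  structure(list(reactivity_medium = reactivity_medium,
                 reactivity_high = reactivity_high),
            class = "class_scheme")
}

#' Assign reactivity classes
#'
#' @param values Numeric vector (may contain the sentinel `-10`).
#' @param scheme A [class_scheme()].
#' @return Character vector over `undefined`, `low`, `medium`, `high`.
#' @export
reactivity_class <- function(values, scheme = class_scheme()) {
  out <- character(length(values))
  und <- values == UNDETERMINED
  out[und] <- "undefined"
  out[!und & values < scheme$reactivity_medium] <- "low"
  out[!und & values >= scheme$reactivity_medium &
        values <= scheme$reactivity_high] <- "medium"
  out[!und & values > scheme$reactivity_high] <- "high"
  out
}

#' Write a per-nucleotide color annotation file
#'
#' One line per position: position, value, reactivity class — consumable by
#' structure viewers that accept per-nucleotide class maps. A values-only
#' one-column variant (a plain color map) is written when
#' `values_only = TRUE`.
#'
#' @param values Numeric vector of reactivities (sentinel `-10` allowed).
#' @param path Output path.
#' @param scheme A [class_scheme()].
#' @param length Declared RNA length; must equal `length(values)`.
#' @param values_only Write the one-column variant instead.
#' @return The path, invisibly.
#' @export
write_color_annotation <- function(values, path, scheme = class_scheme(),
                                   length = base::length(values),
                                   values_only = FALSE) {
  if (base::length(values) != length)
    stop("annotation length ", base::length(values),
         " does not match declared RNA length ", length)
  if (values_only) {
    writeLines(sprintf("%.10g", values), path)
  } else {
    cls <- reactivity_class(values, scheme)
    writeLines(c("position\tvalue\tclass",
                 sprintf("%d\t%.10g\t%s", seq_along(values), values, cls)),
               path)
  }
  invisible(path)
}

# ---- samples table ----------------------------------------------------------

.samples_required_cols <- c("rna_id", "probe", "condition", "replicate",
                            "primer_start", "primer_end", "file_path",
                            "discarded")

#' Read the samples table (samples.tsv)
#'
#' The central table describing every experiment of a project: one row per
#' RNA x probe x condition x replicate x primer range, pointing at its
#' reactivity file. Rows with `discarded = TRUE` are excluded from all
#' downstream stages. Extra columns (e.g. `experimentalist`) are kept as free
#' annotation.
#'
#' @param path Path to samples.tsv.
#' @return A `data.frame` with at least the required columns.
#' @export
read_samples_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.samples_required_cols, names(df))
  if (length(missing))
    stop("samples table misses column(s): ", paste(missing, collapse = ", "))
  df$discarded <- as.logical(df$discarded)
  df$primer_start <- as.integer(df$primer_start)
  df$primer_end <- as.integer(df$primer_end)
  key <- paste(df$rna_id, df$probe, df$condition, df$replicate,
               df$primer_start, df$primer_end)
  if (anyDuplicated(key))
    stop("duplicate sample row: ", key[duplicated(key)][1L])
  df
}

#' Write a samples table
#' @param df Samples data.frame (see [read_samples_table()]).
#' @param path Output path.
#' @export
write_samples_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Active (non-discarded) rows of a samples table
#' @param df Samples data.frame.
#' @return The subset with `discarded == FALSE`.
#' @export
active_samples <- function(df) {
  df[!df$discarded, , drop = FALSE]
}
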