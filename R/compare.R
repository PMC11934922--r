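# Structure-model comparison: per-position three-category classification
# (for color-annotated side-by-side rendering) and base-pair F1 scoring
# against a reference model.

#' Compare two secondary structure models position by position
#'
#' Each position falls into one of three categories: `same` — identical
#' pairing status in both models and, if paired, the same partner;
#' `paired_both_different_partner` — paired in both models but with
#' different partners; `different_status` — paired in exactly one model.
#' The classification is symmetric in the two structures.
#'
#' @param s1,s2 [secondary_structure()]s of equal length.
#' @return `data.frame` with columns `position` and `category`.
#' @export
compare_structures <- function(s1, s2) {
  stopifnot(inherits(s1, "secondary_structure"),
            inherits(s2, "secondary_structure"))
  if (s1$length != s2$length)
    stop("cannot compare structures of different lengths (",
         s1$length, " vs ", s2$length, ")")
  p1 <- partner_vector(s1)
  p2 <- partner_vector(s2)
  category <- ifelse(p1 == p2, "same",
                     ifelse(p1 > 0L & p2 > 0L,
                            "paired_both_different_partner",
                            "different_status"))
  data.frame(position = seq_len(s1$length), category = category)
}

#' Base-pair F1 score of a model against a reference
#'
#' The harmonic mean of base-pair precision and recall with exact-pair
#' matching (no +-1 slippage tolerance): with
#' `TP = |pairs(model) inter pairs(reference)|`,
#' `precision = TP / |pairs(model)|`, `recall = TP / |pairs(reference)|`,
#' `F1 = 2PR / (P + R)`; defined as 0 when `TP = 0` and 1 when the two
#' nonempty pair sets are equal.
#'
#' @param model,reference [secondary_structure()]s of equal length.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(model, reference) {
  stopifnot(inherits(model, "secondary_structure"),
            inherits(reference, "secondary_structure"))
  if (model$length != reference$length)
    stop("cannot score structures of different lengths")
  km <- .pair_keys(model)
  kr <- .pair_keys(reference)
  tp <- length(intersect(km, kr))
  if (tp == 0L) return(0)
  p <- tp / length(km)
  r <- tp / length(kr)
  2 * p * r / (p + r)
}

#' Write structure-comparison annotation files
#'
#' Two files: `common.txt` marks positions with a common structure (1 for
#' `same`, 0 otherwise); `categories.txt` carries the three-category
#' classification with one configurable color per category (defaults
#' blue/red/white for same / paired-with-different-partner / different
#' status).
#'
#' @param records A [compare_structures()] result.
#' @param dir Output directory.
#' @param colors Named character vector of colors for the three
#'   categories.
#' @return The directory, invisibly.
#' @export
write_compare_annotation <- function(records, dir,
                                     colors = c(
                                       same = "blue",
                                       paired_both_different_partner = "red",
                                       different_status = "white")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("position\tcommon",
               sprintf("%d\t%d", records$position,
                       as.integer(records$category == "same"))),
             file.path(dir, "common.txt"))
  writeLines(c("position\tcategory\tcolor",
               sprintf("%d\t%s\t%s", records$position, records$category,
                       unname(colors[records$category]))),
             file.path(dir, "categories.txt"))
  invisible(dir)
}
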