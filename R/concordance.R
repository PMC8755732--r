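#' Identity keys of a variant set
#'
#' The identity tuple used for set membership in concordance computations:
#' (chrom, pos, ref, alt) plus, by default, the genotype. Keys are returned
#' sorted so downstream output is deterministic.
#'
#' @param x A [variant_set()].
#' @param class_filter One of `"ALL"`, `"SNV"`, `"INS"`, `"DEL"`; class
#'   filtering happens before keys are formed.
#' @param genotype Include the genotype in the key (default `TRUE`).
#' @return Sorted character vector of unique keys.
#' @export
variant_keys <- function(x, class_filter = c("ALL", "SNV", "INS", "DEL"),
                         genotype = TRUE) {
  stopifnot(inherits(x, "variant_set"))
  class_filter <- match.arg(class_filter)
  if (class_filter != "ALL") x <- x[x$vclass == class_filter, , drop = FALSE]
  if (nrow(x) == 0) return(character())
  k <- if (genotype) {
    paste(x$chrom, x$pos, x$ref, x$alt, x$genotype, sep = ":")
  } else {
    paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  }
  sort(unique(k))
}

#' Intersection-over-union (Jaccard index) of two variant sets
#'
#' `|A' \eqn{\cap} B'| / |A' \eqn{\cup} B'|` over variant identity keys,
#' where `A'`, `B'` are the class-filtered sets. Two empty filtered sets
#' give 1 (identical emptiness); one empty set gives 0. These degenerate
#' conventions only matter for fixtures with no variants of a class.
#'
#' @inheritParams variant_keys
#' @param a,b [variant_set()] objects.
#' @return A fraction in `[0, 1]`.
#' @export
iou <- function(a, b, class_filter = c("ALL", "SNV", "INS", "DEL"),
                genotype = TRUE) {
  class_filter <- match.arg(class_filter)
  ka <- variant_keys(a, class_filter, genotype)
  kb <- variant_keys(b, class_filter, genotype)
  if (length(ka) == 0 && length(kb) == 0) return(1)
  if (length(ka) == 0 || length(kb) == 0) return(0)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' All-vs-all IoU matrix for a list of variant sets
#'
#' Produces the symmetric pairwise Jaccard matrix used for concordance
#' heatmaps, per variant class. Labels are taken from each set's
#' `sample_label` (made unique) and the ordering follows the input list.
#'
#' @param sets A list of at least two [variant_set()] objects.
#' @inheritParams variant_keys
#' @return An object of class `iou_matrix`: a symmetric numeric matrix
#'   with attribute `class_filter`.
#' @export
iou_matrix <- function(sets, class_filter = c("ALL", "SNV", "INS", "DEL"),
                       genotype = TRUE) {
  class_filter <- match.arg(class_filter)
  stopifnot(is.list(sets), length(sets) >= 2)
  labels <- make.unique(vapply(
    sets, function(s) as.character(attr(s, "sample_label") %||% "sample"),
    ""))
  keys <- lapply(sets, variant_keys, class_filter = class_filter,
                 genotype = genotype)
  n <- length(sets)
  m <- matrix(1, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      ka <- keys[[i]]; kb <- keys[[j]]
      v <- if (length(ka) == 0 && length(kb) == 0) 1
           else if (length(ka) == 0 || length(kb) == 0) 0
           else length(intersect(ka, kb)) / length(union(ka, kb))
      m[i, j] <- v
      m[j, i] <- v
    }
    if (length(keys[[i]]) == 0) m[i, i] <- 1  # empty-set convention
  }
  structure(m, class_filter = class_filter, class = c("iou_matrix",
                                                      class(m)))
}

#' Long-format pairs table from an IoU matrix
#'
#' @param m An [iou_matrix()].
#' @param upper_only Keep each unordered pair once (default `TRUE`).
#' @return A data frame with columns `a`, `b`, `iou`.
#' @export
iou_long <- function(m, upper_only = TRUE) {
  stopifnot(inherits(m, "iou_matrix"))
  sel <- if (upper_only) upper.tri(m) else row(m) != col(m)
  idx <- which(sel, arr.ind = TRUE)
  data.frame(a = rownames(m)[idx[, 1]],
             b = colnames(m)[idx[, 2]],
             iou = m[idx],
             stringsAsFactors = FALSE)
}
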