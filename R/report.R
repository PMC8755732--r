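#' Format fractions as percentage strings
#'
#' @param x Fractions in `[0, 1]` (NA allowed).
#' @param digits Decimal places (default 2, e.g. `"95.81"`).
#' @return Character vector; `NA` for undefined metrics.
#' @export
fmt_pct <- function(x, digits = 2) {
  ifelse(is.na(x), NA_character_,
         formatC(100 * x, format = "f", digits = digits))
}

#' Tabulate a three-way Venn partition
#'
#' @param v A [venn3()] result.
#' @return A data frame with `partition`, `bases`, `pct_of_triple_union`.
#' @export
venn_to_df <- function(v) {
  stopifnot(inherits(v, "venn3_result"))
  data.frame(partition = names(v$partition_bases),
             bases = unname(v$partition_bases),
             pct_of_triple_union = unname(v$pct_of_triple_union),
             stringsAsFactors = FALSE)
}

#' Write a Venn partition as TSV and JSON
#'
#' @param v A [venn3()] result.
#' @param tsv_path,json_path Output paths (`NULL` to skip one).
#' @return Invisibly, the written paths.
#' @export
write_venn <- function(v, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(v, "venn3_result"))
  if (!is.null(tsv_path)) {
    utils::write.table(venn_to_df(v), tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(labels = as.list(v$labels),
           partition_bases = as.list(v$partition_bases),
           pct_of_triple_union = as.list(v$pct_of_triple_union),
           union_bases = v$union_bases,
           pairwise = v$pairwise),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv_path, json_path))
}

#' Accuracy table in the benchmark layout
#'
#' One row per class (SNV, indel) with the columns Total, In PG,
#' Not in PG, PG-specific, Samples-specific and the three percentage
#' metrics (two decimals).
#'
#' @param x A [joint_confusion()].
#' @param metrics Optional precomputed [compute_metrics()] result.
#' @return A data frame.
#' @export
confusion_to_df <- function(x, metrics = compute_metrics(x)) {
  stopifnot(inherits(x, "joint_confusion"))
  data.frame(
    class = c("SNV", "indel"),
    total = c(x$in_pg_snv + x$not_in_pg_snv + x$sample_specific_snv,
              x$in_pg_indel + x$not_in_pg_indel + x$sample_specific_indel),
    in_pg = c(x$in_pg_snv, x$in_pg_indel),
    not_in_pg = c(x$not_in_pg_snv, x$not_in_pg_indel),
    pg_specific = c(x$pg_specific_snv, x$pg_specific_indel),
    samples_specific = c(x$sample_specific_snv, x$sample_specific_indel),
    sensitivity_pct = fmt_pct(c(metrics$snv_sensitivity,
                                metrics$indel_sensitivity)),
    precision_pct = fmt_pct(c(metrics$snv_precision,
                              metrics$indel_precision)),
    f_measure_pct = fmt_pct(c(metrics$snv_f, metrics$indel_f)),
    stringsAsFactors = FALSE)
}

#' Write the accuracy table as TSV
#'
#' @param x A [joint_confusion()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confusion_tsv <- function(x, path) {
  utils::write.table(confusion_to_df(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an IoU matrix as TSV (with row/column labels)
#'
#' @param m An [iou_matrix()].
#' @param path Output path.
#' @param long Also write a long-format pairs table next to it
#'   (`*_pairs.tsv`).
#' @return `path`, invisibly.
#' @export
write_iou_tsv <- function(m, path, long = FALSE) {
  stopifnot(inherits(m, "iou_matrix"))
  df <- data.frame(sample = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (long) {
    utils::write.table(iou_long(m),
                       sub("\\.tsv$", "_pairs.tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a GC-depth grid as dense TSV plus JSON metadata
#'
#' @param g A [gc_depth_grid()].
#' @param tsv_path Dense grid (GC bins as rows).
#' @param json_path Metadata (bounds, dimensions, in-bounds point count).
#' @return Invisibly, the written paths.
#' @export
write_grid <- function(g, tsv_path, json_path = NULL) {
  stopifnot(inherits(g, "gc_depth_grid"))
  utils::write.table(g$grid, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(gc_bins = nrow(g$grid), depth_bins = ncol(g$grid),
           gc_range = g$gc_range, depth_range = g$depth_range,
           n_points_in_bounds = g$n_points_in_bounds),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv_path, json_path))
}

#' Write a pool quantile function as two-column TSV
#'
#' @param pq A [pool_quantile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quantile_tsv <- function(pq, path) {
  stopifnot(inherits(pq, "pool_quantile"))
  utils::write.table(pq$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
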