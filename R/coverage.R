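#' Per-base depth profiles (bedGraph semantics)
#'
#' A `depth_profile` is a data frame of constant-depth runs
#' (`chrom`, `start`, `end`, `depth`) in 0-based half-open coordinates.
#' Runs must be non-overlapping; bases absent from the profile have
#' depth 0.
#'
#' @param x Data frame with columns `chrom`, `start`, `end`, `depth`.
#' @return An object of class `depth_profile` (a data frame).
#' @export
depth_profile <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end", "depth")
  if (!all(need %in% names(x))) {
    stop("depth_profile needs columns chrom, start, end, depth")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)[need]
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start); x$end <- as.numeric(x$end)
  x$depth <- as.numeric(x$depth)
  if (nrow(x) > 0) {
    if (any(x$end <= x$start) || any(x$start < 0)) {
      stop("runs must satisfy 0 <= start < end")
    }
    if (any(x$depth < 0)) stop("depth must be >= 0")
    gr <- GenomicRanges::GRanges(x$chrom,
                                 IRanges::IRanges(x$start + 1, x$end))
    if (sum(GenomicRanges::width(GenomicRanges::reduce(gr))) <
        sum(x$end - x$start)) {
      stop("depth runs overlap")
    }
  }
  structure(x, class = c("depth_profile", "data.frame"))
}

#' Read a 4-column bedGraph file
#'
#' 0-based half-open runs with a numeric depth value; `track`/comment
#' lines are skipped and malformed lines are reported by line number.
#'
#' @inheritParams read_bed
#' @return A [depth_profile()].
#' @export
read_bedgraph <- function(path, chrom_style = c("strip", "add", "asis")) {
  chrom_style <- match.arg(chrom_style)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- .read_interval_lines(path, min_cols = 4L)
  names(df)[names(df) == "value"] <- "depth"
  df$chrom <- .restyle_chrom(df$chrom, chrom_style)
  depth_profile(df)
}

#' Write a depth profile as bedGraph
#'
#' @param x A [depth_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  df <- as.data.frame(x)
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  df$depth <- format(df$depth, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coverage summary over target regions
#'
#' Mean target coverage and the covered-at-depth curve: for each threshold
#' N, the fraction of target bases with depth >= N (the Picard-style
#' "covered xN" convention). Denominators are total target bases; target
#' bases absent from the profile count as depth 0.
#'
#' @param profile A [depth_profile()].
#' @param targets A normalized [interval_set()]; must be non-empty.
#' @param thresholds Depth thresholds (default `c(1, 5, 10, 20, 30)`).
#' @return An object of class `coverage_summary`: a list with
#'   `mean_coverage`, `covered_at` (named fractions), `target_bases`.
#' @export
coverage_summary <- function(profile, targets,
                             thresholds = c(1, 5, 10, 20, 30)) {
  stopifnot(inherits(profile, "depth_profile"))
  if (!isTRUE(attr(targets, "normalized"))) {
    targets <- normalize_intervals(targets)
  }
  if (nrow(targets) == 0) stop("empty target set")
  tb <- total_bases(targets)
  tg <- .as_granges(targets)
  covered_at <- stats::setNames(numeric(length(thresholds)),
                                as.character(thresholds))
  mean_cov <- 0
  if (nrow(profile) > 0) {
    pg <- GenomicRanges::GRanges(profile$chrom,
                                 IRanges::IRanges(profile$start + 1,
                                                  profile$end))
    h <- .harmonize_seqlevels(pg, tg)
    ov <- GenomicRanges::findOverlaps(h[[1]], h[[2]])
    if (length(ov) > 0) {
      w <- GenomicRanges::width(IRanges::pintersect(
        h[[1]][S4Vectors::queryHits(ov)],
        h[[2]][S4Vectors::subjectHits(ov)]))
      d <- profile$depth[S4Vectors::queryHits(ov)]
      mean_cov <- sum(d * w) / tb
      for (i in seq_along(thresholds)) {
        covered_at[i] <- sum(w[d >= thresholds[i]]) / tb
      }
    }
  }
  structure(list(mean_coverage = mean_cov, covered_at = covered_at,
                 target_bases = tb),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("<coverage_summary> mean %.2fx over %s target bases\n",
              x$mean_coverage, format(x$target_bases, big.mark = ",")))
  cat(paste(sprintf("covered x%s: %s%%", names(x$covered_at),
                    fmt_pct(x$covered_at)), collapse = "  "), "\n")
  invisible(x)
}

#' Per-sample read-category counts
#'
#' Counts of on-target, off-target, duplicate and un-aligned reads per
#' sample; the four categories must sum to `total` (supplied or derived).
#'
#' @param x Data frame with columns `sample`, `on_target`, `off_target`,
#'   `duplicates`, `un_aligned` and optionally `total`.
#' @return An object of class `read_category_counts` (a data frame).
#' @export
read_category_counts <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("sample", "on_target", "off_target", "duplicates", "un_aligned")
  if (!all(need %in% names(x))) {
    stop("need columns sample, on_target, off_target, duplicates, un_aligned")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  cats <- x$on_target + x$off_target + x$duplicates + x$un_aligned
  if (is.null(x$total)) {
    x$total <- cats
  } else if (any(x$total != cats)) {
    stop("read categories do not sum to total")
  }
  structure(x[c(need, "total")],
            class = c("read_category_counts", "data.frame"))
}

#' Read/write read-category count tables (TSV)
#'
#' @param path TSV with header `sample on_target off_target duplicates
#'   un_aligned [total]`.
#' @return A [read_category_counts()].
#' @export
read_counts_tsv <- function(path) {
  read_category_counts(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_counts_tsv
#' @param x A [read_category_counts()].
#' @export
write_counts_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Stacked read-category fractions
#'
#' Per-sample fractions of on-target, off-target, duplicate and un-aligned
#' reads (of total reads); the four fractions sum to 1.
#'
#' @param x A [read_category_counts()].
#' @return A data frame with `sample` and the four fraction columns.
#' @export
category_fractions <- function(x) {
  stopifnot(inherits(x, "read_category_counts"))
  if (any(x$total <= 0)) stop("zero total read count")
  data.frame(sample = x$sample,
             on_target = x$on_target / x$total,
             off_target = x$off_target / x$total,
             duplicates = x$duplicates / x$total,
             un_aligned = x$un_aligned / x$total,
             stringsAsFactors = FALSE)
}

#' GC-content vs mean-depth density grid
#'
#' The 2-D histogram used to profile GC bias: per-target
#' (GC fraction, mean depth) points falling inside the open rectangle
#' GC in (0, 1) and depth in (0, 1000) are binned on an evenly spaced
#' 200 (GC) x 100 (depth) grid; counts are then min-max normalized to
#' `[0, 1]` (so the densest cell is 1 whenever any point is in bounds).
#' Points on or outside the rectangle boundary are excluded.
#'
#' @param gc,depth Numeric vectors of per-target GC fraction and mean
#'   depth (recycled against each other must be equal length).
#' @param gc_bins,depth_bins Grid dimensions (defaults 200 and 100).
#' @param gc_range,depth_range Open bounding rectangle (defaults `(0, 1)`
#'   and `(0, 1000)`).
#' @return An object of class `gc_depth_grid`: a list with `grid`
#'   (normalized matrix, rows = GC bins, columns = depth bins), `counts`
#'   (raw matrix), `n_points_in_bounds`, `gc_range`, `depth_range`.
#' @export
gc_depth_grid <- function(gc, depth, gc_bins = 200, depth_bins = 100,
                          gc_range = c(0, 1), depth_range = c(0, 1000)) {
  stopifnot(length(gc) == length(depth))
  inb <- !is.na(gc) & !is.na(depth) &
    gc > gc_range[1] & gc < gc_range[2] &
    depth > depth_range[1] & depth < depth_range[2]
  gc <- gc[inb]; depth <- depth[inb]
  counts <- matrix(0L, nrow = gc_bins, ncol = depth_bins)
  if (length(gc) > 0) {
    gi <- pmin(gc_bins, pmax(1L, ceiling(
      (gc - gc_range[1]) / diff(gc_range) * gc_bins)))
    di <- pmin(depth_bins, pmax(1L, ceiling(
      (depth - depth_range[1]) / diff(depth_range) * depth_bins)))
    tab <- table(factor(gi, levels = seq_len(gc_bins)),
                 factor(di, levels = seq_len(depth_bins)))
    counts <- matrix(as.integer(tab), nrow = gc_bins)
  }
  rng <- range(counts)
  norm <- if (diff(rng) > 0) (counts - rng[1]) / diff(rng)
          else counts * 0
  structure(list(grid = norm, counts = counts,
                 n_points_in_bounds = length(gc),
                 gc_range = gc_range, depth_range = depth_range),
            class = "gc_depth_grid")
}

#' Empirical quantile function and imbalance of pool read totals
#'
#' For per-sample data totals (megabases or reads) in a sequencing pool:
#' the empirical quantile function (sorted totals vs cumulative
#' proportion), the imbalance delta (max minus min), and the fraction of
#' samples receiving less than a given total.
#'
#' @param totals Numeric vector of per-sample totals (>= 0).
#' @param labels Optional sample labels.
#' @return An object of class `pool_quantile`: a list with `points`
#'   (data frame `total`, `prop`, sorted and non-decreasing), `delta`,
#'   and the raw `totals`.
#' @export
pool_quantile <- function(totals, labels = NULL) {
  if (length(totals) == 0) stop("empty pool table")
  if (any(is.na(totals)) || any(totals < 0)) stop("totals must be >= 0")
  o <- order(totals)
  pts <- data.frame(total = totals[o],
                    prop = seq_along(totals) / length(totals))
  if (!is.null(labels)) pts$sample <- labels[o]
  structure(list(points = pts, delta = max(totals) - min(totals),
                 totals = totals),
            class = "pool_quantile")
}

#' Fraction of samples below a total
#'
#' Strictly-less-than convention: `fraction_below(pq, min(totals))` is 0
#' and `fraction_below(pq, x)` is 1 for any `x` above the maximum.
#'
#' @param pq A [pool_quantile()].
#' @param x Threshold total (vectorized).
#' @return Fraction(s) in `[0, 1]`.
#' @export
fraction_below <- function(pq, x) {
  stopifnot(inherits(pq, "pool_quantile"))
  vapply(x, function(v) mean(pq$totals < v), numeric(1))
}
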