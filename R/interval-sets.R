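#' Genomic interval sets for capture-design arithmetic
#'
#' An `interval_set` is a data frame of genomic intervals in BED convention
#' (0-based, half-open) with columns `chrom`, `start`, `end`, used to
#' represent a capture design or an exon track. Coordinates are 0-based
#' half-open at every interface of this package; VCF positions (1-based)
#' are converted at exactly one boundary (see [filter_variants()]).
#'
#' @param x A data frame with columns `chrom` (character), `start`, `end`
#'   (non-negative numbers, `end > start`). Extra columns (e.g. a per-target
#'   `gc` fraction) are carried along but ignored by interval arithmetic.
#' @param label Design name, e.g. `"vendor exome v4"`.
#' @param normalized Logical; set by [normalize_intervals()]. A normalized
#'   set is sorted by (chrom, start) and pairwise non-overlapping,
#'   non-adjacent within a chromosome.
#' @return An object of class `interval_set` (a data frame).
#' @export
interval_set <- function(x, label = "intervals", normalized = FALSE) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    stop("interval_set needs columns chrom, start, end")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (nrow(x) > 0) {
    if (any(is.na(x$chrom) | !nzchar(x$chrom))) stop("empty chromosome name")
    if (any(is.na(x$start) | is.na(x$end))) stop("NA coordinates")
    if (any(x$start < 0)) stop("start must be >= 0")
    if (any(x$end <= x$start)) stop("end must be > start (half-open)")
  }
  structure(x,
            class = c("interval_set", "data.frame"),
            label = label,
            raw_n = nrow(x),
            normalized = normalized)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %s: %d region(s), %s bases%s\n",
              attr(x, "label"), nrow(x),
              format(total_bases(x), big.mark = ","),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

# interval_set -> GRanges (1-based closed internally)
.as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
}

# GRanges -> interval_set rows (back to 0-based half-open)
.from_granges <- function(gr, label, raw_n = NA_integer_) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  out <- interval_set(df, label = label, normalized = TRUE)
  if (!is.na(raw_n)) attr(out, "raw_n") <- raw_n
  out
}

# Put two GRanges on a shared seqlevel universe so set ops don't warn.
.harmonize_seqlevels <- function(...) {
  grs <- list(...)
  sl <- Reduce(union, lapply(grs, GenomeInfoDb::seqlevels))
  lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <- sl
    g
  })
}

#' Read a BED3+ file into an interval set
#'
#' Reads tab-separated BED with at least three columns, skipping `track`,
#' `browser`, comment (`#`) and blank lines. Coordinates are taken verbatim
#' (BED 0-based half-open); the count of raw records is retained so that
#' region-count summaries can be reported pre-merge, as kit metadata
#' conventionally is. Chromosome-name dialects ("chr1" vs "1") are
#' harmonized at read time via `chrom_style`.
#'
#' @param path Path to a BED file.
#' @param label Design name; defaults to the file name.
#' @param chrom_style `"strip"` (default) removes a leading `"chr"`,
#'   `"add"` prepends it where missing, `"asis"` leaves names untouched.
#' @return An (un-normalized) [interval_set()].
#' @export
read_bed <- function(path, label = NULL,
                     chrom_style = c("strip", "add", "asis")) {
  chrom_style <- match.arg(chrom_style)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label)) label <- basename(path)
  df <- .read_interval_lines(path, min_cols = 3L)
  df$chrom <- .restyle_chrom(df$chrom, chrom_style)
  interval_set(df[c("chrom", "start", "end")], label = label)
}

.restyle_chrom <- function(chrom, style) {
  switch(style,
         strip = sub("^chr", "", chrom),
         add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)),
         asis = chrom)
}

# Shared line parser for BED3+ / bedGraph. Reports 1-based file line numbers
# in errors; skips header-ish lines.
.read_interval_lines <- function(path, min_cols) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_cols)) {
    bad <- idx[which(nf < min_cols)[1]]
    stop(sprintf("malformed line %d: fewer than %d tab-separated fields",
                 bad, min_cols))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start != trunc(start) |
    end != trunc(end) | end <= start | start < 0
  if (any(bad)) {
    b <- idx[which(bad)[1]]
    stop(sprintf(
      "malformed line %d: coordinates must be integers with end > start", b))
  }
  value <- rep(NA_real_, length(idx))
  if (min_cols >= 4L) {
    value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    if (anyNA(value)) {
      b <- idx[which(is.na(value))[1]]
      stop(sprintf("malformed line %d: non-numeric value field", b))
    }
  }
  data.frame(chrom = chrom, start = start, end = end, value = value,
             stringsAsFactors = FALSE)
}

#' Write an interval set as BED3
#'
#' @param x An [interval_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)[c("chrom", "start", "end")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalize an interval set
#'
#' Sorts by (chrom, start) and merges overlapping and book-ended (adjacent)
#' intervals; per-base membership is unchanged. Total bases can only stay
#' equal or shrink. Idempotent.
#'
#' @param x An [interval_set()].
#' @return A normalized [interval_set()] retaining the raw record count.
#' @export
normalize_intervals <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  raw_n <- attr(x, "raw_n")
  if (nrow(x) == 0) {
    out <- x
    attr(out, "normalized") <- TRUE
    return(out)
  }
  gr <- GenomicRanges::reduce(.as_granges(x))  # merges adjacent by default
  .from_granges(gr, label = attr(x, "label"), raw_n = raw_n)
}

#' Total bases spanned by an interval set
#'
#' Computed over the merged (normalized) intervals, so overlapping raw
#' records are not double-counted.
#'
#' @param x An [interval_set()].
#' @return Number of distinct bases covered.
#' @export
total_bases <- function(x) {
  if (nrow(x) == 0) return(0)
  if (!isTRUE(attr(x, "normalized"))) x <- normalize_intervals(x)
  sum(x$end - x$start)
}

#' Base-level set operations on interval sets
#'
#' A base is in the result iff the boolean operation on per-base memberships
#' holds. Results are normalized.
#'
#' @param a,b [interval_set()] objects.
#' @param op One of `"intersect"`, `"union"`, `"subtract"` (a minus b).
#' @return A normalized [interval_set()].
#' @export
interval_setop <- function(a, b, op = c("intersect", "union", "subtract")) {
  op <- match.arg(op)
  ga <- GenomicRanges::reduce(.as_granges(a))
  gb <- GenomicRanges::reduce(.as_granges(b))
  h <- .harmonize_seqlevels(ga, gb)
  res <- switch(op,
                intersect = GenomicRanges::intersect(h[[1]], h[[2]]),
                union = GenomicRanges::union(h[[1]], h[[2]]),
                subtract = GenomicRanges::setdiff(h[[1]], h[[2]]))
  lab <- sprintf("%s %s %s", attr(a, "label"), op, attr(b, "label"))
  .from_granges(GenomicRanges::reduce(res), label = lab)
}

#' @rdname interval_setop
#' @export
interval_intersect <- function(a, b) interval_setop(a, b, "intersect")

#' @rdname interval_setop
#' @export
interval_union <- function(a, b) interval_setop(a, b, "union")

#' @rdname interval_setop
#' @export
interval_subtract <- function(a, b) interval_setop(a, b, "subtract")

#' Summarize an interval set
#'
#' Region count and median region size are reported over the records as
#' given (vendor BED files report pre-merge record counts); `total_bases`
#' is always computed on the merged set so overlaps are not double-counted.
#'
#' @param x An [interval_set()].
#' @return A list with `total_bases`, `n_regions`, `median_region_size`.
#' @export
interval_summary <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  list(total_bases = total_bases(x),
       n_regions = nrow(x),
       median_region_size = if (nrow(x)) stats::median(x$end - x$start)
                            else NA_real_)
}

#' Three-way Venn partition of capture designs
#'
#' Partitions the union of three interval sets into the 7 disjoint regions
#' of a 3-set Venn diagram and reports base counts. Percentages for the
#' unique and triple-overlap regions are expressed relative to the 3-way
#' union; pairwise-overlap percentages are expressed relative to the
#' corresponding pairwise union. Both conventions are returned and labelled.
#'
#' @param a,b,e [interval_set()] objects (conventionally two capture
#'   designs and an exon track).
#' @return An object of class `venn3_result`: a list with
#'   `partition_bases` (named: A, B, E, AB, AE, BE, ABE), `union_bases`,
#'   `pct_of_triple_union`, `pairwise` (data frame with per-pair overlap
#'   bases, pairwise-union bases and percentage), and `labels`.
#' @export
venn3 <- function(a, b, e) {
  grs <- .harmonize_seqlevels(
    GenomicRanges::reduce(.as_granges(a)),
    GenomicRanges::reduce(.as_granges(b)),
    GenomicRanges::reduce(.as_granges(e)))
  ga <- grs[[1]]; gb <- grs[[2]]; ge <- grs[[3]]
  bases <- function(g) if (length(g)) sum(GenomicRanges::width(g)) else 0
  iab <- GenomicRanges::intersect(ga, gb)
  iae <- GenomicRanges::intersect(ga, ge)
  ibe <- GenomicRanges::intersect(gb, ge)
  iabe <- GenomicRanges::intersect(iab, ge)
  uab <- GenomicRanges::union(ga, gb)
  uae <- GenomicRanges::union(ga, ge)
  ube <- GenomicRanges::union(gb, ge)
  uall <- GenomicRanges::union(uab, ge)
  part <- c(
    A = bases(GenomicRanges::setdiff(ga, ube)),
    B = bases(GenomicRanges::setdiff(gb, uae)),
    E = bases(GenomicRanges::setdiff(ge, uab)),
    AB = bases(GenomicRanges::setdiff(iab, ge)),
    AE = bases(GenomicRanges::setdiff(iae, gb)),
    BE = bases(GenomicRanges::setdiff(ibe, ga)),
    ABE = bases(iabe))
  ub <- bases(uall)
  pct <- if (ub > 0) 100 * part / ub else part * 0
  pairwise <- data.frame(
    pair = c("AB", "AE", "BE"),
    overlap_bases = c(bases(iab), bases(iae), bases(ibe)),
    pairwise_union_bases = c(bases(uab), bases(uae), bases(ube)),
    stringsAsFactors = FALSE)
  pairwise$pct_of_pairwise_union <- ifelse(
    pairwise$pairwise_union_bases > 0,
    100 * pairwise$overlap_bases / pairwise$pairwise_union_bases, 0)
  structure(list(partition_bases = part,
                 union_bases = ub,
                 pct_of_triple_union = pct,
                 pairwise = pairwise,
                 labels = c(A = attr(a, "label"), B = attr(b, "label"),
                            E = attr(e, "label"))),
            class = "venn3_result")
}

#' @export
print.venn3_result <- function(x, ...) {
  cat("<venn3_result> A =", x$labels["A"], "| B =", x$labels["B"],
      "| E =", x$labels["E"], "\n")
  df <- data.frame(partition = names(x$partition_bases),
                   bases = unname(x$partition_bases),
                   pct_of_union = sprintf("%.2f", x$pct_of_triple_union))
  print(df, row.names = FALSE)
  cat("union:", format(x$union_bases, big.mark = ","), "bases\n")
  invisible(x)
}
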