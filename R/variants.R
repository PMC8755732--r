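#' Variant sets
#'
#' A `variant_set` is a data frame of small variants with columns `chrom`,
#' `pos` (1-based, VCF convention), `ref`, `alt`, `genotype` (unphased
#' diploid over the {0,1} alleles, e.g. `"0/1"`), `qual` (Phred-scaled
#' variant quality, `NA` if absent), `depth` (read depth DP, `NA` if
#' absent), and `vclass` (one of `"SNV"`, `"INS"`, `"DEL"`, `"OTHER"`).
#' Indel alleles are minimally normalized on construction: shared trailing
#' bases are trimmed, then shared leading bases beyond a single anchor base
#' are trimmed (advancing `pos`), so equivalent representations compare
#' equal without a reference FASTA. Records are unique on
#' (chrom, pos, ref, alt).
#'
#' @param x Data frame with at least `chrom`, `pos`, `ref`, `alt`,
#'   `genotype`; `qual`, `depth` default to `NA`.
#' @param sample_label Sample name.
#' @param provenance Free-text provenance (pool, protocol).
#' @return An object of class `variant_set` (a data frame).
#' @export
variant_set <- function(x, sample_label = "sample", provenance = "") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "pos", "ref", "alt", "genotype")
  if (!all(need %in% names(x))) {
    stop("variant_set needs columns chrom, pos, ref, alt, genotype")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(x$qual)) x$qual <- rep(NA_real_, nrow(x))
  if (is.null(x$depth)) x$depth <- rep(NA_real_, nrow(x))
  x$chrom <- as.character(x$chrom)
  x$pos <- as.numeric(x$pos)
  x$ref <- toupper(as.character(x$ref))
  x$alt <- toupper(as.character(x$alt))
  x$genotype <- .canonical_gt(as.character(x$genotype))
  x$qual <- as.numeric(x$qual)
  x$depth <- as.numeric(x$depth)
  if (nrow(x) > 0) {
    if (any(!nzchar(x$ref) | !nzchar(x$alt))) stop("empty ref or alt allele")
    norm <- .trim_alleles(x$pos, x$ref, x$alt)
    x$pos <- norm$pos; x$ref <- norm$ref; x$alt <- norm$alt
  }
  x$vclass <- variant_class(x$ref, x$alt)
  dup <- duplicated(paste(x$chrom, x$pos, x$ref, x$alt, sep = "\r"))
  n_dup <- sum(dup)
  if (n_dup > 0) x <- x[!dup, , drop = FALSE]
  rownames(x) <- NULL
  keep <- c("chrom", "pos", "ref", "alt", "genotype", "qual", "depth",
            "vclass")
  structure(x[keep],
            class = c("variant_set", "data.frame"),
            sample_label = sample_label,
            provenance = provenance,
            n_deduplicated = n_dup)
}

#' @export
print.variant_set <- function(x, ...) {
  tab <- table(factor(x$vclass, levels = c("SNV", "INS", "DEL", "OTHER")))
  cat(sprintf("<variant_set> %s: %d record(s) (SNV %d, INS %d, DEL %d, OTHER %d)\n",
              attr(x, "sample_label"), nrow(x),
              tab["SNV"], tab["INS"], tab["DEL"], tab["OTHER"]))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

# "0|1" -> "0/1"; allele order normalized so "1/0" == "0/1"
.canonical_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  vapply(parts, function(p) paste(sort(p), collapse = "/"), "")
}

#' Classify a variant by allele lengths
#'
#' `|ref| == |alt| == 1` is an SNV; `|ref| < |alt|` an insertion;
#' `|ref| > |alt|` a deletion; equal lengths > 1 are `OTHER` (MNV).
#'
#' @param ref,alt Allele strings (vectorized).
#' @return Character vector of `"SNV"`, `"INS"`, `"DEL"`, `"OTHER"`.
#' @export
variant_class <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == 1 & la == 1, "SNV",
         ifelse(lr < la, "INS",
                ifelse(lr > la, "DEL", "OTHER")))
}

# Minimal allele normalization: right-trim shared suffix, then left-trim
# shared prefix keeping one anchor base (pos advances). Vectorized via an
# iterative single-character trim; loop count bounded by max allele length.
.trim_alleles <- function(pos, ref, alt) {
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    can <- lr > 1 & la > 1 &
      substr(ref, lr, lr) == substr(alt, la, la)
    if (!any(can)) break
    ref[can] <- substr(ref[can], 1, lr[can] - 1)
    alt[can] <- substr(alt[can], 1, la[can] - 1)
  }
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    can <- lr > 1 & la > 1 & substr(ref, 1, 1) == substr(alt, 1, 1)
    if (!any(can)) break
    ref[can] <- substr(ref[can], 2, lr[can])
    alt[can] <- substr(alt[can], 2, la[can])
    pos[can] <- pos[can] + 1
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Read a single-sample VCF into a variant set
#'
#' Minimal ingestion of VCF 4.x via the vcfR parser: CHROM, POS, REF, ALT,
#' QUAL, FORMAT GT (required) and DP (FORMAT preferred, INFO fallback).
#' Multi-allelic lines are split into one record per ALT allele; the
#' per-allele genotype counts copies of that allele (2 copies -> `"1/1"`,
#' 1 -> `"0/1"`, 0 -> `"0/0"`). Missing DP/QUAL are recorded as `NA` and
#' fail any threshold filter.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param sample_label Sample name; defaults to the VCF sample column name.
#' @param chrom_style Chromosome-name harmonization, as in [read_bed()].
#' @return A [variant_set()].
#' @export
read_vcf <- function(path, sample_label = NULL,
                     chrom_style = c("strip", "add", "asis")) {
  chrom_style <- match.arg(chrom_style)
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # always a matrix, unlike getFIX() on one-record files
  if (is.null(fix) || nrow(fix) == 0) {
    return(variant_set(data.frame(chrom = character(), pos = numeric(),
                                  ref = character(), alt = character(),
                                  genotype = character()),
                       sample_label = sample_label %||% "sample"))
  }
  if (is.null(v@gt) || ncol(v@gt) < 2) stop("VCF has no sample genotypes")
  if (is.null(sample_label)) sample_label <- colnames(v@gt)[2]
  gt <- tryCatch(vcfR::extract.gt(v, "GT")[, 1],
                 error = function(e) stop("GT field is required: ",
                                          conditionMessage(e)))
  if (anyNA(gt)) stop("missing GT for ", sum(is.na(gt)), " record(s)")
  dp <- tryCatch(suppressWarnings(
    vcfR::extract.gt(v, "DP", as.numeric = TRUE)[, 1]),
    error = function(e) rep(NA_real_, nrow(fix)))
  if (all(is.na(dp))) {
    dp_info <- tryCatch(suppressWarnings(
      vcfR::extract.info(v, "DP", as.numeric = TRUE)),
      error = function(e) rep(NA_real_, nrow(fix)))
    if (!all(is.na(dp_info))) dp <- dp_info
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  chrom <- .restyle_chrom(fix[, "CHROM"], chrom_style)
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row <- rep(seq_along(alts), n_alt)
  alt_idx <- sequence(n_alt)
  alleles <- strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)
  copies <- mapply(function(al, k) sum(al == as.character(k)),
                   alleles[row], alt_idx)
  out <- data.frame(
    chrom = chrom[row], pos = pos[row], ref = ref[row],
    alt = unlist(alts, use.names = FALSE),
    genotype = c("0/0", "0/1", "1/1")[copies + 1],
    qual = qual[row], depth = dp[row],
    stringsAsFactors = FALSE)
  variant_set(out, sample_label = sample_label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a variant set as a minimal single-sample VCF
#'
#' Emits VCF 4.2 with QUAL and `FORMAT GT:DP`; round-trips through
#' [read_vcf()].
#'
#' @param x A [variant_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  sample <- attr(x, "sample_label") %||% "sample"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=wesbench",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample)), con)
  if (nrow(x) > 0) {
    o <- order(x$chrom, x$pos, x$ref, x$alt)
    x <- x[o, , drop = FALSE]
    qual <- ifelse(is.na(x$qual), ".", format(x$qual, trim = TRUE))
    dp <- ifelse(is.na(x$depth), ".",
                 format(round(x$depth), scientific = FALSE, trim = TRUE))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT:DP\t%s:%s",
                       x$chrom, as.integer(x$pos), x$ref, x$alt, qual,
                       x$genotype, dp), con)
  }
  invisible(path)
}

#' Filter variant calls by depth, quality and target membership
#'
#' Applies the call-set filter used throughout the evaluation: keep a
#' record iff `depth > min_depth` and `qual > min_qual` (strict
#' inequalities, e.g. DP > 13 and QUAL > 20 at the defaults; DP exactly 13
#' is removed) and, when a target set is given, the variant position lies
#' inside a target interval. The 1-based VCF position is converted to the
#' 0-based half-open BED frame here, at this single boundary. Records with
#' missing DP or QUAL fail the corresponding threshold.
#'
#' @param x A [variant_set()].
#' @param min_depth Exclusive depth threshold (default 13).
#' @param min_qual Exclusive quality threshold (default 20).
#' @param targets Optional [interval_set()] restriction (normalized).
#' @param strict Use strict `>` (default); `FALSE` uses `>=`.
#' @return The filtered [variant_set()]; attribute `removed` holds the
#'   number of records failing each criterion (counted independently).
#' @export
filter_variants <- function(x, min_depth = 13, min_qual = 20,
                            targets = NULL, strict = TRUE) {
  stopifnot(inherits(x, "variant_set"))
  cmp <- if (strict) `>` else `>=`
  depth_ok <- !is.na(x$depth) & cmp(x$depth, min_depth)
  qual_ok <- !is.na(x$qual) & cmp(x$qual, min_qual)
  if (!is.null(targets)) {
    if (!isTRUE(attr(targets, "normalized"))) {
      targets <- normalize_intervals(targets)
    }
    if (nrow(x) > 0 && nrow(targets) > 0) {
      pts <- GenomicRanges::GRanges(x$chrom,
                                    IRanges::IRanges(x$pos, x$pos))
      h <- .harmonize_seqlevels(pts, .as_granges(targets))
      target_ok <- GenomicRanges::countOverlaps(h[[1]], h[[2]]) > 0
    } else {
      target_ok <- rep(FALSE, nrow(x))
    }
  } else {
    target_ok <- rep(TRUE, nrow(x))
  }
  keep <- depth_ok & qual_ok & target_ok
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(x)
  attr(out, "sample_label") <- attrs$sample_label
  attr(out, "provenance") <- attrs$provenance
  attr(out, "removed") <- c(depth = sum(!depth_ok),
                            qual = sum(!qual_ok),
                            off_target = sum(!target_ok))
  class(out) <- c("variant_set", "data.frame")
  out
}
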