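#' Joint SNV/indel confusion matrix
#'
#' The eight tally categories used when a called variant set is compared
#' with a Platinum-Genomes-style truth set, with SNVs and indels treated as
#' one joint detection task:
#'
#' * `in_pg_snv` / `in_pg_indel` — calls exactly matching a truth record of
#'   the same class (chrom, pos, ref, alt and, by default, genotype).
#' * `not_in_pg_snv` — calls detected as SNV whose position holds an indel
#'   in the truth set; `not_in_pg_indel` the converse.
#' * `sample_specific_snv` / `sample_specific_indel` — calls matching no
#'   truth record at all.
#' * `pg_specific_snv` / `pg_specific_indel` — truth records never matched
#'   by any call.
#'
#' Every call lands in exactly one of the first six categories, so
#' `in_pg + not_in_pg + sample_specific` summed over classes equals the
#' called-set size.
#'
#' @param in_pg_snv,not_in_pg_snv,in_pg_indel,not_in_pg_indel,pg_specific_snv,pg_specific_indel,sample_specific_snv,sample_specific_indel
#'   Non-negative tallies.
#' @param n_calls,n_truth Set sizes (records of class SNV/INS/DEL).
#' @return An object of class `joint_confusion`.
#' @export
joint_confusion <- function(in_pg_snv = 0, not_in_pg_snv = 0,
                            in_pg_indel = 0, not_in_pg_indel = 0,
                            pg_specific_snv = 0, pg_specific_indel = 0,
                            sample_specific_snv = 0,
                            sample_specific_indel = 0,
                            n_calls = NA_real_, n_truth = NA_real_) {
  tallies <- c(in_pg_snv = in_pg_snv, not_in_pg_snv = not_in_pg_snv,
               in_pg_indel = in_pg_indel, not_in_pg_indel = not_in_pg_indel,
               pg_specific_snv = pg_specific_snv,
               pg_specific_indel = pg_specific_indel,
               sample_specific_snv = sample_specific_snv,
               sample_specific_indel = sample_specific_indel)
  if (any(tallies < 0)) stop("confusion tallies must be non-negative")
  structure(as.list(c(tallies, n_calls = n_calls, n_truth = n_truth)),
            class = "joint_confusion")
}

#' @export
print.joint_confusion <- function(x, ...) {
  cat("<joint_confusion>\n")
  df <- data.frame(
    class = c("SNV", "indel"),
    in_pg = c(x$in_pg_snv, x$in_pg_indel),
    not_in_pg = c(x$not_in_pg_snv, x$not_in_pg_indel),
    pg_specific = c(x$pg_specific_snv, x$pg_specific_indel),
    sample_specific = c(x$sample_specific_snv, x$sample_specific_indel))
  print(df, row.names = FALSE)
  invisible(x)
}

# SNV / indel collapse used for confusion tallies; OTHER (MNV) records are
# excluded from matching and counted separately.
.joint_class <- function(vclass) {
  ifelse(vclass == "SNV", "SNV",
         ifelse(vclass %in% c("INS", "DEL"), "indel", NA_character_))
}

#' Match a called variant set against a truth set
#'
#' A call matches a truth record iff (chrom, pos, ref, alt) and, when
#' `genotype = TRUE` (default), the genotype are all equal; matched calls
#' are tallied `in_pg` by their class. An unmatched call whose position
#' coincides with a truth record of the opposite class (SNV vs indel) is
#' tallied `not_in_pg` of the call's class. Any other unmatched call is
#' `sample_specific`; truth records never exactly matched are
#' `pg_specific`. A genotype mismatch at an otherwise matching site is a
#' non-match (sample-specific call plus PG-specific truth record) unless
#' `genotype = FALSE`. Records of class `OTHER` are excluded from matching.
#'
#' @param calls,truth [variant_set()] objects from the same coordinate
#'   space, deduplicated.
#' @param genotype Require genotype identity for a match (default `TRUE`).
#' @return A [joint_confusion()].
#' @export
match_truth <- function(calls, truth, genotype = TRUE) {
  stopifnot(inherits(calls, "variant_set"), inherits(truth, "variant_set"))
  cc <- .joint_class(calls$vclass)
  tc <- .joint_class(truth$vclass)
  calls <- calls[!is.na(cc), , drop = FALSE]; cc <- cc[!is.na(cc)]
  truth <- truth[!is.na(tc), , drop = FALSE]; tc <- tc[!is.na(tc)]
  key <- function(v) {
    if (genotype) paste(v$chrom, v$pos, v$ref, v$alt, v$genotype, sep = "\r")
    else paste(v$chrom, v$pos, v$ref, v$alt, sep = "\r")
  }
  ck <- key(calls); tk <- key(truth)
  exact <- ck %in% tk
  truth_matched <- tk %in% ck
  cpos <- paste(calls$chrom, calls$pos, sep = "\r")
  tpos <- paste(truth$chrom, truth$pos, sep = "\r")
  snv_pos <- unique(tpos[tc == "SNV"])
  indel_pos <- unique(tpos[tc == "indel"])
  other_class_hit <- !exact &
    ((cc == "SNV" & cpos %in% indel_pos) |
     (cc == "indel" & cpos %in% snv_pos))
  samp <- !exact & !other_class_hit
  joint_confusion(
    in_pg_snv = sum(exact & cc == "SNV"),
    not_in_pg_snv = sum(other_class_hit & cc == "SNV"),
    in_pg_indel = sum(exact & cc == "indel"),
    not_in_pg_indel = sum(other_class_hit & cc == "indel"),
    pg_specific_snv = sum(!truth_matched & tc == "SNV"),
    pg_specific_indel = sum(!truth_matched & tc == "indel"),
    sample_specific_snv = sum(samp & cc == "SNV"),
    sample_specific_indel = sum(samp & cc == "indel"),
    n_calls = nrow(calls), n_truth = nrow(truth))
}

#' Sensitivity, precision and F-measure from the joint confusion matrix
#'
#' Computes the six accuracy statistics of the joint SNV/indel detection
#' task. Because SNV and indel detection are one classification task over
#' the same sites, the precision denominators cross classes:
#'
#' \deqn{SNV\ sens = \frac{InPG_{SNV}}{InPG_{SNV} + NotInPG_{SNV}}, \quad
#'       SNV\ prec = \frac{InPG_{SNV}}{InPG_{SNV} + NotInPG_{indel}}}
#'
#' and symmetrically for indels; F is the harmonic mean of sensitivity and
#' precision per class. Truth records never called (`pg_specific`) do not
#' enter these denominators; see [standard_metrics()] for the conventional
#' recall/precision on the same tallies. A zero denominator yields `NA`.
#'
#' @param x A [joint_confusion()].
#' @return An object of class `accuracy_metrics`: a list with
#'   `snv_sensitivity`, `snv_precision`, `snv_f`, `indel_sensitivity`,
#'   `indel_precision`, `indel_f`, all fractions in `[0, 1]` (or `NA`).
#' @export
compute_metrics <- function(x) {
  stopifnot(inherits(x, "joint_confusion"))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  sens_s <- frac(x$in_pg_snv, x$in_pg_snv + x$not_in_pg_snv)
  prec_s <- frac(x$in_pg_snv, x$in_pg_snv + x$not_in_pg_indel)
  sens_i <- frac(x$in_pg_indel, x$in_pg_indel + x$not_in_pg_indel)
  prec_i <- frac(x$in_pg_indel, x$in_pg_indel + x$not_in_pg_snv)
  f <- function(s, p) {
    if (is.na(s) || is.na(p) || s + p == 0) return(NA_real_)
    2 * s * p / (s + p)
  }
  structure(list(snv_sensitivity = sens_s, snv_precision = prec_s,
                 snv_f = f(sens_s, prec_s),
                 indel_sensitivity = sens_i, indel_precision = prec_i,
                 indel_f = f(sens_i, prec_i)),
            class = "accuracy_metrics")
}

#' Conventional recall/precision on the joint confusion tallies
#'
#' For comparison with [compute_metrics()]: per class, recall =
#' TP / (TP + FN) where FN are the `pg_specific` truth records of that
#' class, and precision = TP / (TP + FP) where FP are all calls of that
#' class not matching truth of that class (`not_in_pg` + `sample_specific`).
#' Never substituted for the joint-task formulas.
#'
#' @param x A [joint_confusion()].
#' @return A list with per-class `recall`, `precision`, `f`.
#' @export
standard_metrics <- function(x) {
  stopifnot(inherits(x, "joint_confusion"))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  rec_s <- frac(x$in_pg_snv, x$in_pg_snv + x$pg_specific_snv)
  prec_s <- frac(x$in_pg_snv,
                 x$in_pg_snv + x$not_in_pg_snv + x$sample_specific_snv)
  rec_i <- frac(x$in_pg_indel, x$in_pg_indel + x$pg_specific_indel)
  prec_i <- frac(x$in_pg_indel,
                 x$in_pg_indel + x$not_in_pg_indel + x$sample_specific_indel)
  f <- function(s, p) {
    if (is.na(s) || is.na(p) || s + p == 0) return(NA_real_)
    2 * s * p / (s + p)
  }
  list(snv_recall = rec_s, snv_precision = prec_s, snv_f = f(rec_s, prec_s),
       indel_recall = rec_i, indel_precision = prec_i,
       indel_f = f(rec_i, prec_i))
}

#' @export
print.accuracy_metrics <- function(x, ...) {
  cat("<accuracy_metrics>\n")
  df <- data.frame(
    class = c("SNV", "indel"),
    sensitivity = fmt_pct(c(x$snv_sensitivity, x$indel_sensitivity)),
    precision = fmt_pct(c(x$snv_precision, x$indel_precision)),
    f_measure = fmt_pct(c(x$snv_f, x$indel_f)))
  print(df, row.names = FALSE)
  invisible(x)
}
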