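#' Fan a master seed out into independent per-component seeds
#'
#' Every generator in the package takes its own seed; study-level drivers
#' derive those from one master seed so components can be regenerated
#' independently and reproducibly.
#'
#' @param seed Master seed (integer).
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds, each below 2^31.
#' @export
fan_seeds <- function(seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Error model for synthetic variant calling
#'
#' Parameterises how a called variant set is derived from a truth set:
#'
#' * `miss_rate` — probability a truth variant is not called at all.
#' * `spurious_per_mb` — expected spurious (non-truth) calls per Mb of
#'   target; spurious positions never collide with truth positions.
#' * `type_swap_rate` — probability an emitted call has the opposite
#'   class (SNV <-> indel) at the same position.
#' * `genotype_error_rate` — probability an emitted, non-swapped call has
#'   its genotype flipped (het <-> hom-alt).
#' * `dp_mean`, `dp_dispersion` — negative-binomial depth model
#'   (`dispersion = 0` gives constant depth `dp_mean`).
#' * `qual_mean`, `qual_sd` — normal QUAL model truncated at 0
#'   (`qual_sd = 0` gives constant QUAL).
#' * `spurious_snv_fraction` — class mix of spurious calls.
#'
#' @return An object of class `error_model` (a list of the above).
#' @export
error_model <- function(miss_rate = 0, spurious_per_mb = 0,
                        type_swap_rate = 0, genotype_error_rate = 0,
                        dp_mean = 60, dp_dispersion = 0,
                        qual_mean = 60, qual_sd = 0,
                        spurious_snv_fraction = 0.9) {
  probs <- c(miss_rate, type_swap_rate, genotype_error_rate,
             spurious_snv_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (spurious_per_mb < 0 || dp_mean < 0 || dp_dispersion < 0 ||
      qual_sd < 0) {
    stop("rates must be >= 0")
  }
  structure(list(miss_rate = miss_rate, spurious_per_mb = spurious_per_mb,
                 type_swap_rate = type_swap_rate,
                 genotype_error_rate = genotype_error_rate,
                 dp_mean = dp_mean, dp_dispersion = dp_dispersion,
                 qual_mean = qual_mean, qual_sd = qual_sd,
                 spurious_snv_fraction = spurious_snv_fraction),
            class = "error_model")
}

#' The fully deterministic zero-error model
#'
#' No misses, no spurious calls, no class swaps, no genotype errors, and
#' degenerate DP/QUAL distributions (constant 60), so identical truth sets
#' give byte-identical call sets in every replicate and all accuracy
#' metrics are exactly 100%.
#'
#' @return An [error_model()].
#' @export
zero_error_model <- function() error_model()

.bases <- c("A", "C", "G", "T")

#' Simulate a capture-target design with per-target GC content
#'
#' Generates `n_regions` disjoint target intervals laid out along
#' synthetic chromosomes, with lognormal region sizes (median
#' `median_size`, default 210 bp as typical of commercial exome designs)
#' and per-target GC drawn from a bimodal normal mixture emulating the
#' bimodal GC distribution of human exons.
#'
#' @param n_regions Number of target regions.
#' @param median_size Median region size in bp (default 210).
#' @param size_sdlog Lognormal sdlog of region sizes (0 = all equal).
#' @param gc_modes Two-row matrix-like list: means and sds of the two GC
#'   mixture components.
#' @param gc_weight Mixing weight of the first (AT-richer) component.
#' @param gap_mean Mean inter-target gap in bp (exponential).
#' @param n_chroms Number of synthetic chromosomes to spread targets over.
#' @param seed Integer seed.
#' @return An [interval_set()] (already normalized by construction) with
#'   an extra `gc` column per target.
#' @export
sim_targets <- function(n_regions = 2000, median_size = 210,
                        size_sdlog = 0.45,
                        gc_modes = list(c(0.38, 0.06), c(0.55, 0.07)),
                        gc_weight = 0.55, gap_mean = 2000, n_chroms = 4,
                        seed = 1) {
  stopifnot(n_regions >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sizes <- if (size_sdlog > 0) {
    pmax(20, round(stats::rlnorm(n_regions, log(median_size), size_sdlog)))
  } else rep(median_size, n_regions)
  gaps <- pmax(1, round(stats::rexp(n_regions, 1 / gap_mean)))
  chrom <- sort(rep_len(as.character(seq_len(n_chroms)), n_regions))
  start <- numeric(n_regions)
  offset <- 0
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- cumsum(gaps[i]) + c(0, cumsum(sizes[i])[-length(i)])
  }
  comp <- stats::rbinom(n_regions, 1, 1 - gc_weight) + 1
  mu <- c(gc_modes[[1]][1], gc_modes[[2]][1])[comp]
  sd <- c(gc_modes[[1]][2], gc_modes[[2]][2])[comp]
  gc <- pmin(0.99, pmax(0.01, stats::rnorm(n_regions, mu, sd)))
  df <- data.frame(chrom = chrom, start = start, end = start + sizes,
                   gc = gc, stringsAsFactors = FALSE)
  out <- interval_set(df, label = sprintf("sim-design-%d", seed),
                      normalized = TRUE)
  out
}

# Map indices in the concatenated target base space to (chrom, 1-based pos).
.base_index_to_pos <- function(targets, idx) {
  w <- targets$end - targets$start
  cw <- cumsum(w)
  region <- findInterval(idx - 1, c(0, cw), rightmost.closed = FALSE)
  offset <- idx - c(0, cw)[region] - 1      # 0-based offset within region
  data.frame(chrom = targets$chrom[region],
             pos = targets$start[region] + offset + 1,  # 1-based
             stringsAsFactors = FALSE)
}

#' Simulate a diploid truth variant set over a target design
#'
#' Variant counts are Poisson in the target size (defaults of 950 SNV/Mb
#' and 55 indels/Mb give call-set sizes proportional to a deeply covered
#' human exome); positions are uniform over target bases without
#' collisions; genotypes are heterozygous with probability `het_fraction`.
#' Alleles are synthetic single letters (plus 1-3 inserted/deleted bases
#' for indels); no reference FASTA is modelled.
#'
#' @param targets An [interval_set()] from [sim_targets()].
#' @param snv_per_mb,indel_per_mb Expected variants per Mb of target.
#' @param het_fraction Probability a variant is heterozygous.
#' @param seed Integer seed.
#' @return A [variant_set()] with attribute `het_fraction`.
#' @export
sim_truth <- function(targets, snv_per_mb = 950, indel_per_mb = 55,
                      het_fraction = 0.6, seed = 1) {
  stopifnot(snv_per_mb >= 0, indel_per_mb >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mb <- total_bases(targets) / 1e6
  n_snv <- stats::rpois(1, snv_per_mb * mb)
  n_indel <- stats::rpois(1, indel_per_mb * mb)
  n <- n_snv + n_indel
  if (n == 0) {
    return(structure(
      variant_set(data.frame(chrom = character(), pos = numeric(),
                             ref = character(), alt = character(),
                             genotype = character()),
                  sample_label = "truth"),
      het_fraction = het_fraction))
  }
  tb <- total_bases(targets)
  if (n > tb) stop("more variants than target bases")
  idx <- sample.int(tb, n)
  loc <- .base_index_to_pos(targets, idx)
  is_snv <- rep(c(TRUE, FALSE), c(n_snv, n_indel))
  ref <- sample(.bases, n, replace = TRUE)
  alt <- character(n)
  if (n_snv > 0) {
    alt[is_snv] <- vapply(ref[is_snv],
                          function(r) sample(setdiff(.bases, r), 1), "")
  }
  if (n_indel > 0) {
    ii <- which(!is_snv)
    ins <- stats::rbinom(length(ii), 1, 0.5) == 1
    len <- sample(1:3, length(ii), replace = TRUE)
    extra <- vapply(len, function(l)
      paste(sample(.bases, l, replace = TRUE), collapse = ""), "")
    alt[ii[ins]] <- paste0(ref[ii[ins]], extra[ins])
    ref[ii[!ins]] <- paste0(ref[ii[!ins]], extra[!ins])
    alt[ii[!ins]] <- substr(ref[ii[!ins]], 1, 1)
  }
  gt <- ifelse(stats::runif(n) < het_fraction, "0/1", "1/1")
  out <- variant_set(
    data.frame(chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
               genotype = gt, stringsAsFactors = FALSE),
    sample_label = "truth", provenance = "simulated truth")
  attr(out, "het_fraction") <- het_fraction
  attr(out, "targets_label") <- attr(targets, "label")
  out
}

.draw_depth <- function(n, model) {
  if (model$dp_dispersion > 0) {
    stats::rnbinom(n, mu = model$dp_mean, size = 1 / model$dp_dispersion)
  } else rep(round(model$dp_mean), n)
}

.draw_qual <- function(n, model) {
  if (model$qual_sd > 0) {
    pmax(0, stats::rnorm(n, model$qual_mean, model$qual_sd))
  } else rep(model$qual_mean, n)
}

.flip_gt <- function(gt) ifelse(gt == "0/1", "1/1", "0/1")

# Swap a record's class at the same position: SNV -> 1-base insertion;
# insertion/deletion -> SNV on the anchor base.
.swap_class <- function(ref, alt, vclass) {
  n <- length(ref)
  for (i in seq_len(n)) {
    if (vclass[i] == "SNV") {
      alt[i] <- paste0(ref[i], sample(.bases, 1))
    } else {
      anchor <- substr(ref[i], 1, 1)
      ref[i] <- anchor
      alt[i] <- sample(setdiff(.bases, anchor), 1)
    }
  }
  list(ref = ref, alt = alt)
}

#' Simulate a called variant set from a truth set under an error model
#'
#' Each truth variant is independently missed with probability
#' `miss_rate`; emitted calls are class-swapped with probability
#' `type_swap_rate` (position unchanged) or, if not swapped,
#' genotype-flipped with probability `genotype_error_rate`. Spurious calls
#' are added as a Poisson process over target bases, rejection-sampled so
#' they never coincide with truth positions (keeping the category
#' expectations closed-form; see [expected_confusion()]). DP and QUAL are
#' drawn from the model for every call.
#'
#' @param truth A [variant_set()] from [sim_truth()].
#' @param targets The [interval_set()] the truth was generated over.
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @param sample_label Label for the resulting call set.
#' @return A [variant_set()] with attribute `n_missed`.
#' @export
sim_calls <- function(truth, targets, model = zero_error_model(), seed = 1,
                      sample_label = "sim-sample") {
  stopifnot(inherits(truth, "variant_set"), inherits(model, "error_model"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(truth)
  emitted <- if (n > 0) stats::runif(n) >= model$miss_rate else logical(0)
  calls <- as.data.frame(truth)[emitted, , drop = FALSE]
  ne <- nrow(calls)
  if (ne > 0) {
    swap <- stats::runif(ne) < model$type_swap_rate
    if (any(swap)) {
      sw <- .swap_class(calls$ref[swap], calls$alt[swap],
                        calls$vclass[swap])
      calls$ref[swap] <- sw$ref
      calls$alt[swap] <- sw$alt
    }
    gt_err <- !swap & stats::runif(ne) < model$genotype_error_rate
    calls$genotype[gt_err] <- .flip_gt(calls$genotype[gt_err])
  }
  mb <- total_bases(targets) / 1e6
  n_spur <- stats::rpois(1, model$spurious_per_mb * mb)
  if (n_spur > 0) {
    tb <- total_bases(targets)
    truth_pos <- paste(truth$chrom, truth$pos, sep = "\r")
    picked <- character(0)
    pos_df <- NULL
    for (attempt in 1:50) {
      idx <- sample.int(tb, n_spur * 2)
      cand <- .base_index_to_pos(targets, idx)
      ckey <- paste(cand$chrom, cand$pos, sep = "\r")
      ok <- !(ckey %in% truth_pos) & !(ckey %in% picked) & !duplicated(ckey)
      cand <- cand[ok, , drop = FALSE]
      picked <- c(picked, ckey[ok])
      pos_df <- rbind(pos_df, cand)
      if (nrow(pos_df) >= n_spur) break
    }
    if (is.null(pos_df) || nrow(pos_df) < n_spur) {
      stop("could not place spurious calls off truth positions")
    }
    pos_df <- pos_df[seq_len(n_spur), , drop = FALSE]
    is_snv <- stats::runif(n_spur) < model$spurious_snv_fraction
    ref <- sample(.bases, n_spur, replace = TRUE)
    alt <- character(n_spur)
    alt[is_snv] <- vapply(ref[is_snv],
                          function(r) sample(setdiff(.bases, r), 1), "")
    if (any(!is_snv)) {
      alt[!is_snv] <- paste0(ref[!is_snv],
                             sample(.bases, sum(!is_snv), replace = TRUE))
    }
    het <- attr(truth, "het_fraction") %||% 0.5
    spur <- data.frame(
      chrom = pos_df$chrom, pos = pos_df$pos, ref = ref, alt = alt,
      genotype = ifelse(stats::runif(n_spur) < het, "0/1", "1/1"),
      qual = NA_real_, depth = NA_real_,
      vclass = NA_character_, stringsAsFactors = FALSE)
    calls <- rbind(calls[names(spur)], spur)
  }
  nc <- nrow(calls)
  calls$depth <- .draw_depth(nc, model)
  calls$qual <- .draw_qual(nc, model)
  out <- variant_set(calls[c("chrom", "pos", "ref", "alt", "genotype",
                             "qual", "depth")],
                     sample_label = sample_label,
                     provenance = "simulated calls")
  attr(out, "n_missed") <- sum(!emitted)
  out
}

#' Closed-form expected confusion tallies under the generative model
#'
#' Expectations (and standard deviations) of the eight joint-confusion
#' tallies for a truth set of `n_snv` SNVs and `n_indel` indels processed
#' by [sim_calls()] under `model`, assuming depth/quality filters remove
#' nothing. Used as a test oracle for the simulation-plus-matching
#' pipeline; never used by the pipeline itself. With miss rate m, swap
#' rate s and genotype error rate g, an SNV truth record is exactly
#' matched with probability (1-m)(1-s)(1-g), emitted as an opposite-class
#' call at its site with probability (1-m)s, and emitted same-class with a
#' wrong genotype (a sample-specific call) with probability (1-m)(1-s)g.
#' Spurious calls are Poisson with mean `spurious_per_mb * target_mb`,
#' split by `spurious_snv_fraction`.
#'
#' @param n_snv,n_indel Truth-set sizes by class.
#' @param model An [error_model()].
#' @param target_mb Target size in Mb (for the spurious process).
#' @return A list with `expected` and `sd`, each a named vector over the
#'   eight tallies.
#' @export
expected_confusion <- function(n_snv, n_indel, model, target_mb = 0) {
  m <- model$miss_rate; s <- model$type_swap_rate
  g <- model$genotype_error_rate
  p_match <- (1 - m) * (1 - s) * (1 - g)
  p_swap <- (1 - m) * s
  p_gt <- (1 - m) * (1 - s) * g
  lam <- model$spurious_per_mb * target_mb
  lam_snv <- lam * model$spurious_snv_fraction
  lam_ind <- lam - lam_snv
  expected <- c(
    in_pg_snv = n_snv * p_match,
    not_in_pg_snv = n_indel * p_swap,
    in_pg_indel = n_indel * p_match,
    not_in_pg_indel = n_snv * p_swap,
    pg_specific_snv = n_snv * (1 - p_match),
    pg_specific_indel = n_indel * (1 - p_match),
    sample_specific_snv = n_snv * p_gt + lam_snv,
    sample_specific_indel = n_indel * p_gt + lam_ind)
  bv <- function(n, p) n * p * (1 - p)
  sd <- sqrt(c(
    in_pg_snv = bv(n_snv, p_match),
    not_in_pg_snv = bv(n_indel, p_swap),
    in_pg_indel = bv(n_indel, p_match),
    not_in_pg_indel = bv(n_snv, p_swap),
    pg_specific_snv = bv(n_snv, p_match),
    pg_specific_indel = bv(n_indel, p_match),
    sample_specific_snv = bv(n_snv, p_gt) + lam_snv,
    sample_specific_indel = bv(n_indel, p_gt) + lam_ind))
  list(expected = expected, sd = sd)
}

#' Relative-coverage multiplier as a function of GC content
#'
#' Returns a unimodal GC-bias curve: coverage is depressed in targets with
#' extreme GC (falling off below ~20% and above ~80% GC, as hybrid-capture
#' data show) and normalized so the multiplier at 50% GC is 1.
#'
#' @param low,high Logistic midpoints of the low- and high-GC falloff.
#' @param steep Logistic steepness (smaller = sharper).
#' @return A function `f(gc)` returning non-negative multipliers.
#' @export
gc_bias_curve <- function(low = 0.15, high = 0.85, steep = 0.05) {
  raw <- function(gc) {
    stats::plogis((gc - low) / steep) * stats::plogis((high - gc) / steep)
  }
  norm <- raw(0.5)
  function(gc) raw(gc) / norm
}

#' Simulate a per-target depth profile with GC bias
#'
#' Per-target depth is negative binomial with mean
#' `mean_depth * bias(gc)`; each target becomes one constant-depth run
#' (bedGraph semantics). Off-target bases are absent (depth 0).
#'
#' @param targets An [interval_set()] with a `gc` column
#'   (from [sim_targets()]).
#' @param bias A [gc_bias_curve()] (or any function of GC); use
#'   `function(gc) 1` for no bias.
#' @param mean_depth Mean depth at 50% GC.
#' @param dispersion Negative-binomial dispersion (0 = deterministic mean).
#' @param seed Integer seed.
#' @return A [depth_profile()].
#' @export
sim_depth_profile <- function(targets, bias = gc_bias_curve(),
                              mean_depth = 100, dispersion = 0.05,
                              seed = 1) {
  stopifnot(mean_depth > 0, !is.null(targets$gc))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mu <- mean_depth * bias(targets$gc)
  depth <- if (dispersion > 0) {
    stats::rnbinom(nrow(targets), mu = mu, size = 1 / dispersion)
  } else round(mu)
  depth_profile(data.frame(chrom = targets$chrom, start = targets$start,
                           end = targets$end, depth = depth,
                           stringsAsFactors = FALSE))
}

#' Simulate per-sample pool data totals
#'
#' Per-sample totals (megabases) are lognormal with median `median_mb` and
#' log-scale spread `imbalance_sigma`; `imbalance_sigma = 0` gives a
#' perfectly balanced pool.
#'
#' @param n_samples Number of samples in the pool.
#' @param median_mb Median per-sample total in Mb (default 18 000, the
#'   scale of a 50-75 M read-pair exome sample).
#' @param imbalance_sigma Lognormal sdlog of the totals.
#' @param pool Pool label.
#' @param seed Integer seed.
#' @return A data frame with `sample`, `pool`, `total_mb`.
#' @export
sim_pool <- function(n_samples = 12, median_mb = 18000,
                     imbalance_sigma = 0.12, pool = "A", seed = 1) {
  stopifnot(n_samples >= 1, median_mb > 0, imbalance_sigma >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  totals <- if (imbalance_sigma > 0) {
    stats::rlnorm(n_samples, log(median_mb), imbalance_sigma)
  } else rep(median_mb, n_samples)
  data.frame(sample = sprintf("%s_s%02d", pool, seq_len(n_samples)),
             pool = pool, total_mb = totals, stringsAsFactors = FALSE)
}

#' Simulate per-sample read-category counts
#'
#' Multinomial draws of on-target / off-target / duplicate / un-aligned
#' read counts at fixed expected fractions, one row per sample.
#'
#' @param n_samples Number of samples.
#' @param total_reads Reads per sample (a downsampled count).
#' @param fractions Named numeric of expected fractions `on_target`,
#'   `off_target`, `duplicates`, `un_aligned`, summing to 1.
#' @param prefix Sample-name prefix.
#' @param seed Integer seed.
#' @return A [read_category_counts()].
#' @export
sim_read_categories <- function(n_samples = 6, total_reads = 50000,
                                fractions = c(on_target = 0.865,
                                              off_target = 0.071,
                                              duplicates = 0.059,
                                              un_aligned = 0.005),
                                prefix = "s", seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- stats::rmultinom(n_samples, total_reads, fractions)
  read_category_counts(data.frame(
    sample = sprintf("%s%02d", prefix, seq_len(n_samples)),
    on_target = draws[1, ], off_target = draws[2, ],
    duplicates = draws[3, ], un_aligned = draws[4, ],
    stringsAsFactors = FALSE))
}

#' Simulate a miniature capture-protocol comparison study
#'
#' Emulates a two-pool, three-protocol exome comparison at toy scale: a
#' shared exon track plus two capture designs derived from it, one truth
#' genome for the replicate reference sample and one for a second control
#' genome, and per-protocol error models, depth profiles, read-category
#' counts and pool totals. Protocol 1 emulates a low-duplicate, balanced
#' protocol; protocol 3 a higher off-target, more imbalanced one. Each
#' pool contains three replicate libraries of the reference genome and one
#' of the control genome.
#'
#' @param seed Master seed; all component seeds are fanned out from it.
#' @param n_regions Regions in the exon track (designs subset/pad it).
#' @param median_size Median target size in bp.
#' @param snv_per_mb,indel_per_mb Truth variant densities.
#' @return A list with `designs` (exons, design_a, design_b), `truths`
#'   (reference, control), `protocols` (per-protocol error models,
#'   samples, depth profiles, read-category counts, pool tables).
#' @export
sim_study <- function(seed = 1, n_regions = 600, median_size = 300,
                      snv_per_mb = 950, indel_per_mb = 55) {
  seeds <- fan_seeds(seed, 64)
  si <- 0L
  nxt <- function() {
    si <<- si + 1L
    seeds[si]
  }
  exons <- sim_targets(n_regions, median_size = median_size, seed = nxt())
  subset_pad <- function(x, keep, pad, label, seed) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    rows <- sort(sample.int(nrow(x), round(keep * nrow(x))))
    df <- as.data.frame(x)[rows, , drop = FALSE]
    df$start <- pmax(0, df$start - pad)
    df$end <- df$end + pad
    s <- normalize_intervals(interval_set(df[c("chrom", "start", "end")],
                                          label = label))
    # carry GC back over by midpoint lookup against the exon track
    s
  }
  design_a <- subset_pad(exons, 0.88, 30, "design A", nxt())
  design_b <- subset_pad(exons, 0.85, 45, "design B", nxt())
  truth_ref <- sim_truth(exons, snv_per_mb, indel_per_mb, seed = nxt())
  truth_ctl <- sim_truth(exons, snv_per_mb, indel_per_mb, seed = nxt())
  proto_defs <- list(
    p1 = list(model = error_model(miss_rate = 0.002, spurious_per_mb = 1,
                                  type_swap_rate = 0.001),
              fractions = c(on_target = 0.865, off_target = 0.071,
                            duplicates = 0.059, un_aligned = 0.005),
              pool_sigma = 0.15, pool_mb = 19000, n_pool = 12,
              mean_depth = 110),
    p2 = list(model = error_model(miss_rate = 0.004, spurious_per_mb = 2,
                                  type_swap_rate = 0.001),
              fractions = c(on_target = 0.779, off_target = 0.097,
                            duplicates = 0.119, un_aligned = 0.005),
              pool_sigma = 0.10, pool_mb = 18000, n_pool = 12,
              mean_depth = 100),
    p3 = list(model = error_model(miss_rate = 0.006, spurious_per_mb = 3,
                                  type_swap_rate = 0.001),
              fractions = c(on_target = 0.709, off_target = 0.167,
                            duplicates = 0.119, un_aligned = 0.005),
              pool_sigma = 0.45, pool_mb = 13500, n_pool = 8,
              mean_depth = 45))
  protocols <- lapply(names(proto_defs), function(p) {
    def <- proto_defs[[p]]
    samples <- list()
    for (pool in c("A", "B")) {
      for (r in 1:3) {
        lab <- sprintf("ref_%s_%s_r%d", p, pool, r)
        samples[[lab]] <- sim_calls(truth_ref, exons, def$model,
                                    seed = nxt(), sample_label = lab)
      }
      lab <- sprintf("ctl_%s_%s", p, pool)
      samples[[lab]] <- sim_calls(truth_ctl, exons, def$model,
                                  seed = nxt(), sample_label = lab)
    }
    list(name = p, model = def$model, samples = samples,
         depth = sim_depth_profile(exons, mean_depth = def$mean_depth,
                                   seed = nxt()),
         counts = sim_read_categories(6, fractions = def$fractions,
                                      prefix = paste0(p, "_"),
                                      seed = nxt()),
         pools = rbind(
           sim_pool(def$n_pool, median_mb = def$pool_mb,
                    imbalance_sigma = def$pool_sigma,
                    pool = paste0(p, "A"), seed = nxt()),
           sim_pool(def$n_pool, median_mb = def$pool_mb,
                    imbalance_sigma = def$pool_sigma,
                    pool = paste0(p, "B"), seed = nxt())))
  })
  names(protocols) <- names(proto_defs)
  list(designs = list(exons = exons, design_a = design_a,
                      design_b = design_b),
       truths = list(reference = truth_ref, control = truth_ctl),
       protocols = protocols)
}

#' Write a simulated study as standard-format fixture files
#'
#' Emits the complete miniature study as BED (designs), VCF (truth and
#' per-sample calls), bedGraph (depth) and TSV (read categories, pool
#' totals) under `dir`, exactly as real upstream exports would arrive.
#'
#' @param study A [sim_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_fixtures <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(study$designs$exons, file.path(dir, "exons.bed"))
  write_bed(study$designs$design_a, file.path(dir, "design_a.bed"))
  write_bed(study$designs$design_b, file.path(dir, "design_b.bed"))
  write_vcf(study$truths$reference, file.path(dir, "truth_reference.vcf"))
  write_vcf(study$truths$control, file.path(dir, "truth_control.vcf"))
  for (p in study$protocols) {
    pd <- file.path(dir, p$name)
    dir.create(pd, showWarnings = FALSE)
    for (s in p$samples) {
      write_vcf(s, file.path(pd, paste0(attr(s, "sample_label"), ".vcf")))
    }
    write_bedgraph(p$depth, file.path(pd, "depth.bedGraph"))
    write_counts_tsv(p$counts, file.path(pd, "read_categories.tsv"))
    utils::write.table(p$pools, file.path(pd, "pool_totals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
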