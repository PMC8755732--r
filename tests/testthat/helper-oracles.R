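# Independent brute-force oracles used to validate interval arithmetic and
# truth matching. These enumerate per-base memberships / all record pairs
# directly and share no code with the package implementations.

# Per-base membership of an interval_set on a toy genome: one logical
# vector per chromosome, element i = base (i-1) covered (0-based).
oracle_membership <- function(x, chroms, genome_len) {
  memb <- lapply(chroms, function(ch) logical(genome_len))
  names(memb) <- chroms
  df <- as.data.frame(x)
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    lo <- df$start[i] + 1
    hi <- min(df$end[i], genome_len)
    if (lo <= hi) memb[[ch]][lo:hi] <- TRUE
  }
  memb
}

oracle_bases <- function(memb) sum(vapply(memb, sum, 0))

oracle_setop <- function(a, b, op, chroms, genome_len) {
  ma <- oracle_membership(a, chroms, genome_len)
  mb <- oracle_membership(b, chroms, genome_len)
  f <- switch(op,
              intersect = function(x, y) x & y,
              union = function(x, y) x | y,
              subtract = function(x, y) x & !y)
  mapply(f, ma, mb, SIMPLIFY = FALSE)
}

oracle_venn3_bases <- function(a, b, e, chroms, genome_len) {
  ma <- oracle_membership(a, chroms, genome_len)
  mb <- oracle_membership(b, chroms, genome_len)
  me <- oracle_membership(e, chroms, genome_len)
  count <- function(f) {
    sum(mapply(function(x, y, z) sum(f(x, y, z)), ma, mb, me))
  }
  c(A = count(function(x, y, z) x & !y & !z),
    B = count(function(x, y, z) !x & y & !z),
    E = count(function(x, y, z) !x & !y & z),
    AB = count(function(x, y, z) x & y & !z),
    AE = count(function(x, y, z) x & !y & z),
    BE = count(function(x, y, z) !x & y & z),
    ABE = count(function(x, y, z) x & y & z))
}

random_interval_set <- function(n, chroms, genome_len, max_width = 200,
                                label = "rand") {
  start <- sample.int(genome_len - max_width, n, replace = TRUE) - 1
  width <- sample.int(max_width, n, replace = TRUE)
  interval_set(data.frame(chrom = sample(chroms, n, replace = TRUE),
                          start = start, end = start + width,
                          stringsAsFactors = FALSE),
               label = label)
}

# Exhaustive O(n*m) matcher: compares every call against every truth
# record directly and tallies the eight joint-confusion categories.
oracle_match <- function(calls, truth, genotype = TRUE) {
  cls <- function(v) ifelse(v == "SNV", "SNV", "indel")
  tall <- c(in_pg_snv = 0, not_in_pg_snv = 0, in_pg_indel = 0,
            not_in_pg_indel = 0, pg_specific_snv = 0,
            pg_specific_indel = 0, sample_specific_snv = 0,
            sample_specific_indel = 0)
  truth_matched <- rep(FALSE, nrow(truth))
  for (i in seq_len(nrow(calls))) {
    exact <- FALSE
    other <- FALSE
    for (j in seq_len(nrow(truth))) {
      same_site <- calls$chrom[i] == truth$chrom[j] &&
        calls$pos[i] == truth$pos[j]
      ident <- same_site && calls$ref[i] == truth$ref[j] &&
        calls$alt[i] == truth$alt[j] &&
        (!genotype || calls$genotype[i] == truth$genotype[j])
      if (ident) {
        exact <- TRUE
        truth_matched[j] <- TRUE
      }
      if (same_site &&
          cls(calls$vclass[i]) != cls(truth$vclass[j])) {
        other <- TRUE
      }
    }
    cc <- if (cls(calls$vclass[i]) == "SNV") "snv" else "indel"
    if (exact) {
      tall[paste0("in_pg_", cc)] <- tall[paste0("in_pg_", cc)] + 1
    } else if (other) {
      tall[paste0("not_in_pg_", cc)] <- tall[paste0("not_in_pg_", cc)] + 1
    } else {
      tall[paste0("sample_specific_", cc)] <-
        tall[paste0("sample_specific_", cc)] + 1
    }
  }
  for (j in seq_len(nrow(truth))) {
    if (!truth_matched[j]) {
      tc <- if (cls(truth$vclass[j]) == "SNV") "snv" else "indel"
      tall[paste0("pg_specific_", tc)] <-
        tall[paste0("pg_specific_", tc)] + 1
    }
  }
  tall
}

# Random small variant set on integer positions; densities high enough to
# force same-position collisions between calls and truth.
random_variant_df <- function(n, n_pos = 50) {
  bases <- c("A", "C", "G", "T")
  pos <- sample.int(n_pos, n, replace = TRUE)
  is_snv <- runif(n) < 0.7
  ref <- sample(bases, n, replace = TRUE)
  alt <- character(n)
  alt[is_snv] <- vapply(ref[is_snv],
                        function(r) sample(setdiff(bases, r), 1), "")
  ins <- !is_snv & runif(n) < 0.5
  del <- !is_snv & !ins
  alt[ins] <- paste0(ref[ins], sample(bases, sum(ins), replace = TRUE))
  ref[del] <- paste0(ref[del], sample(bases, sum(del), replace = TRUE))
  alt[del] <- substr(ref[del], 1, 1)
  data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
             genotype = sample(c("0/1", "1/1"), n, replace = TRUE),
             qual = 60, depth = 60, stringsAsFactors = FALSE)
}

confusion_call_sum <- function(jc) {
  jc$in_pg_snv + jc$not_in_pg_snv + jc$in_pg_indel + jc$not_in_pg_indel +
    jc$sample_specific_snv + jc$sample_specific_indel
}
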