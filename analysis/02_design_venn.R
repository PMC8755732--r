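#!/usr/bin/env Rscript
# Three-way Venn partition of the two capture designs against the coding
# exon track: how much target space the designs share, and how much of
# the exon track either design misses.

suppressPackageStartupMessages(library(wesbench))

fixtures <- "scratch/fixtures"
if (!dir.exists(fixtures)) {
  write_study_fixtures(sim_study(seed = 20, n_regions = 600), fixtures)
}

a <- normalize_intervals(read_bed(file.path(fixtures, "design_a.bed"),
                                  label = "design A"))
b <- normalize_intervals(read_bed(file.path(fixtures, "design_b.bed"),
                                  label = "design B"))
e <- normalize_intervals(read_bed(file.path(fixtures, "exons.bed"),
                                  label = "exons"))

for (s in list(a, b, e)) {
  sm <- interval_summary(s)
  cat(sprintf("%-10s %5d regions, %7d bases, median size %.0f bp\n",
              attr(s, "label"), sm$n_regions, sm$total_bases,
              sm$median_region_size))
}

v <- venn3(a, b, e)
print(v)
cat(sprintf("\nTriple overlap: %d bases (%.2f%% of the 3-way union)\n",
            v$partition_bases[["ABE"]], v$pct_of_triple_union[["ABE"]]))
ab <- v$pairwise[v$pairwise$pair == "AB", ]
cat(sprintf("Design A vs B overlap: %d bases (%.2f%% of their union)\n",
            ab$overlap_bases, ab$pct_of_pairwise_union))
cat(sprintf("Exon bases uncovered by either design: %.2f%%\n",
            v$pct_of_triple_union[["E"]]))

dir.create("results", showWarnings = FALSE)
write_venn(v, "results/02_venn.tsv", "results/02_venn.json")
cat("wrote results/02_venn.tsv and results/02_venn.json\n")
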