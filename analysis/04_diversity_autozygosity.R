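#!/usr/bin/env Rscript
# LD decay (HR statistic with MAF-matched pairs), runs of homozygosity with
# the across-region Kruskal-Wallis comparison, and HetR / nHetR.
# Requires results/panel.vcf and results/sample_map.tsv from step 01.

suppressPackageStartupMessages(library(pyrenpop))
map <- read_sample_map("results/sample_map.tsv")
panel <- read_vcf("results/panel.vcf", region_map = map)
regions <- sort(unique(panel$region_labels))

# LD decay per region
curves <- lapply(regions, function(r)
  ld_decay(panel, region = r,
           config = ld_config(bin_edges = seq(0, 5e5, 2.5e4))))
ld_tab <- do.call(rbind, lapply(seq_along(regions), function(i)
  data.frame(region = regions[i], mid_bp = curves[[i]]$mid,
             mean_hr = curves[[i]]$mean_hr, n_pairs = curves[[i]]$n_pairs)))
write.table(ld_tab, "results/ld_decay.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("mean HR in the first 25 kb bin, by region:\n")
print(with(subset(ld_tab, mid_bp == min(mid_bp)),
           setNames(round(mean_hr, 3), region)))

# RoH (detection scaled to the 2 Mb panel) and the across-region comparison
rp <- roh_params(window_snvs = 25, max_het_per_window = 1,
                 min_length_bp = 2e5, min_snvs = 25, max_gap_bp = 1e5)
roh <- detect_roh(panel, params = rp)
write.table(data.frame(chrom = "1", start = roh$start, end = roh$end,
                       sample_id = roh$sample_id, n_snvs = roh$n_snvs),
            "results/roh_segments.bed", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
totals <- roh_totals(roh, panel$sample_ids)
write.table(data.frame(sample_id = panel$sample_ids,
                       region = panel$region_labels, total_roh_bp = totals),
            "results/roh_totals.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("mean total RoH (Mb) by region:\n")
print(round(tapply(totals / 1e6, panel$region_labels, mean), 3))
kw <- roh_region_test(totals, panel$region_labels)
cat(sprintf("Kruskal-Wallis across regions: H = %.3f, p = %.4g\n",
            kw$H, kw$p_value))

# HetR and resampling-normalized nHetR (5 samples per region, 5000 reps)
het <- normalized_het_ratio(panel, subsample_size = 5, n_reps = 5000,
                            seed = 99)
write.table(het, "results/het_ratios.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("mean nHetR by region:\n")
print(round(tapply(het$nHetR, het$region, mean), 3))
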