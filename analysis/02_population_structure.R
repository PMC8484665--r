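#!/usr/bin/env Rscript
# Population structure at the micro-geographic scale:
#   1-IBS distances -> classical MDS -> Procrustes test against geography;
#   Li-Stephens haplotype painting -> coancestry matrix -> agglomerative
#   coancestry clustering with silhouette model choice.
# Requires results/panel.vcf and results/sample_map.tsv from step 01.

suppressPackageStartupMessages(library(pyrenpop))
map <- read_sample_map("results/sample_map.tsv")
panel <- read_vcf("results/panel.vcf", region_map = map)

d <- ibs_distance(panel_dosages(panel))
mds <- classical_mds(d, k = 2)
write.table(cbind(sample_id = mds$sample_ids,
                  as.data.frame(mds$coordinates)),
            "results/mds_coordinates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

pt <- procrustes_test(mds$coordinates, panel$coords, n_perm = 9999)
cat(sprintf("Procrustes correlation MDS vs geography: %.3f (p = %.4g, %d permutations)\n",
            pt$correlation, pt$p_value, pt$n_perm))

sr <- estimate_switch_rate(panel, n_em_iters = 3)
cat(sprintf("EM copying switch rate: %.3g per bp\n", sr$switch_rate))
cm <- paint_panel(panel, switch_rate = sr$switch_rate)
write_coancestry(cm, "results/coancestry.tsv")

cl <- cluster_coancestry(cm, k_max = 5)
cat("mean silhouette by k:\n"); print(round(cl$silhouette, 3))
cat(sprintf("chosen k = %d\n", cl$best_k))
print(table(cluster = cl$membership, region = panel$region_labels))
write.table(data.frame(sample_id = panel$sample_ids,
                       region = panel$region_labels,
                       cluster = cl$membership),
            "results/coancestry_clusters.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
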