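#!/usr/bin/env Rscript
# Stage 5: miRNA gene clusters (genomic proximity, 10 kb single-linkage)
# and seed families; within-group sign concordance of the fold changes;
# hypergeometric pathway enrichment of the differential miRNAs' targets
# over a synthetic validated-target table and gene sets.

suppressPackageStartupMessages(library(isomiRQuant))

ps <- read_precursor_set("results/sim/precursors.fa",
                         mature_gff3 = "results/sim/matures.gff3")
d <- read.delim("results/tables/differential.tsv",
                stringsAsFactors = FALSE)

groups <- group_report(build_clusters(ps), build_families(ps), ps, d)
write.table(groups, "results/tables/group_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
g2 <- groups[!is.na(groups$concordance), ]
message(sprintf("%d clusters + %d families scored; mean concordance %.2f (clusters %.2f, families %.2f)",
                sum(groups$kind == "cluster"), sum(groups$kind == "family"),
                mean(g2$concordance),
                mean(g2$concordance[g2$kind == "cluster"]),
                mean(g2$concordance[g2$kind == "family"])))

# enrichment over a synthetic target/pathway world (no external
# databases are bundled; the tables are generated, and labelled, as such)
ts <- simulate_target_sets(ps$matures$mature_id, seed = 20130)
de_ids <- d$mature_id[d$status != "unchanged"]
query <- map_targets(de_ids, ts$targets)
enr <- hypergeom_enrich(query$gene, ts$pathways,
                        unique(ts$targets$gene))
write.table(query, "results/tables/target_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(enr, "results/tables/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d DE miRNAs -> %d target genes; top set: %s (k=%d/%d, BH p=%.3g)",
                length(de_ids), nrow(query), enr$pathway_id[1], enr$k[1],
                enr$K[1], enr$p_adjusted[1]))
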