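#!/usr/bin/env Rscript
# Stage 6: figures — read length distributions per library, ranked
# up/down fold changes under both estimators, and per-group member fold
# changes.

suppressPackageStartupMessages({
  library(isomiRQuant)
  library(ggplot2)
})
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

hist <- read.delim("results/tables/length_histogram.tsv",
                   stringsAsFactors = FALSE)
p1 <- ggplot(hist, aes(length, reads)) +
  geom_col(fill = "steelblue") +
  facet_wrap(~library_id, ncol = 1, scales = "free_y") +
  labs(x = "mapped read length (nt)", y = "reads",
       title = "Length distribution of mapped reads") +
  theme_bw()
ggsave("results/figures/length_distribution.pdf", p1, width = 5,
       height = 5)

d <- read.delim("results/tables/differential.tsv",
                stringsAsFactors = FALSE)
de <- d[d$status != "unchanged", ]
long <- rbind(data.frame(mature_id = de$mature_id, estimator = "sum",
                         log2fc = de$log2fc_sum, status = de$status),
              data.frame(mature_id = de$mature_id,
                         estimator = "dominant",
                         log2fc = de$log2fc_dominant, status = de$status))
long$mature_id <- factor(long$mature_id,
                         levels = de$mature_id[order(de$log2fc_sum)])
p2 <- ggplot(long, aes(mature_id, log2fc, fill = estimator)) +
  geom_col(position = "dodge") +
  coord_flip() +
  labs(x = NULL, y = "log2 FC (case/control)",
       title = "Differential miRNAs under both estimators") +
  theme_bw()
ggsave("results/figures/differential_estimators.pdf", p2, width = 6,
       height = 7)

groups <- read.delim("results/tables/group_report.tsv",
                     stringsAsFactors = FALSE)
g <- groups[!is.na(groups$concordance), ]
memb <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
  kv <- strsplit(strsplit(g$member_log2fc[i], ";")[[1]], "=")
  data.frame(group = paste(g$kind[i], g$group_id[i]),
             mature_id = vapply(kv, `[`, "", 1),
             log2fc = as.numeric(vapply(kv, `[`, "", 2)))
}))
p3 <- ggplot(memb, aes(mature_id, log2fc)) +
  geom_col(fill = "darkorange") +
  facet_wrap(~group, scales = "free_x") +
  theme_bw() +
  theme(axis.text.x = element_text(angle = 45, hjust = 1, size = 6)) +
  labs(x = NULL, y = "log2 FC",
       title = "Member fold changes within clusters and families")
ggsave("results/figures/group_members.pdf", p3, width = 9, height = 7)

message("wrote results/figures/{length_distribution,differential_estimators,group_members}.pdf")
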