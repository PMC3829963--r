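#!/usr/bin/env Rscript
# Stage 3: discard sub-2-count tags, match tags to the hairpins under
# the +/-4 nt / <=1 mismatch isomiR rule, and quantify each miRNA under
# both estimators (dominant isomiR; sum of isomiRs) in RPM.

suppressPackageStartupMessages(library(isomiRQuant))

ps <- read_precursor_set("results/sim/precursors.fa",
                         mature_gff3 = "results/sim/matures.gff3")
expr <- list(); hists <- list()
for (lib in c("obob", "WT")) {
  tags <- read.delim(file.path("results/tables",
                               paste0("tags_", lib, ".tsv")),
                     stringsAsFactors = FALSE)
  q <- quantify_library(tags, ps)
  expr[[lib]] <- q$records
  hists[[lib]] <- cbind(library_id = lib, q$histogram)
  write.table(q$hits, file.path("results/tables",
                                paste0("hits_", lib, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d/%d tags mapped (%d reads, %.1f%%); %d miRNAs; modal read length %d nt",
                  lib, q$log[["tags_mapped"]], q$log[["tags_in"]],
                  q$log[["reads_mapped"]],
                  100 * q$log[["reads_mapped"]] / sum(tags$count),
                  nrow(q$records), attr(q$histogram, "mode")))
}
write.table(do.call(rbind, expr), "results/tables/expression.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, hists), "results/tables/length_histogram.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
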