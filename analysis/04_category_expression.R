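#!/usr/bin/env Rscript
# Stage 4: functional-category structure of the target sets and their
# relation to differential expression. Compares category proportions between
# shared and species-specific reference targets (the fold statistic), runs a
# hypergeometric enrichment of the shared set against the ortholog universe
# with BH correction, and intersects species-b hindwing targets with the
# >= 2-fold expression set.

suppressMessages(library(crossbind))

data_dir <- "results/data"
out_dir <- "results"

annotation <- read_annotation_table(file.path(data_dir, "annotation.tsv"))
categories <- sort(names(annotation$labels))
venn <- read.delim(file.path(out_dir, "venn_members.tsv"))
shared <- gene_set(venn$ref_id[venn$region == "a&b"], "reference", "shared")

fold_rows <- NULL
for (sp in c("a", "b")) {
  spec_ids <- venn$ref_id[venn$region == sp]
  spec <- gene_set(spec_ids, "reference", sprintf("%s_specific", sp))
  for (cat_id in categories) {
    row <- fold_overrepresentation(shared, spec, annotation, cat_id)
    row$comparison <- sprintf("shared_vs_%s_specific", sp)
    fold_rows <- rbind(fold_rows, row)
  }
}
write.table(fold_rows, file.path(out_dir, "category_fold.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
wing <- fold_rows[fold_rows$category_id == "CAT-WING", ]
cat(sprintf("wing-development category: %.2f-fold (vs a-specific), %.2f-fold (vs b-specific)\n",
            wing$fold[wing$comparison == "shared_vs_a_specific"],
            wing$fold[wing$comparison == "shared_vs_b_specific"]))

omap <- read_ortholog_map(file.path(data_dir, "orthologs.tsv"))
uni <- gene_set(unique(unlist(omap, use.names = FALSE)), "reference",
                "universe")
hyper <- enrichment_vs_universe(shared, annotation, uni, categories)
write.table(hyper, file.path(out_dir, "category_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
top <- hyper[1, ]
cat(sprintf("top enriched category in shared targets: %s (q = %.3g)\n",
            top$category_id, top$q_value))

expr <- read_expression_table(file.path(data_dir, "b.expression.tsv"))
de <- fold_change_filter(expr, min_fold = 2, pseudocount = 1,
                         species_tag = "b")
asg_b <- read.delim(file.path(out_dir, "targets_b.tsv"))
targets_b <- target_gene_set(asg_b, "b")
ov <- de_overlap(targets_b, de)
write.table(data.frame(gene_id = de$ids),
            file.path(out_dir, "de_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d genes pass the 2-fold filter; %d are hindwing targets (%.1f%% of targets)\n",
            length(de), ov$overlap_count,
            100 * ov$proportion_of_targets))
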