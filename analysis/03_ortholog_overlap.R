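#!/usr/bin/env Rscript
# Stage 3: project both species' target sets onto the reference gene space
# through the ortholog table, partition them into Venn regions, and score
# the overlap hypergeometrically against the universe of reference genes
# with at least one ortholog entry.

suppressMessages(library(crossbind))

data_dir <- "results/data"
out_dir <- "results"

omap <- read_ortholog_map(file.path(data_dir, "orthologs.tsv"))
mapped <- list()
for (sp in c("a", "b")) {
  asg <- read.delim(file.path(out_dir, sprintf("targets_%s.tsv", sp)))
  targets <- target_gene_set(asg, species_tag = sp)
  m <- map_to_reference(targets, omap)
  mapped[[sp]] <- m
  cat(sprintf("species %s: %d targets, %d with orthologs (%d unmapped) -> %d reference genes\n",
              sp, m$n_input, m$n_mapped, m$unmapped_count,
              length(m$set$ids)))
}

v <- venn_partition(list(mapped$a$set, mapped$b$set))
write.table(data.frame(region = names(v$region_counts),
                       count = as.integer(v$region_counts)),
            file.path(out_dir, "venn_regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
members <- data.frame(
  region = rep(names(v$region_members), lengths(v$region_members)),
  ref_id = unlist(v$region_members, use.names = FALSE))
write.table(members, file.path(out_dir, "venn_members.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

universe <- length(unique(unlist(omap, use.names = FALSE)))
ot <- overlap_significance(mapped$a$set, mapped$b$set, universe)
cat(sprintf("shared reference targets: %d of %d x %d (universe %d), fold %.2f, p = %.3g\n",
            ot$overlap, ot$size_a, ot$size_b, universe, ot$fold, ot$p_value))
cat("Wrote venn_regions.tsv and venn_members.tsv under", out_dir, "\n")
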