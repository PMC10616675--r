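#!/usr/bin/env Rscript
# Apply the differential-expression thresholds (|log2 FC| >= 0.3785 i.e.
# 1.3-fold, adjusted p <= 0.05, control mean > 0.1, knocked-out genes
# excluded) to a DEG result table simulated around the screen's truth, and
# compute the cross-tabulations: binding-site fractions in up- vs
# down-regulated sets, known-target flags and up/down set overlaps between
# two contrasts.

library(decaychase)

ind <- "results/simulated"
out <- "results/deg"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
set.seed(202)

truth <- read.delim(file.path(ind, "truth.tsv"))
ctrl <- truth[truth$genotype == "control", ]
stab <- ctrl$gene_id[ctrl$stabilized_gene %in% c(TRUE, "TRUE")]

# Synthetic DEG table: stabilized transcripts tend up in the knockout, the
# rest scatter around zero; a sprinkle of unrelated true DEGs in both tails.
n <- nrow(ctrl)
lfc <- rnorm(n, 0, 0.15)
names(lfc) <- ctrl$gene_id
lfc[stab] <- rnorm(length(stab), 1.2, 0.3)
other <- sample(setdiff(ctrl$gene_id, stab), 200)
lfc[other] <- rnorm(200, 0, 1)
se <- 0.18
padj <- p.adjust(2 * pnorm(-abs(lfc / se)), method = "BH")
deg <- data.frame(gene_id = ctrl$gene_id, log2fc = round(lfc, 4),
                  padj = signif(padj, 4),
                  control_mean = round(ctrl$baseline, 3))
write.table(deg, file.path(out, "deg_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

deg <- read_deg_table(file.path(out, "deg_table.tsv"))
sets <- apply_deg_thresholds(deg, deg_thresholds())
cat(sprintf("up: %d, down: %d, excluded: %d\n",
            length(sets$up), length(sets$down), nrow(sets$excluded)))

utrs <- read_utr_fasta(file.path(ind, "utrs.fa"))
ann <- annotate_gene_set(utrs)
cat(sprintf("site fraction: up %.2f vs down %.2f\n",
            site_fraction(sets$up, ann), site_fraction(sets$down, ann)))

known <- flag_known_targets(sets$up, known_targets = stab)
cat(sprintf("known-target fraction among up-regulated: %.2f\n",
            attr(known, "fraction")))

# Overlap with a weaker second contrast (half the up set plus noise genes).
second <- c(sample(sets$up, length(sets$up) %/% 2),
            sample(setdiff(deg$gene_id, sets$up), 30))
ov <- overlap_sets(sets$up, second)
venn <- data.frame(set = names(ov$counts), n = as.integer(ov$counts))
write.table(venn, file.path(out, "venn_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(venn)

for (nm in c("up", "down")) {
  genes <- sets[[nm]]
  tab <- data.frame(gene_id = genes,
                    has_site = vapply(genes, function(g)
                      !is.null(ann[[g]]) && ann[[g]]$has_site, logical(1)),
                    known_target = flag_known_targets(genes, stab)$known_target)
  write.table(tab, file.path(out, paste0(nm, "_regulated.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
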