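#!/usr/bin/env Rscript
# Stage 4: screen architectures against the aggregation outcomes.
#
# Runs the elimination chain on the transcribed variant-by-pH outcome
# matrix at pH 3.6 (the mono-anionic phosphate regime, where outcomes
# differ most): 3 strand arrangements -> 1 surviving registry -> 2
# compatible zipper classes -> 1 consistent class.

suppressMessages(library(phosphozip))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

outcomes <- strand_e_outcomes()
cat("outcomes at pH 3.6:\n")
print(subset(as.data.frame(outcomes), pH == 3.6,
             select = c(variant, outcome)), row.names = FALSE)

inf <- infer_architecture(outcomes, pH = 3.6, margin = 3)
cat("\n")
print(inf)

report_rows <- function(reports, stage) {
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(stage = stage, candidate = nm, verdict = r$verdict,
               reason = ifelse(nzchar(r$reason), r$reason, "-"),
               separations = paste(sprintf("%s=%.3g", names(r$separations),
                                           r$separations), collapse = "; "))
  }))
}
tab <- rbind(report_rows(inf$arrangement_reports, "strand_arrangement"),
             report_rows(inf$class_reports, "zipper_class"))
write.table(tab, file.path(out_dir, "architecture_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("\naudit trail:\n")
for (i in seq_len(nrow(tab)))
  cat(sprintf("  [%s] %-26s %s\n", tab$stage[i], tab$candidate[i], tab$verdict[i]))

cat("\nfindings: parallel and in-register antiparallel registries cannot",
    "rank the blocked variants (p5Y, p8Y) below the aggregating p9Y;",
    "the antiparallel shifted registry can, and of its two compatible",
    sprintf("zipper classes only class %d separates the aggregating",
            inf$winner),
    "phosphosites beyond the 3 A margin.\n")
cat("wrote", file.path(out_dir, "architecture_report.tsv"), "\n")
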