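#!/usr/bin/env Rscript
# Aggregate the four per-method rankings into per-block comprehensive
# (geometric-mean) rankings and the study-level ordering.

library(rgstab)

m <- read_ct_table("results/synthetic_ct.csv")
res <- run_full_analysis(m)

comp <- comprehensive_table(res)
write.csv(comp, "results/comprehensive_ranking.csv", row.names = FALSE)
write.csv(res$study, "results/study_ranking.csv", row.names = FALSE)

message("study-level comprehensive ranking (most stable first):")
message("  ", paste(res$study$gene, collapse = " > "))
message("per-block winners:")
winners <- comp[comp$rank == 1, c("region", "time_point", "gene", "geomean_2dp")]
print(winners, row.names = FALSE)
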