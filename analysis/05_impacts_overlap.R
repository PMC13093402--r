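#!/usr/bin/env Rscript
# Mixed trophic impacts (with the fishing fleet), keystoneness / relative
# total impact, and Pianka prey / predator niche overlap.
suppressPackageStartupMessages(library(limnoweb))
dir.create("results", showWarnings = FALSE)

bal <- balance_model(kaptai_model())
imp <- mti_matrix(bal, include_fleet = TRUE)
ks <- keystone_analysis(imp, bal)
ks <- ks[order(-ks$relative_total_impact), ]
cat("relative total impact (top 5):\n")
print(head(ks[, c("name", "relative_total_impact", "keystoneness")], 5),
      row.names = FALSE)

ov <- niche_overlap(bal)
fish <- 1:10
po <- ov$prey_overlap[fish, fish]; diag(po) <- 0
top <- which(po == max(po), arr.ind = TRUE)[1, ]
cat("\nmaximum fish prey overlap:", rownames(po)[top[1]], "-",
    rownames(po)[top[2]], "=", round(max(po), 3), "\n")
pr <- ov$predator_overlap[fish, fish]; diag(pr) <- 0
top2 <- which(pr == max(pr), arr.ind = TRUE)[1, ]
cat("maximum fish predator overlap:", rownames(pr)[top2[1]], "-",
    rownames(pr)[top2[2]], "=", round(max(pr), 3), "\n")

write.csv(round(imp$mti, 6), "results/mti.csv")
write.csv(ks, "results/keystone.csv", row.names = FALSE)
write.csv(round(ov$prey_overlap, 4), "results/prey_overlap.csv")
write.csv(round(ov$predator_overlap, 4), "results/predator_overlap.csv")
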