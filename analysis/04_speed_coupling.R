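#!/usr/bin/env Rscript
# Amplitude/frequency vs running-speed coupling in 5-s bins, per context
# and condition, plus the speed-matched pre/post comparison of band
# powers at the wheel.

library(fourhz)

res <- readRDS("results/pipeline.rds")
pre <- read_session("results/sessions/pre.rds")
post <- read_session("results/sessions/post.rds")

cat("Spearman correlations (5-s bins):\n")
print(res$tables$correlations, digits = 3, row.names = FALSE)
write.csv(res$tables$correlations, "results/speed_correlations.csv",
          row.names = FALSE)

sp <- rbind(trial_mean_speeds(pre$speed, pre$trials, pre$fs_beh),
            trial_mean_speeds(post$speed, post$trials, post$fs_beh))
m <- speed_matched_subsets(sp)
cat(sprintf("\nSpeed matching (55-63 cm/s): %d pre, %d post trials, ",
            nrow(m$pre), nrow(m$post)))
cat(sprintf("residual speed difference p = %.2f\n", m$match_test))

tab <- res$tables$psd
bp <- function(bn, cond, ids)
  mean(tab$power[tab$band == bn & tab$condition == cond &
                 tab$context == "wheel" & tab$trial_id %in% ids])
for (bn in c("fourhz", "theta")) {
  r <- bp(bn, "pre", m$pre$trial_id) / bp(bn, "post", m$post$trial_id)
  cat(sprintf("matched wheel %-6s power ratio pre/post: %6.2f\n", bn, r))
}
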