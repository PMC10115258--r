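#!/usr/bin/env Rscript
# Simulate one pre- and one post-inactivation session under the default
# study conditions (30 maze + 30 wheel trials of 15 s each, 8
# interneurons, 24 pyramidal cells) and store the containers plus the
# generator configuration.

library(fourhz)

dir.create("results/sessions", showWarnings = FALSE, recursive = TRUE)

cfg <- synth_config()           # defaults ARE the study conditions
write_synth_config(cfg, "results/sessions/config.json")

pre <- gen_session(cfg, "pre", seed = 20260901L)
post <- gen_session(cfg, "post", seed = 20260902L)
write_session(pre, "results/sessions/pre.rds")
write_session(post, "results/sessions/post.rds")

cat("pre:  ", nrow(pre$trials), "trials,", length(pre$neurons), "neurons,",
    round(length(pre$lfp) / pre$fs_lfp / 60, 1), "min of LFP\n")
cat("post: ", nrow(post$trials), "trials,", length(post$neurons), "neurons\n")
cat("containers written under results/sessions/\n")
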