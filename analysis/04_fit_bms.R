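#!/usr/bin/env Rscript
# Model-based analysis on a simulated group: fit the within-trial model
# space (H0, H1, H2, H2.1) to every subject of a bonus-model group by MAP
# with Laplace-approximate evidence, then compare the models with
# group-level random-effects Bayesian model selection. Also compares the
# across-trial carry-over variants (local, global, two-level) on the same
# data. Writes results/evidence.csv, results/bms_within.json and
# results/bms_carryover.json.

suppressMessages(library(covertchoice))
dir.create("results", showWarnings = FALSE)

message("simulating 30 subjects under the local bonus model ...")
subs <- simulate_group(model_spec("H2.1"),
                       model_params(beta = 0.081, delta = 0.59),
                       n_subjects = 30L, profile = "exp1", seed = 11L,
                       n_sessions = 5L)

message("fitting the within-trial model space ...")
fg <- fit_group(subs, c("H0", "H1", "H2", "H2.1"), seed = 11L)
ev <- data.frame(subject = rep(seq_len(nrow(fg$evidence)), ncol(fg$evidence)),
                 model = rep(colnames(fg$evidence), each = nrow(fg$evidence)),
                 free_energy = as.vector(fg$evidence))
write.csv(ev, "results/evidence.csv", row.names = FALSE)
b <- bms(fg$evidence, seed = 11L)
print(b)
jsonlite::write_json(list(models = b$models, alpha = b$alpha, ef = b$ef,
                          ep = b$ep),
                     "results/bms_within.json", auto_unbox = TRUE, digits = NA)

d <- vapply(fg$fits, function(f) f[[4]]$posterior_mean[["delta"]], 0)
tt <- t.test(d, mu = 0)
cat(sprintf("\nposterior bonus under the generating model: %.2f +/- %.3f, t(%d) = %.2f, p = %.2g\n",
            mean(d), sd(d) / sqrt(length(d)), length(d) - 1L,
            tt$statistic, tt$p.value))
cat("\nNote: at a homogeneous group-mean bonus the per-subject evidence\n",
    "gain of the bonus model over leaner alternatives is smaller than the\n",
    "complexity penalty, so BMS may prefer H1 or H0 here even though the\n",
    "recovered bonus is significantly positive; identifiability improves\n",
    "with larger or heterogeneous per-subject bonuses.\n", sep = "")

message("comparing carry-over variants (local / global / two-level) ...")
fg2 <- fit_group(subs, c("H2.1", "H2.1global", "H2.1twolevel"), seed = 11L)
b2 <- bms(fg2$evidence, seed = 11L)
print(b2)
jsonlite::write_json(list(models = b2$models, alpha = b2$alpha, ef = b2$ef,
                          ep = b2$ep),
                     "results/bms_carryover.json", auto_unbox = TRUE,
                     digits = NA)
cat("\nData were generated by the local model, so the local variant should\n",
    "win the carry-over comparison.\n", sep = "")
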