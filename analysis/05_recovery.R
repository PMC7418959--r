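#!/usr/bin/env Rscript
# Recovery analyses. (1) Parameter recovery: simulate groups under known
# parameters and refit the generating model -- the null model's inverse
# temperature from a single 72-trial session, the bonus model's (beta,
# delta) from the full five-session dataset. (2) Model recovery: simulate
# groups under each model of the comparison space, fit all models to all
# subjects, select per group by random-effects BMS at Ep > 0.95, and
# tabulate the confusion matrix. Writes results/parameter_recovery.csv
# and results/recovery.csv.

suppressMessages(library(covertchoice))
dir.create("results", showWarnings = FALSE)

message("parameter recovery: H0 (beta), one session ...")
pr0 <- parameter_recovery(model_spec("H0"), model_params(beta = 0.081),
                          n_subjects = 30L, seed = 501L)
message("parameter recovery: H2.1 (beta, delta), five sessions ...")
pr1 <- parameter_recovery(model_spec("H2.1"),
                          model_params(beta = 0.081, delta = 0.59),
                          n_subjects = 30L, seed = 1001L, n_sessions = 5L)
tt <- t.test(pr1$delta, mu = 0)
par_tab <- data.frame(
  model = c("H0", "H2.1", "H2.1"),
  parameter = c("beta", "beta", "delta"),
  generating = c(0.081, 0.081, 0.59),
  recovered_mean = c(mean(pr0$beta), mean(pr1$beta), mean(pr1$delta)),
  recovered_sem = c(sd(pr0$beta), sd(pr1$beta), sd(pr1$delta)) / sqrt(30))
write.csv(par_tab, "results/parameter_recovery.csv", row.names = FALSE)
print(par_tab, row.names = FALSE, digits = 3)
cat(sprintf("group t-test on the recovered bonus: t(29) = %.2f, p = %.2g\n\n",
            tt$statistic, tt$p.value))

message("model recovery: 4 groups per generating model ...")
rc <- model_recovery(models = c("H0", "H1", "H2", "H2.1", "H3"),
                     n_groups = 4L, n_subjects = 30L, profile = "exp1",
                     seed = 2026L)
write.csv(rc$confusion, "results/recovery.csv")
print(rc)
cat("\nThe pruning model H3 is perfectly identifiable (opposite-signed\n",
    "signature). Null-model groups go to H0 or no winner. At the\n",
    "group-mean bonus the bonus-model columns are confusable with the\n",
    "primacy model, whose single positive bias mimics the position effect\n",
    "at a smaller complexity cost -- the same mechanism by which a small\n",
    "primacy bias is confusable with the null model.\n", sep = "")
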