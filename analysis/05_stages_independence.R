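#!/usr/bin/env Rscript
# Life-history stages and offspring independence: delineates BPC / MOC
# / NPC windows per bird and estimates each male's offspring
# independence from the convergence of his daily dive effort onto the
# pooled female reference (rolling mean <= female mean + 1 SD sustained
# for 7 days), checked against the generator's truth.

library(murrelog)

cfg <- scenario_config(seed = 2010, n_females = 6, n_males = 6)
birds <- simulate_birds(cfg)

fem <- birds[birds$sex == "F", ]
ref <- female_effort_reference(lapply(seq_len(nrow(fem)), function(i)
  simulate_daily_effort(cfg, fem[i, ], i, dates = fem$departure_date[i] + 1:60)))
cat(sprintf("Female reference: %.1f +/- %.1f min/day (%d birds, %d days)\n",
            ref$mean, ref$sd, ref$n_birds, ref$n_days))

males <- birds[birds$sex == "M", ]
rows <- lapply(seq_len(nrow(males)), function(i) {
  b <- males[i, ]
  eff <- simulate_daily_effort(cfg, b, nrow(fem) + i,
                               dates = b$departure_date + 1:100)
  est <- estimate_independence(eff, b$departure_date, ref)
  data.frame(bird_id = b$bird_id, resolved = est$resolved,
             independence_days_est = est$independence_days,
             independence_days_true = b$dependence_days)
})
ind <- do.call(rbind, rows)

stages <- do.call(rbind, lapply(seq_len(nrow(birds)), function(i) {
  b <- birds[i, ]
  cbind(bird_id = b$bird_id, sex = b$sex,
        delineate_stages(b$sex, b$deployment_date, b$departure_date,
                         as.Date("2011-01-31"),
                         independence_date = b$independence_date))
}))
write.csv(stages, "results/05_stage_windows.csv", row.names = FALSE)
write.csv(ind, "results/05_independence.csv", row.names = FALSE)

err <- abs(ind$independence_days_est - ind$independence_days_true)
cat(sprintf("Independence resolved for %d/%d males; MAE %.1f d (true %s d)\n",
            sum(ind$resolved), nrow(ind), mean(err, na.rm = TRUE),
            paste(range(ind$independence_days_true), collapse = "-")))
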