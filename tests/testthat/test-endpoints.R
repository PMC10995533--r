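test_that("death counts treat trapped mosquitoes as killed", {
  expect_equal(death_count(data.frame(trapped = 4, dead_untrapped = 3,
                                      alive_delayed_dead = 1,
                                      alive_survived = 2)), 8L)
  expect_equal(death_count(data.frame(trapped = 0, dead_untrapped = 0,
                                      alive_delayed_dead = 0,
                                      alive_survived = 0)), 0L)
  # trapped-alive count as dead
  expect_equal(death_count(data.frame(trapped = 5, dead_untrapped = 0,
                                      alive_delayed_dead = 0,
                                      alive_survived = 9)), 5L)
  # never exceeds entry
  r <- random_records(50, seed = 8)
  expect_true(all(death_count(r) <= total_entry(r)))
})

test_that("arm summaries match hand-computed totals, means and SDs", {
  rec <- rbind(
    make_record(1, 1, "X", trapped = 2, dead = 3, delayed = 1, survived = 1),
    make_record(2, 1, "X", survived = 3),
    make_record(1, 2, "Y", dead = 4, survived = 4),
    make_record(2, 2, "Y", dead = 4, survived = 4)
  )
  s <- summarize_arm(rec, "X")
  expect_equal(s$n_hut_nights, 2)
  expect_equal(s$total_entry, 10)
  expect_equal(s$total_death, 6)
  expect_equal(s$mean_daily_entry, 5)
  expect_equal(s$sd_daily_entry, sd(c(7, 3)))
  expect_equal(s$mortality_pct, 60)
  expect_equal(s$trapped_total, 2)
  expect_equal(s$trap_attributable_pct, 100 * 2 / 6)
  # mean x n recovers the total exactly
  expect_equal(s$mean_daily_entry * s$n_hut_nights, s$total_entry)

  # two equal hut-nights give SD 0
  sy <- summarize_arm(rec, "Y")
  expect_equal(sy$sd_daily_entry, 0)
  expect_equal(sy$mortality_pct, 50)

  expect_error(summarize_arm(rec, "Z"), "lookup error|empty-data")
  expect_error(summarize_arm(rec, "X", species_group = "other"),
               "empty-data")
})

test_that("summaries are invariant under record order permutation", {
  rec <- random_records(80, seed = 5)
  rec <- rec[!duplicated(rec[c("night", "hut", "species_group")]), ]
  s1 <- summarize_arms(rec, arms = sort(unique(rec$arm)))
  s2 <- summarize_arms(rec[sample(nrow(rec)), ],
                       arms = sort(unique(rec$arm)))
  expect_equal(s1, s2)
})

test_that("pooled mortality equals the entry-weighted mean of
          per-hut-night mortality", {
  for (seed in 1:5) {
    rec <- random_records(60, seed = seed)
    rec <- rec[!duplicated(rec[c("night", "hut", "species_group")]), ]
    a <- unique(rec$arm)[1]
    s <- summarize_arm(rec, a)
    ra <- rec[rec$arm == a, ]
    hn <- paste(ra$night, ra$hut)
    e <- tapply(total_entry(ra), hn, sum)
    d <- tapply(death_count(ra), hn, sum)
    pos <- e > 0
    weighted <- 100 * sum(e[pos] * (d[pos] / e[pos])) / sum(e)
    expect_equal(s$mortality_pct, weighted)
  }
})

test_that("reference-arm killing effect formula gives the worked values", {
  expect_equal(killing_effect_methods(678, 413, 509)$value_pct,
               100 * 265 / 509)  # 52.06
  expect_equal(killing_effect_methods(678, 535, 611)$value_pct,
               100 * 143 / 611)  # 23.40
  expect_equal(killing_effect_methods(100, 100, 57)$value_pct, 0)
  expect_error(killing_effect_methods(1, 1, 0), "division-domain")
})

test_that("control-adjusted killing effect matches its worked values and
          is independent of the control kill", {
  expect_equal(killing_effect_control_adjusted(678, 413, 118, 450)$value_pct,
               100 * 265 / 450)  # 58.89
  expect_equal(killing_effect_control_adjusted(678, 505, 118, 450)$value_pct,
               100 * 173 / 450)  # 38.44
  expect_error(killing_effect_control_adjusted(1, 1, 1, 0),
               "division-domain")

  # algebraic cancellation of k_untreated, quantified
  set.seed(1)
  for (i in 1:50) {
    kc <- rpois(1, 300); kr <- rpois(1, 200); tu <- rpois(1, 400) + 1
    v1 <- killing_effect_control_adjusted(kc, kr, rpois(1, 100), tu)$value_pct
    v2 <- killing_effect_control_adjusted(kc, kr, rpois(1, 100), tu)$value_pct
    expect_equal(v1, v2)
    expect_equal(v1, 100 * (kc - kr) / tu)
  }
  # candidate = reference gives 0 regardless of the control
  expect_equal(killing_effect_control_adjusted(50, 50, 31, 400)$value_pct, 0)
})

test_that("killing-effect tables reproduce the reference-trial arithmetic", {
  an <- reference_trial_totals()$an_gambiae
  ca <- killing_effect_table(an, "T-LLIN",
                             reference_arms = c("PN2.0", "Tsara", "IG2"),
                             untreated_arm = "control",
                             variant = "control_adjusted")
  expect_equal(ca$value_pct, c(100 * 265 / 450, 100 * 173 / 450,
                               100 * 143 / 450), tolerance = 1e-12)

  me <- killing_effect_table(an, "T-LLIN",
                             reference_arms = c("PN2.0", "Tsara", "IG2"),
                             variant = "methods")
  expect_equal(round(me$value_pct, 2), c(52.06, 24.79, 23.40))

  # candidate as its own reference
  self <- killing_effect_table(an, "T-LLIN", reference_arms = "T-LLIN",
                               untreated_arm = "control")
  expect_equal(self$value_pct, 0)

  expect_error(killing_effect_table(an, "missing", untreated_arm = "control"),
               "lookup error")

  # single-arm dataset: empty table, no error
  one <- killing_effect_table(an[an$arm == "T-LLIN", ], "T-LLIN",
                              untreated_arm = NULL, variant = "methods")
  expect_equal(nrow(one), 0)
})
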