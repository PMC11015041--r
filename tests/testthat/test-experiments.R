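# Long coupled runs are shared through helper-cache.R (primed by the
# acceptance suite, which runs first alphabetically); everything else here
# is cheap.

test_that("sweep tables are tidy, deterministic in structure, and summarized", {
  sw <- krec_sweep_tumor1()
  expect_s3_class(sw, "psma_sweep")
  expect_identical(nrow(sw), 4L)
  expect_true(all(is.na(sw$error)))
  expect_true(all(sw$tia_tumor > 0))
  sm <- sweep_summary(sw)
  expect_identical(names(sm),
                   c("variable", "argmax_value", "tia_at_argmax", "fold_extremes"))
  expect_true(sm$argmax_value %in% sw$value)
  p <- autoplot(sw)
  expect_s3_class(p, "ggplot")
})

test_that("tumor-averaged total concentration exceeds the normal-tissue average", {
  sim <- bolus_infusion_pair()$sims$bolus
  tot_t <- rowSums(sim$ts$tumor[, c("C_F", "C_B", "C_I", "C_FU", "C_BU", "C_IU")])
  tot_n <- rowSums(sim$ts$normal[, c("C_F", "C_B", "C_I", "C_FU", "C_BU", "C_IU")])
  late <- sim$times_min > 30  # beyond the early filling transient
  expect_true(all(tot_t[late] > tot_n[late]))
})

test_that("free ligand peaks before bound, and bound before internalized", {
  sim <- bolus_infusion_pair()$sims$bolus
  pk <- peak_times(sim)
  tp <- function(s) pk$t_peak[pk$region == "tumor" & pk$species == s]
  expect_lt(tp("C_F"), tp("C_B"))
  expect_lt(tp("C_B"), tp("C_I"))
})

test_that("sustained infusion delays the free-ligand peak relative to a bolus", {
  cmp <- bolus_infusion_pair()
  pk <- cmp$peaks
  tp <- function(md) pk$t_peak[pk$mode == md & pk$region == "tumor" &
                                 pk$species == "C_F"]
  expect_gte(tp("infusion"), tp("bolus"))
})

test_that("simulation accessors return consistent tidy structures", {
  sim <- bolus_infusion_pair()$sims$bolus
  td <- tidy(sim)
  expect_true(all(c("t", "region", "species", "concentration") %in% names(td)))
  expect_setequal(unique(td$region), c("tumor", "normal"))
  g <- glance(sim)
  expect_identical(nrow(g), 1L)
  a <- auc_by_species(sim, "tumor")
  tot <- a$auc[a$species == "total_labeled"]
  parts <- sum(a$auc[a$species %in% c("C_F", "C_B", "C_I")])
  expect_equal(tot, parts, tolerance = 1e-10)  # AUC additivity
  nrm <- normalize_by_cp0(sim)
  cp0 <- sim$protocol$amount_total / sim$protocol$plasma_volume
  expect_equal(nrm$concentration_norm * cp0, nrm$concentration, tolerance = 1e-12)
  expect_s3_class(autoplot(sim), "ggplot")
})

test_that("the carrier-competition experiment reports both arms consistently", {
  # short-horizon version of the carrier-competition experiment; the
  # reported relative change must tie the two arms together exactly
  res <- carrier_competition_experiment(t_end_h = 10)
  expect_identical(res$arm, c("labeled_only", "with_carrier"))
  expect_true(all(res$tia_tumor > 0))
  expect_equal(res$tia_tumor[1] * (1 + res$relative_change[2]),
               res$tia_tumor[2], tolerance = 1e-12)
})

test_that("flow summaries expose the diagnostics a practitioner checks first", {
  ps <- load_parameters()
  fl <- solve_ifp(surrogate_phantom(), ps)
  g <- glance(fl)
  expect_true(g$fluid_balance_rel_error < 0.005)
  expect_true(g$p_center > g$p_normal_mean)
  expect_s3_class(autoplot(fl), "ggplot")
})

test_that("TIA rises with receptor density with a saturating (concave) shape", {
  sw <- receptor_density_sweep()
  sw <- sw[order(sw$value), ]
  expect_true(all(diff(sw$tia_tumor) > 0))
  slopes <- diff(sw$tia_tumor) / diff(sw$value)
  expect_true(all(diff(slopes) < 0))  # decreasing marginal gain above 100 nmol/L
})
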