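pep_row <- function(peptide, protein, heavy, time, genotype, light = 1,
                    replicate = 1L) {
  data.frame(peptide = peptide, protein = protein, heavy_area = heavy,
             light_area = light, chase_time = time, genotype = genotype,
             replicate = replicate)
}

test_that("protein rollup is the arithmetic mean including singletons", {
  rec <- rbind(
    pep_row(c("AK", "BK", "CK"), "P1", c(10, 20, 30), 0, "CTRL"),
    pep_row("DK", "P2", 7, 0, "CTRL"),
    pep_row("EK", "P3", 5, 0, "CTRL")
  )
  expect_equal(rollup_protein_heavy(rec, "P1", 0, "CTRL"), 20)
  expect_equal(rollup_protein_heavy(rec, "P2", 0, "CTRL"), 7)   # singleton
  expect_true(is.na(rollup_protein_heavy(rec, "P9", 0, "CTRL"))) # absent, not 0
  # zero-heavy observations are not labeled peptides and do not dilute
  rec2 <- rbind(rec, pep_row("FK", "P1", 0, 0, "CTRL", light = 5))
  expect_equal(rollup_protein_heavy(rec2, "P1", 0, "CTRL"), 20)
})

test_that("profiles anchor at chase start and apply the ratio < 1 rule", {
  rec <- rbind(
    pep_row("AK", "P1", 100, 0, "CTRL"), pep_row("AK", "P1", 44, 5, "CTRL"),
    # P2's only later ratio is >= 1: whole protein-genotype dropped
    pep_row("BK", "P2", 10, 0, "CTRL"), pep_row("BK", "P2", 13, 1, "CTRL"),
    # P3 mixes one admissible and one inadmissible time
    pep_row("CK", "P3", 50, 0, "CTRL"), pep_row("CK", "P3", 55, 1, "CTRL"),
    pep_row("CK", "P3", 20, 5, "CTRL"),
    # P4 has no anchor
    pep_row("DK", "P4", 9, 5, "CTRL")
  )
  prof <- turnover_profiles(rec)
  expect_equal(prof$ratio[prof$protein == "P1"], 0.44)
  expect_false("P2" %in% prof$protein)
  expect_equal(prof$chase_time[prof$protein == "P3"], 5)
  expect_equal(prof$ratio[prof$protein == "P3"], 0.4)
  expect_false("P4" %in% prof$protein)
  expect_true(all(prof$ratio < 1))
  expect_error(turnover_profiles(rec[rec$chase_time > 0, ]),
               class = "silac_validation_error")
})

test_that("common proteins are the per-time genotype intersection", {
  rec <- rbind(
    pep_row("AK", "P1", c(100, 50), c(0, 5), "MUT"),
    pep_row("BK", "P1", c(100, 40), c(0, 5), "CTRL"),
    pep_row("CK", "P2", c(80, 30), c(0, 5), "MUT")
  )
  prof <- turnover_profiles(rec)
  expect_equal(common_proteins(prof, 5), "P1")
  expect_equal(common_proteins(prof, 21), character(0))
})

test_that("ties are non-persisting and fractions use strict inequality", {
  rec <- rbind(
    pep_row("AK", "P1", c(100, 50), c(0, 5), "MUT"),
    pep_row("BK", "P1", c(200, 100), c(0, 5), "CTRL"),   # identical ratio 0.5
    pep_row("CK", "P2", c(100, 60), c(0, 5), "MUT"),
    pep_row("DK", "P2", c(100, 40), c(0, 5), "CTRL")     # mut persists
  )
  pc <- persistence_calls(turnover_profiles(rec))
  expect_equal(pc$fractions$n_common, 2)
  expect_equal(pc$fractions$n_persisting, 1)
  calls <- pc$calls
  expect_false(calls$persists[calls$protein == "P1"])
  expect_true(calls$persists[calls$protein == "P2"])
})

test_that("persists_all requires commonality and persistence at every time", {
  rec <- rbind(
    pep_row("AK", "P1", c(100, 90, 50, 20), c(0, 1, 5, 21), "MUT"),
    pep_row("BK", "P1", c(100, 80, 40, 10), c(0, 1, 5, 21), "CTRL"),
    pep_row("CK", "P2", c(100, 90, 50), c(0, 1, 5), "MUT"),  # absent at 21
    pep_row("DK", "P2", c(100, 80, 40), c(0, 1, 5), "CTRL")
  )
  pc <- persistence_calls(turnover_profiles(rec), chase_times = c(1, 5, 21))
  at <- pc$all_times
  expect_true(at$persists_all[at$protein == "P1"])
  expect_false(at$persists_all[at$protein == "P2"])
  expect_equal(pc$venn$n_proteins[pc$venn$times == "1&5&21"], 1)
  expect_equal(pc$venn$n_proteins[pc$venn$times == "1&5"], 1)
})

test_that("paired comparison matches the textbook paired-t computation", {
  mk <- function(mut_r, ctrl_r) {
    rows <- list()
    for (i in seq_along(mut_r)) {
      p <- sprintf("P%d", i)
      rows[[length(rows) + 1]] <- pep_row(paste0("A", i, "K"), p, c(100, 100 * mut_r[i]), c(0, 5), "MUT")
      rows[[length(rows) + 1]] <- pep_row(paste0("B", i, "K"), p, c(100, 100 * ctrl_r[i]), c(0, 5), "CTRL")
    }
    turnover_profiles(do.call(rbind, rows))
  }
  mut <- c(0.6, 0.7, 0.8); ctrl <- c(0.4, 0.45, 0.6)
  cmp <- compare_mean_normalized_intensity(mk(mut, ctrl), 5)
  d <- mut - ctrl
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp$t, t_hand, tolerance = 1e-12)
  expect_equal(cmp$p_paired, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)
  expect_equal(cmp$mean_mut - cmp$mean_ctrl, mean(d), tolerance = 1e-12)
  # identical profiles: zero difference, p = 1
  cmp0 <- compare_mean_normalized_intensity(mk(mut, mut), 5)
  expect_equal(cmp0$p_paired, 1)
  expect_equal(cmp0$t, 0)
  expect_error(compare_mean_normalized_intensity(mk(0.5, 0.4), 5),
               class = "silac_insufficient_data_error")
})

test_that("peptide-level comparison self-normalizes and tests across genotypes", {
  mk <- function(mut_vals, ctrl_vals) {
    rows <- list()
    for (i in seq_along(mut_vals)) {
      rows[[length(rows) + 1]] <- pep_row(sprintf("M%dK", i), "P1",
                                          c(100, 100 * mut_vals[i]), c(0, 5), "MUT")
    }
    for (i in seq_along(ctrl_vals)) {
      rows[[length(rows) + 1]] <- pep_row(sprintf("C%dK", i), "P1",
                                          c(50, 50 * ctrl_vals[i]), c(0, 5), "CTRL")
    }
    do.call(rbind, rows)
  }
  jit <- c(-0.005, 0, 0.005)
  out <- peptide_level_comparison(mk(0.8 + jit, 0.4 + jit), "P1", 5)
  expect_equal(out$mean_mut, 0.8, tolerance = 1e-9)
  expect_equal(out$mean_ctrl, 0.4, tolerance = 1e-9)
  expect_lt(out$p_unpaired, 0.01)
  # hand-computed Welch statistic
  v <- var(0.8 + jit) / 3 + var(0.4 + jit) / 3
  expect_equal(out$t, (0.8 - 0.4) / sqrt(v), tolerance = 1e-9)
  # identical value sets across genotypes: p = 1
  out0 <- peptide_level_comparison(mk(0.8 + jit, 0.8 + jit), "P1", 5)
  expect_equal(out0$p_unpaired, 1, tolerance = 1e-9)
  expect_error(peptide_level_comparison(mk(0.8, 0.4 + jit), "P1", 5),
               class = "silac_insufficient_data_error")
})

test_that("peptide values equal exp(-k t) in a noiseless simulation", {
  cfg <- turnover_sim_config(n_proteins = 6, noise_cv = 0,
                             dropout_midpoint = -Inf, frac_slowed = 0.5,
                             rate_factor = 0.5, peptides_per_protein = c(3, 5),
                             seed = 41)
  sim <- simulate_turnover(cfg)
  tr <- sim$truth$proteins
  for (p in tr$protein[1:3]) {
    out <- peptide_level_comparison(sim$records, p, 5)
    k_mut <- tr$k_mut[tr$protein == p]; k_ctrl <- tr$k_ctrl[tr$protein == p]
    expect_equal(unique(round(out$values$value[out$values$genotype == "MUT"], 12)),
                 round(exp(-k_mut * 5), 12))
    expect_equal(unique(round(out$values$value[out$values$genotype == "CTRL"], 12)),
                 round(exp(-k_ctrl * 5), 12))
  }
})

test_that("global rescaling leaves ratios unchanged; single-run scaling does not", {
  sim <- simulate_turnover(turnover_sim_config(n_proteins = 12, seed = 33))
  rec <- sim$records
  prof <- turnover_profiles(rec)
  all_scaled <- rec
  all_scaled$heavy_area <- all_scaled$heavy_area * 3.7
  all_scaled$light_area <- all_scaled$light_area * 3.7
  expect_equal(turnover_profiles(all_scaled)$ratio, prof$ratio, tolerance = 1e-12)
  one_run <- rec
  hit <- one_run$chase_time == 5 & one_run$genotype == "MUT"
  one_run$heavy_area[hit] <- one_run$heavy_area[hit] * 3.7
  prof2 <- turnover_profiles(one_run)
  r1 <- prof$ratio[prof$chase_time == 5 & prof$genotype == "MUT"]
  r2 <- prof2$ratio[prof2$chase_time == 5 & prof2$genotype == "MUT"]
  expect_false(isTRUE(all.equal(r1, r2)))
})

test_that("median-of-ratios normalization undoes a single-run scale factor", {
  cfg <- turnover_sim_config(n_proteins = 15, noise_cv = 0,
                             dropout_midpoint = -Inf, seed = 44)
  rec <- simulate_turnover(cfg)$records
  skewed <- rec
  hit <- skewed$chase_time == 5 & skewed$genotype == "MUT"
  skewed$heavy_area[hit] <- skewed$heavy_area[hit] * 2.5
  skewed$light_area[hit] <- skewed$light_area[hit] * 2.5
  # normalization restores the turnover ratios the scaling had distorted
  prof_fixed <- turnover_profiles(normalize_runs(skewed))
  prof_ref <- turnover_profiles(rec)
  expect_false(isTRUE(all.equal(turnover_profiles(skewed)$ratio, prof_ref$ratio)))
  expect_equal(prof_fixed$ratio, prof_ref$ratio, tolerance = 1e-9)
})
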