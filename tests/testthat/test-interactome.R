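sc_row <- function(protein, bait, count, genotype = "MUT", replicate = 1L) {
  data.frame(protein = protein, bait = bait, genotype = genotype,
             replicate = replicate, spec_count = count)
}

test_that("bait normalization divides by the bait count", {
  run <- sc_row(c("VCP", "P1"), "VCP", c(50L, 10L))
  norm <- bait_normalize(run)
  expect_equal(norm[["P1"]], 0.2)
  expect_equal(norm[["VCP"]], 1)
  expect_error(bait_normalize(sc_row(c("VCP", "P1"), "VCP", c(0L, 10L))),
               class = "silac_bait_missing_error")
  expect_error(bait_normalize(sc_row("P1", "VCP", 10L)),
               class = "silac_bait_missing_error")
})

test_that("replicate routes: exclusivity, strict >3 ratio, failure", {
  rec <- rbind(
    sc_row(c("VCP", "A", "B", "C"), "VCP", c(50L, 9L, 9L, 10L)),
    sc_row(c("B", "C"), "IGG", c(3L, 3L))
  )
  calls <- call_replicate(rec, "MUT", 1)
  route <- setNames(calls$route, calls$protein)
  expect_equal(route[["A"]], "EXCLUSIVE")      # VCP 9, IgG absent
  expect_equal(route[["B"]], "FAIL")           # ratio exactly 3 fails
  expect_equal(route[["C"]], "RATIO_PASS")     # 10/3 > 3
  expect_false("VCP" %in% calls$protein)       # bait is not its own interactor
  expect_equal(calls$igg_ratio[calls$protein == "A"], Inf)
  # a configurable IgG floor relaxes presence/absence exclusivity
  calls2 <- call_replicate(rec, "MUT", 1, igg_floor = 3)
  expect_equal(calls2$route[calls2$protein == "B"], "EXCLUSIVE")
})

test_that("concordance needs a qualifying route in every replicate", {
  rec <- rbind(
    sc_row(c("VCP", "A", "B"), "VCP", c(40L, 9L, 8L), replicate = 1L),
    sc_row(c("VCP", "A", "B"), "VCP", c(45L, 7L, 20L), replicate = 2L),
    sc_row(c("VCP", "A", "B"), "VCP", c(50L, 6L, 21L), replicate = 3L),
    sc_row("B", "IGG", 4L, replicate = 2L),    # B: 20/4 = 5 > 3, passes by ratio
    sc_row("A", "IGG", 5L, replicate = 3L)     # A: 6/5 fails in rep 3
  )
  calls <- dplyr::bind_rows(lapply(1:3, function(r) call_replicate(rec, "MUT", r)))
  expect_equal(concordant_interactors(calls), "B")  # route mixing allowed
  expect_equal(concordant_interactors(calls, n_required = 2), c("A", "B"))
  expect_error(concordant_interactors(calls, n_required = 4),
               class = "silac_config_error")
  # absence from one replicate's VCP run blocks the call
  rec2 <- rec[!(rec$protein == "B" & rec$replicate == 1), ]
  calls2 <- dplyr::bind_rows(lapply(1:3, function(r) call_replicate(rec2, "MUT", r)))
  expect_equal(concordant_interactors(calls2), character(0))
})

test_that("genotype partition is the straightforward set algebra", {
  part <- genotype_partition(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(part$MUT_ONLY, "A")
  expect_equal(part$CTRL_ONLY, "D")
  expect_equal(part$COMMON, c("B", "C"))
  same <- genotype_partition(c("A", "B"), c("A", "B"))
  expect_equal(same$MUT_ONLY, character(0))
  expect_equal(same$CTRL_ONLY, character(0))
  disjoint <- genotype_partition("A", "B")
  expect_equal(disjoint$COMMON, character(0))
})

test_that("shared-set enrichment matches a hand-computed Welch t test", {
  mk <- function(mut_counts, ctrl_counts, bait = 100L) {
    rows <- list()
    for (r in 1:3) {
      rows[[length(rows) + 1]] <- sc_row(c("VCP", "X"), "VCP",
                                         c(bait, mut_counts[r]), "MUT", r)
      rows[[length(rows) + 1]] <- sc_row(c("VCP", "X"), "VCP",
                                         c(bait, ctrl_counts[r]), "CTRL", r)
    }
    do.call(rbind, rows)
  }
  rec <- mk(c(30L, 31L, 29L), c(10L, 11L, 9L))
  out <- common_enrichment(rec, "X")
  expect_equal(out$mean_ratio_mut, 0.30)
  expect_equal(out$mean_ratio_ctrl, 0.10)
  expect_lt(out$p_value, 0.05)
  expect_equal(out$enriched_in, "MUT")
  ht <- t.test(c(30, 31, 29) / 100, c(10, 11, 9) / 100)
  expect_equal(out$t, unname(ht$statistic), tolerance = 1e-12)
  expect_equal(out$p_value, ht$p.value, tolerance = 1e-12)
  # identical ratio vectors: p = 1, NEITHER
  out0 <- common_enrichment(mk(c(20L, 21L, 19L), c(20L, 21L, 19L)), "X")
  expect_equal(out0$p_value, 1, tolerance = 1e-9)
  expect_equal(out0$enriched_in, "NEITHER")
  # missing replicate values flag the protein with NA p
  rec_na <- rec[!(rec$protein == "X" & rec$genotype == "CTRL" & rec$replicate > 1), ]
  out_na <- common_enrichment(rec_na, "X")
  expect_true(is.na(out_na$p_value))
  expect_equal(out_na$enriched_in, "NEITHER")
})

test_that("raising the ratio threshold never grows an interactor set", {
  set.seed(61)
  for (i in 1:5) {
    rec <- random_speccount_table(15)
    sets <- lapply(c(1, 3, 5, 10), function(th) {
      res <- interactome_pipeline(rec, threshold = th)
      sort(unique(unlist(res$interactors)))
    })
    for (j in seq_along(sets)[-1]) {
      expect_true(all(sets[[j]] %in% sets[[j - 1]]))
    }
  }
})

test_that("zero-leak simulation: all present interactors called, parity never", {
  sim <- simulate_ip(ip_sim_config(
    n_true_interactors = 40, n_background = 30, interactor_igg_leak = 0,
    igg_leak_range = c(0.9, 1.0), interactor_ratio_range = c(0.1, 0.5),
    frac_mut_exclusive = 0, frac_ctrl_exclusive = 0, seed = 67
  ))
  res <- interactome_pipeline(sim$records)
  vcp_runs <- sim$records[sim$records$bait == "VCP", ]
  present_all <- names(which(table(vcp_runs$protein[grepl("^INT", vcp_runs$protein)]) == 6))
  expect_true(all(present_all %in% res$partition$COMMON))
  # background proteins with near-parity IgG counts are never called
  called_bg <- grep("^BG", unlist(res$interactors), value = TRUE)
  for (p in called_bg) {
    calls <- res$calls[res$calls$protein == p, ]
    expect_true(all(calls$igg_count == 0 | calls$igg_ratio > 3))
  }
})

test_that("shared-set enrichment flags about alpha of proteins under the null", {
  flagged <- 0; tested <- 0
  for (s in 1:20) {
    sim <- simulate_ip(ip_sim_config(n_true_interactors = 60, n_background = 0,
                                     frac_mut_exclusive = 0, frac_ctrl_exclusive = 0,
                                     seed = 300 + s))
    res <- interactome_pipeline(sim$records)
    ok <- !is.na(res$enrichment$p_value)
    tested <- tested + sum(ok)
    flagged <- flagged + sum(res$enrichment$enriched_in[ok] != "NEITHER")
  }
  rate <- flagged / tested
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.12)
})

test_that("pipeline recovers the planted genotype partition", {
  sim <- simulate_ip(ip_sim_config(n_true_interactors = 100, n_background = 50,
                                   interactor_ratio_range = c(0.05, 0.5),
                                   seed = 71))
  res <- interactome_pipeline(sim$records)
  truth <- sim$truth
  for (cl in c("MUT_ONLY", "CTRL_ONLY", "COMMON")) {
    planted <- truth$protein[truth$class == cl]
    recall <- mean(planted %in% res$partition[[cl]])
    expect_gt(recall, 0.9)
  }
  expect_false(any(grepl("^BG", unlist(res$partition))))
})
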