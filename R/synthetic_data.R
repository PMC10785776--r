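# Synthetic pulse-chase and IP-MS data with known ground truth
#
# The generators emulate the statistical structure of the two experiment
# types the pipeline consumes — peptide-level heavy/light MS1 areas along a
# SILAC chase, and spectral counts from bait-vs-IgG immunoprecipitations —
# so every downstream stage has a parameter-recovery oracle.  They simulate
# post-search quantification tables, not spectra.

#' Configuration for the pulse-chase turnover simulation
#'
#' The simulated design follows a SILAC pulse-chase in postmitotic neuron
#' cultures: heavy labeling to steady state, then chase sampling at 0, 1, 5
#' and 21 days.  Per-protein first-order degradation rates k (1/day) are
#' drawn log-normally; a fraction of proteins degrade more slowly in the
#' mutant genotype (rate multiplied by `rate_factor`).  The default rate
#' distribution `k ~ 10^N(-0.89, 0.40)` puts half of the labeled material
#' below 50% remaining by day 5 and ~15% remaining at day 21.
#'
#' @param n_proteins Number of proteins.
#' @param peptides_per_protein Integer range `c(min, max)`; each protein's
#'   peptide count is drawn uniformly from it.
#' @param chase_times Chase sampling times in days; must be ascending and
#'   contain 0 (0 = end of pulse, day 30 in vitro).
#' @param k_log10_mean,k_log10_sd Mean and SD of log10(k), k in 1/day.
#' @param frac_slowed Fraction of proteins whose mutant rate is reduced.
#' @param rate_factor Multiplier in (0, 1] applied to k for slowed proteins
#'   in the mutant genotype.
#' @param label_efficiency Heavy fraction at chase time 0, in (0, 1].
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise (0 disables noise).
#' @param dropout_midpoint,dropout_steepness Logistic intensity-dependent
#'   missingness: a peptide-run is dropped with probability
#'   `plogis(steepness * (midpoint - log10(expected total area)))`.
#'   Set `dropout_midpoint = -Inf` to disable dropout.
#' @param abundance_meanlog,abundance_sdlog Log-normal protein abundance
#'   distribution (arbitrary area units).
#' @param ion_sdlog Log-scale SD of the per-peptide ionization factor
#'   (drawn once per peptide, shared across all runs).
#' @param n_replicates Independent replicate experiments to emit.
#' @param seed Integer seed; the single RNG stream and documented draw
#'   order make output tables byte-identical across runs.
#' @return Object of class `turnover_sim_config`.
#' @export
turnover_sim_config <- function(n_proteins = 500,
                                peptides_per_protein = c(3, 15),
                                chase_times = c(0, 1, 5, 21),
                                k_log10_mean = -0.89,
                                k_log10_sd = 0.40,
                                frac_slowed = 0.2,
                                rate_factor = 0.5,
                                label_efficiency = 0.9,
                                noise_cv = 0.2,
                                dropout_midpoint = 4.7,
                                dropout_steepness = 2,
                                abundance_meanlog = log(1e6),
                                abundance_sdlog = 1,
                                ion_sdlog = 0.5,
                                n_replicates = 1,
                                seed = 1L) {
  cfg <- list(
    n_proteins = n_proteins, peptides_per_protein = peptides_per_protein,
    chase_times = sort(unique(chase_times)),
    k_log10_mean = k_log10_mean, k_log10_sd = k_log10_sd,
    frac_slowed = frac_slowed, rate_factor = rate_factor,
    label_efficiency = label_efficiency, noise_cv = noise_cv,
    dropout_midpoint = dropout_midpoint, dropout_steepness = dropout_steepness,
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    ion_sdlog = ion_sdlog, n_replicates = n_replicates, seed = as.integer(seed)
  )
  if (cfg$n_proteins < 1) stop_config("n_proteins must be >= 1")
  if (length(cfg$peptides_per_protein) != 2 ||
      cfg$peptides_per_protein[1] < 1 ||
      cfg$peptides_per_protein[2] < cfg$peptides_per_protein[1]) {
    stop_config("peptides_per_protein must be c(min, max) with 1 <= min <= max")
  }
  if (!0 %in% cfg$chase_times || any(cfg$chase_times < 0)) {
    stop_config("chase_times must be nonnegative and contain 0")
  }
  if (cfg$frac_slowed < 0 || cfg$frac_slowed > 1) stop_config("frac_slowed must be in [0, 1]")
  if (cfg$rate_factor <= 0 || cfg$rate_factor > 1) stop_config("rate_factor must be in (0, 1]")
  if (cfg$label_efficiency <= 0 || cfg$label_efficiency > 1) {
    stop_config("label_efficiency must be in (0, 1]")
  }
  if (cfg$noise_cv < 0) stop_config("noise_cv must be >= 0")
  if (cfg$n_replicates < 1) stop_config("n_replicates must be >= 1")
  structure(cfg, class = "turnover_sim_config")
}

# tryptic-looking peptide sequences, unique within the table
random_peptides <- function(n, min_len = 7, max_len = 15) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]  # no K/R internally
  draw <- function(m) {
    lens <- sample(min_len:max_len, m, replace = TRUE)
    core <- vapply(lens, function(l) paste(sample(aa, l, replace = TRUE), collapse = ""),
                   character(1))
    paste0(core, sample(c("K", "R"), m, replace = TRUE))
  }
  out <- draw(n)
  while (anyDuplicated(out)) {
    idx <- which(duplicated(out))
    out[idx] <- draw(length(idx))
  }
  out
}

lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)  # mean exactly 1
}

#' Simulate a pulse-chase peptide quantification table
#'
#' Under the steady-state pool assumption (synthesis balances degradation,
#' total abundance constant — appropriate for postmitotic cells), protein p
#' / peptide j at time t in genotype g has expected areas
#' \deqn{heavy = A_p \cdot ion_j \cdot E \cdot e^{-k_{p,g} t}, \quad
#'       light = A_p \cdot ion_j \cdot (1 - E e^{-k_{p,g} t})}
#' with E the labeling efficiency.  Observed areas are the expectations
#' times mean-1 log-normal noise of CV `noise_cv`; each peptide-run is
#' dropped with the logistic missingness probability evaluated at its
#' expected total (heavy + light) intensity.
#'
#' Draw order (single stream from `seed`): protein abundances, rates k,
#' slowed subset, peptide counts, peptide sequences, ionization factors,
#' then per (replicate, genotype, time, peptide) cell: dropout uniforms,
#' heavy noise, light noise.
#'
#' @param config A [turnover_sim_config()].
#' @return List with `records` (tibble of peptide records) and `truth`
#'   (list of `proteins` and `peptides` tibbles holding the generating
#'   parameters).
#' @export
#' @examples
#' sim <- simulate_turnover(turnover_sim_config(n_proteins = 5, seed = 42))
#' head(sim$records)
simulate_turnover <- function(config) {
  if (!inherits(config, "turnover_sim_config")) config <- do.call(turnover_sim_config, config)
  set.seed(config$seed)
  n <- config$n_proteins
  protein_ids <- sprintf("P%04d", seq_len(n))

  abundance <- rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  k_ctrl <- 10^rnorm(n, config$k_log10_mean, config$k_log10_sd)
  n_slow <- round(config$frac_slowed * n)
  slowed_idx <- if (n_slow > 0) sample.int(n, n_slow) else integer(0)
  slowed <- seq_len(n) %in% slowed_idx
  k_mut <- ifelse(slowed, k_ctrl * config$rate_factor, k_ctrl)

  n_pep <- sample(config$peptides_per_protein[1]:config$peptides_per_protein[2],
                  n, replace = TRUE)
  peptides <- tibble(
    protein = rep(protein_ids, n_pep),
    peptide = random_peptides(sum(n_pep)),
    ion_factor = rlnorm(sum(n_pep), -config$ion_sdlog^2 / 2, config$ion_sdlog)
  )

  grid <- tidyr::expand_grid(
    replicate = seq_len(config$n_replicates),
    genotype = GENOTYPES,
    chase_time = config$chase_times,
    peptides
  )
  pidx <- match(grid$protein, protein_ids)
  k <- ifelse(grid$genotype == "MUT", k_mut[pidx], k_ctrl[pidx])
  E <- config$label_efficiency
  decay <- exp(-k * grid$chase_time)
  base <- abundance[pidx] * grid$ion_factor
  mu_heavy <- base * E * decay
  mu_light <- base * (1 - E * decay)

  m <- nrow(grid)
  p_drop <- plogis(config$dropout_steepness * (config$dropout_midpoint - log10(base)))
  keep <- runif(m) >= p_drop
  heavy <- mu_heavy * lognorm_noise(m, config$noise_cv)
  light <- mu_light * lognorm_noise(m, config$noise_cv)

  records <- tibble(
    peptide = grid$peptide, protein = grid$protein,
    heavy_area = heavy, light_area = light,
    chase_time = grid$chase_time, genotype = grid$genotype,
    replicate = as.integer(grid$replicate)
  )[keep, ]
  records <- records[records$heavy_area > 0 | records$light_area > 0, ]

  truth_proteins <- tibble(
    protein = protein_ids, abundance = abundance,
    k_ctrl = k_ctrl, k_mut = k_mut, slowed = slowed
  )
  list(
    records = validate_peptide_records(records),
    truth = list(proteins = truth_proteins, peptides = peptides),
    config = config
  )
}

#' Configuration for the IP spectral-count simulation
#'
#' Models a crosslink-IP/MS design: for each genotype, `n_replicates`
#' paired bait (VCP) and IgG-control runs.  True interactors receive
#' bait-proportional counts in VCP runs and (by default) zero IgG counts;
#' background proteins receive comparable VCP and IgG counts.  Fractions of
#' true interactors can be made genotype-exclusive; default fractions
#' mirror a 153/157/399 mut-exclusive/control-exclusive/shared split of
#' 709 interactors.
#'
#' @param n_true_interactors,n_background Protein counts per class.
#' @param bait_count_mean Expected bait spectral count per VCP run.
#' @param interactor_ratio_range Uniform range for a true interactor's
#'   expected VCP-run count as a fraction of `bait_count_mean`.
#' @param igg_leak_range Uniform range in \[0, 1\] for the fraction of a
#'   background protein's VCP-run expectation appearing in the IgG run.
#' @param interactor_igg_leak Leak fraction for true interactors (default
#'   0: interactors are bait-exclusive).
#' @param bg_count_mean Center of background VCP-run expected counts
#'   (per-protein expectations drawn uniformly in 0.5–2 times this).
#' @param frac_mut_exclusive,frac_ctrl_exclusive Fractions of true
#'   interactors emitted only in MUT (resp. CTRL) runs; the remainder are
#'   shared.  Must sum to at most 1.
#' @param n_replicates Independent IP replicates per genotype (default 3).
#' @param count_noise Count distribution; only `"poisson"` is implemented.
#' @param seed Integer seed.
#' @return Object of class `ip_sim_config`.
#' @export
ip_sim_config <- function(n_true_interactors = 709,
                          n_background = 300,
                          bait_count_mean = 200,
                          interactor_ratio_range = c(0.02, 0.5),
                          igg_leak_range = c(0.6, 1.0),
                          interactor_igg_leak = 0,
                          bg_count_mean = 10,
                          frac_mut_exclusive = 153 / 709,
                          frac_ctrl_exclusive = 157 / 709,
                          n_replicates = 3,
                          count_noise = "poisson",
                          seed = 1L) {
  cfg <- list(
    n_true_interactors = n_true_interactors, n_background = n_background,
    bait_count_mean = bait_count_mean,
    interactor_ratio_range = interactor_ratio_range,
    igg_leak_range = igg_leak_range, interactor_igg_leak = interactor_igg_leak,
    bg_count_mean = bg_count_mean,
    frac_mut_exclusive = frac_mut_exclusive,
    frac_ctrl_exclusive = frac_ctrl_exclusive,
    n_replicates = as.integer(n_replicates), count_noise = count_noise,
    seed = as.integer(seed)
  )
  if (cfg$n_true_interactors < 1) stop_config("n_true_interactors must be >= 1")
  if (cfg$n_background < 0) stop_config("n_background must be >= 0")
  if (cfg$bait_count_mean <= 0) stop_config("bait_count_mean must be > 0")
  if (cfg$frac_mut_exclusive < 0 || cfg$frac_ctrl_exclusive < 0 ||
      cfg$frac_mut_exclusive + cfg$frac_ctrl_exclusive > 1 + 1e-12) {
    stop_config("exclusivity fractions must be nonnegative and sum to <= 1")
  }
  if (any(cfg$igg_leak_range < 0) || any(cfg$igg_leak_range > 1)) {
    stop_config("igg_leak_range must lie in [0, 1]")
  }
  if (cfg$n_replicates < 1) stop_config("n_replicates must be >= 1")
  if (!identical(cfg$count_noise, "poisson")) stop_config("count_noise must be 'poisson'")
  structure(cfg, class = "ip_sim_config")
}

#' Simulate an IP spectral-count table
#'
#' Every VCP run contains the bait with count ~ Poisson(`bait_count_mean`).
#' A true interactor's VCP-run count is Poisson with mean `ratio *
#' bait_count_mean` (ratio drawn once per protein from
#' `interactor_ratio_range`); its IgG-run mean is that times
#' `interactor_igg_leak`.  Background proteins appear in both VCP and IgG
#' runs of both genotypes with comparable Poisson means.  Zero counts are
#' not emitted (absence from a run encodes a zero count).
#'
#' Draw order (single stream from `seed`): interactor ratios, background
#' means, background leaks, then per genotype and replicate: bait count,
#' interactor VCP counts, interactor IgG counts, background VCP counts,
#' background IgG counts.
#'
#' @param config An [ip_sim_config()].
#' @return List with `records` (spectral-count tibble) and `truth` (tibble:
#'   protein, class in MUT_ONLY/CTRL_ONLY/COMMON/BACKGROUND, and per-genotype
#'   interactor flags).
#' @export
simulate_ip <- function(config) {
  if (!inherits(config, "ip_sim_config")) config <- do.call(ip_sim_config, config)
  set.seed(config$seed)
  n_int <- config$n_true_interactors
  n_mut <- round(config$frac_mut_exclusive * n_int)
  n_ctrl <- round(config$frac_ctrl_exclusive * n_int)
  if (n_mut + n_ctrl > n_int) n_ctrl <- n_int - n_mut
  class_int <- rep(c("MUT_ONLY", "CTRL_ONLY", "COMMON"),
                   c(n_mut, n_ctrl, n_int - n_mut - n_ctrl))
  int_ids <- sprintf("INT%04d", seq_len(n_int))
  bg_ids <- if (config$n_background > 0) sprintf("BG%04d", seq_len(config$n_background)) else character(0)

  ratio <- runif(n_int, config$interactor_ratio_range[1], config$interactor_ratio_range[2])
  bg_mu <- config$bg_count_mean * runif(config$n_background, 0.5, 2)
  bg_leak <- runif(config$n_background, config$igg_leak_range[1], config$igg_leak_range[2])

  rows <- list()
  for (g in GENOTYPES) {
    present <- class_int == "COMMON" |
      (g == "MUT" & class_int == "MUT_ONLY") |
      (g == "CTRL" & class_int == "CTRL_ONLY")
    for (r in seq_len(config$n_replicates)) {
      bait_count <- rpois(1, config$bait_count_mean)
      int_vcp <- rpois(n_int, ratio * config$bait_count_mean)
      int_igg <- rpois(n_int, config$interactor_igg_leak * ratio * config$bait_count_mean)
      bg_vcp <- rpois(config$n_background, bg_mu)
      bg_igg <- rpois(config$n_background, bg_mu * bg_leak)
      vcp <- tibble(
        protein = c("VCP", int_ids[present], bg_ids),
        bait = "VCP", genotype = g, replicate = as.integer(r),
        spec_count = as.integer(c(bait_count, int_vcp[present], bg_vcp))
      )
      igg <- tibble(
        protein = c(int_ids[present], bg_ids),
        bait = "IGG", genotype = g, replicate = as.integer(r),
        spec_count = as.integer(c(int_igg[present], bg_igg))
      )
      rows[[length(rows) + 1]] <- dplyr::bind_rows(vcp, igg)
    }
  }
  records <- dplyr::bind_rows(rows)
  records <- records[records$spec_count > 0 | records$protein == "VCP", ]

  truth <- tibble(
    protein = c("VCP", int_ids, bg_ids),
    class = c("BAIT", class_int, rep("BACKGROUND", config$n_background))
  )
  truth$interactor_mut <- truth$class %in% c("MUT_ONLY", "COMMON")
  truth$interactor_ctrl <- truth$class %in% c("CTRL_ONLY", "COMMON")
  list(
    records = validate_speccount_records(records),
    truth = truth,
    config = config
  )
}
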