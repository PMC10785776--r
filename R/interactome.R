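# IP-MS interactor filtering and genotype comparison
#
# Filtering follows four rules applied to paired bait (VCP) and IgG
# control runs: (1) bait normalization — each protein's spectral count
# over the bait's count in the same run; (2) IgG exclusivity — proteins
# co-precipitating only with the bait; (3) for proteins co-precipitating
# with both, a raw VCP/IgG count ratio strictly greater than 3; (4)
# replicate concordance — a protein must qualify (by either route) in
# every independent IP replicate.  Interactor sets are then partitioned
# across genotypes and the shared set is tested for genotype enrichment
# with per-protein unpaired t tests on bait-normalized ratios.

subset_run <- function(records, bait, genotype, replicate) {
  records[records$bait == bait & records$genotype == genotype &
            records$replicate == replicate, , drop = FALSE]
}

#' Bait-normalize one IP run
#'
#' Divides every protein's spectral count by the bait's count in the same
#' run; the bait maps to 1.
#'
#' @param run_records Spectral-count records of a single run (one bait x
#'   genotype x replicate).
#' @param bait_protein Accession of the bait (default `"VCP"`).
#' @return Named numeric vector: protein -> count / bait count.
#' @export
bait_normalize <- function(run_records, bait_protein = "VCP") {
  bait_count <- run_records$spec_count[run_records$protein == bait_protein]
  if (length(bait_count) != 1 || bait_count <= 0) {
    stop_silac(
      paste0("bait '", bait_protein, "' absent or zero in run; run unusable"),
      "silac_bait_missing_error"
    )
  }
  setNames(run_records$spec_count / bait_count, run_records$protein)
}

#' Classify proteins of one replicate into interactor routes
#'
#' For one genotype x replicate pair of runs: a protein present in the VCP
#' run and absent from the IgG run (count at or below `igg_floor`,
#' default 0) is `EXCLUSIVE`; a protein present in both passes as
#' `RATIO_PASS` when its raw VCP/IgG count ratio is strictly greater than
#' `threshold` (default 3; a ratio of exactly 3 fails) and is `FAIL`
#' otherwise.  The bait itself is not classified.
#'
#' @param records Spectral-count records (both baits).
#' @param genotype,replicate Which paired runs to classify.
#' @param threshold Strict lower bound on the VCP/IgG count ratio.
#' @param igg_floor IgG count at or below which a protein still counts as
#'   not co-precipitated with IgG.
#' @param bait_protein Bait accession.
#' @return Tibble: `protein`, `genotype`, `replicate`, `vcp_count`,
#'   `igg_count`, `vcp_ratio` (bait-normalized VCP-run ratio),
#'   `igg_ratio` (raw VCP/IgG, `Inf` when IgG count is 0), `route`.
#' @export
call_replicate <- function(records, genotype, replicate, threshold = 3,
                           igg_floor = 0, bait_protein = "VCP") {
  vcp_run <- subset_run(records, "VCP", genotype, replicate)
  igg_run <- subset_run(records, "IGG", genotype, replicate)
  norm <- bait_normalize(vcp_run, bait_protein)
  vcp_run <- vcp_run[vcp_run$protein != bait_protein & vcp_run$spec_count > 0, ]
  igg_count <- igg_run$spec_count[match(vcp_run$protein, igg_run$protein)]
  igg_count[is.na(igg_count)] <- 0L
  ratio <- ifelse(igg_count > 0, vcp_run$spec_count / igg_count, Inf)
  route <- ifelse(
    igg_count <= igg_floor, "EXCLUSIVE",
    ifelse(ratio > threshold, "RATIO_PASS", "FAIL")
  )
  tibble(
    protein = vcp_run$protein, genotype = genotype,
    replicate = as.integer(replicate),
    vcp_count = vcp_run$spec_count, igg_count = as.integer(igg_count),
    vcp_ratio = unname(norm[vcp_run$protein]),
    igg_ratio = ratio, route = route
  )
}

#' Interactors concordant across replicates
#'
#' A protein is a genuine interactor for a genotype when it qualifies
#' (route `EXCLUSIVE` or `RATIO_PASS` — mixing routes across replicates is
#' allowed) in at least `n_required` replicates; the default requires
#' every replicate present in `calls`.  A protein absent from a
#' replicate's VCP run does not qualify in that replicate.
#'
#' @param calls Row-bound [call_replicate()] output for one genotype.
#' @param n_required Number of replicates a protein must qualify in
#'   (default: all replicates present in `calls`).
#' @return Sorted character vector of interactor accessions.
#' @export
concordant_interactors <- function(calls, n_required = NULL) {
  reps <- sort(unique(calls$replicate))
  if (is.null(n_required)) n_required <- length(reps)
  if (n_required > length(reps)) {
    stop_config("n_required exceeds the number of replicates present")
  }
  ok <- calls[calls$route != "FAIL", , drop = FALSE]
  n_ok <- table(ok$protein)
  sort(names(n_ok)[n_ok >= n_required])
}

#' Partition interactor sets across genotypes
#'
#' @param interactors_mut,interactors_ctrl Accession vectors.
#' @return List: `MUT_ONLY`, `CTRL_ONLY`, `COMMON` (sorted vectors).
#' @export
genotype_partition <- function(interactors_mut, interactors_ctrl) {
  list(
    MUT_ONLY = sort(setdiff(interactors_mut, interactors_ctrl)),
    CTRL_ONLY = sort(setdiff(interactors_ctrl, interactors_mut)),
    COMMON = sort(intersect(interactors_mut, interactors_ctrl))
  )
}

#' Genotype enrichment among shared interactors
#'
#' For each shared interactor, a two-tailed unpaired t test compares its
#' replicate-level bait-normalized VCP-run ratios between genotypes
#' (absence from a run is missing, not zero, for this magnitude
#' comparison).  `enriched_in` takes the sign of the mean difference when
#' p < `alpha`; no multiple-testing correction by default (a
#' Benjamini-Hochberg mode is available).
#'
#' @param records Spectral-count records.
#' @param common Accessions shared by both genotypes' interactor sets.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Classical equal-variance t test instead of Welch.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param bait_protein Bait accession.
#' @return Tibble: `protein`, `mean_ratio_mut`, `mean_ratio_ctrl`, `t`,
#'   `p_value`, `enriched_in` (`MUT`/`CTRL`/`NEITHER`; `NA` p for
#'   proteins with under two usable replicates in a genotype).
#' @export
common_enrichment <- function(records, common, alpha = 0.05,
                              var_equal = FALSE, p_adjust = c("none", "BH"),
                              bait_protein = "VCP") {
  p_adjust <- match.arg(p_adjust)
  if (!length(common)) {
    return(tibble(protein = character(0), mean_ratio_mut = numeric(0),
                  mean_ratio_ctrl = numeric(0), t = numeric(0),
                  p_value = numeric(0), enriched_in = character(0)))
  }
  runs <- unique(records[records$bait == "VCP", c("genotype", "replicate")])
  ratio_tab <- dplyr::bind_rows(lapply(seq_len(nrow(runs)), function(i) {
    run <- subset_run(records, "VCP", runs$genotype[i], runs$replicate[i])
    norm <- bait_normalize(run, bait_protein)
    tibble(protein = names(norm), genotype = runs$genotype[i],
           replicate = runs$replicate[i], ratio = unname(norm))
  }))
  res <- lapply(sort(common), function(p) {
    mut <- ratio_tab$ratio[ratio_tab$protein == p & ratio_tab$genotype == "MUT"]
    ctrl <- ratio_tab$ratio[ratio_tab$protein == p & ratio_tab$genotype == "CTRL"]
    if (length(mut) < 2 || length(ctrl) < 2) {
      return(tibble(protein = p, mean_ratio_mut = mean(mut),
                    mean_ratio_ctrl = mean(ctrl), t = NA_real_,
                    p_value = NA_real_))
    }
    ht <- safe_t_test(mut, ctrl, paired = FALSE, var.equal = var_equal)
    tibble(protein = p, mean_ratio_mut = mean(mut),
           mean_ratio_ctrl = mean(ctrl), t = ht$statistic,
           p_value = ht$p.value)
  })
  out <- dplyr::bind_rows(res)
  p_use <- if (p_adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$enriched_in <- dplyr::case_when(
    is.na(p_use) | p_use >= alpha ~ "NEITHER",
    out$mean_ratio_mut > out$mean_ratio_ctrl ~ "MUT",
    TRUE ~ "CTRL"
  )
  out
}

#' Full interactome filtering pipeline
#'
#' Applies per-replicate route calling, replicate concordance, genotype
#' partitioning and shared-set enrichment in one pass.
#'
#' @param records Spectral-count records covering both genotypes.
#' @param threshold VCP/IgG ratio threshold (strict, default 3).
#' @param alpha Enrichment significance level.
#' @param igg_floor IgG count floor for exclusivity (default 0).
#' @param n_required Replicates required for concordance (default all).
#' @param var_equal,p_adjust Passed to [common_enrichment()].
#' @param bait_protein Bait accession.
#' @return Object of class `interactome_result`: list with `calls`,
#'   `interactors` (per genotype), `partition`, `enrichment`, `summary`
#'   (named counts).
#' @export
#' @examples
#' sim <- simulate_ip(ip_sim_config(n_true_interactors = 30, n_background = 10,
#'                                  seed = 3))
#' res <- interactome_pipeline(sim$records)
#' res$summary
interactome_pipeline <- function(records, threshold = 3, alpha = 0.05,
                                 igg_floor = 0, n_required = NULL,
                                 var_equal = FALSE, p_adjust = "none",
                                 bait_protein = "VCP") {
  interactors <- list()
  all_calls <- list()
  for (g in GENOTYPES) {
    reps <- sort(unique(records$replicate[records$genotype == g & records$bait == "VCP"]))
    calls <- dplyr::bind_rows(lapply(reps, function(r) {
      call_replicate(records, g, r, threshold = threshold,
                     igg_floor = igg_floor, bait_protein = bait_protein)
    }))
    all_calls[[g]] <- calls
    interactors[[g]] <- concordant_interactors(calls, n_required)
  }
  part <- genotype_partition(interactors$MUT, interactors$CTRL)
  enrich <- common_enrichment(records, part$COMMON, alpha = alpha,
                              var_equal = var_equal, p_adjust = p_adjust,
                              bait_protein = bait_protein)
  summary <- c(
    n_interactors_total = length(union(interactors$MUT, interactors$CTRL)),
    n_mut_only = length(part$MUT_ONLY),
    n_ctrl_only = length(part$CTRL_ONLY),
    n_common = length(part$COMMON),
    n_enriched_mut = sum(enrich$enriched_in == "MUT"),
    n_enriched_ctrl = sum(enrich$enriched_in == "CTRL")
  )
  structure(
    list(calls = dplyr::bind_rows(all_calls), interactors = interactors,
         partition = part, enrichment = enrich, summary = summary,
         threshold = threshold, alpha = alpha),
    class = "interactome_result"
  )
}

#' @export
print.interactome_result <- function(x, ...) {
  cat("IP interactome filtering (VCP/IgG ratio >", x$threshold, ", all replicates)\n")
  s <- x$summary
  cat(sprintf("  interactors total: %d (MUT-only %d, CTRL-only %d, common %d)\n",
              s[["n_interactors_total"]], s[["n_mut_only"]],
              s[["n_ctrl_only"]], s[["n_common"]]))
  cat(sprintf("  enriched at alpha = %g: MUT %d, CTRL %d\n", x$alpha,
              s[["n_enriched_mut"]], s[["n_enriched_ctrl"]]))
  invisible(x)
}
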