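# Protein turnover ratios anchored at the end of the pulse
#
# Peptide heavy areas are rolled up to proteins by the arithmetic mean over
# labeled peptides (singletons included).  For each protein and genotype,
# the heavy ratio at chase time t is the rollup at t over the rollup at the
# chase start (t = 0, day 30 in vitro).  Filtering rules: a protein needs a
# chase-start rollup plus at least one later time point, and only ratios
# below 1 are retained.  Persistence compares the retained ratios between
# mutant and control genotypes: a protein persists at t when its mutant
# ratio strictly exceeds the control ratio.

# mean heavy area over labeled peptides for every protein/genotype/time
rollup_table <- function(records) {
  lab <- records[records$heavy_area > 0, , drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(lab, .data$protein, .data$genotype, .data$chase_time),
    heavy_mean = mean(.data$heavy_area),
    n_peptides = dplyr::n(),
    .groups = "drop"
  )
}

#' Roll peptide heavy areas up to one protein value
#'
#' Arithmetic mean of `heavy_area` over all labeled peptide observations
#' (heavy area > 0, singletons included) of a protein at one chase time in
#' one genotype.
#'
#' @param records Peptide records.
#' @param protein,chase_time,genotype Selection of the rollup cell.
#' @return The mean heavy area, or `NA_real_` when no labeled peptide
#'   matches (absence, never zero).
#' @export
#' @examples
#' r <- data.frame(peptide = c("AK", "BK", "CK"), protein = "P1",
#'                 heavy_area = c(10, 20, 30), light_area = 1,
#'                 chase_time = 0, genotype = "CTRL", replicate = 1L)
#' rollup_protein_heavy(r, "P1", 0, "CTRL")  # 20
rollup_protein_heavy <- function(records, protein, chase_time, genotype) {
  hit <- records$protein == protein &
    records$chase_time == chase_time &
    records$genotype == genotype &
    records$heavy_area > 0
  if (!any(hit)) return(NA_real_)
  mean(records$heavy_area[hit])
}

#' Day-30-anchored turnover profiles
#'
#' Builds per protein x genotype heavy-ratio profiles: the anchor is the
#' rollup at chase time 0; `ratio = rollup(t) / anchor` for every later
#' time with data.  A protein-genotype needs the anchor plus at least one
#' additional time point; individual ratios >= 1 are dropped, and the
#' protein-genotype is dropped entirely when no ratio survives.
#'
#' @param records Peptide records containing chase time 0.
#' @return Tibble of class `turnover_profiles` with columns `protein`,
#'   `genotype`, `chase_time` (> 0), `anchor_heavy`, `ratio`,
#'   `n_peptides` (contributing at `chase_time`), `n_peptides_anchor`.
#' @export
turnover_profiles <- function(records) {
  if (!any(records$chase_time == 0)) {
    stop_validation("records contain no chase_time-0 (anchor) observations")
  }
  roll <- rollup_table(records)
  anchor <- roll[roll$chase_time == 0, c("protein", "genotype", "heavy_mean", "n_peptides")]
  names(anchor)[3:4] <- c("anchor_heavy", "n_peptides_anchor")
  later <- roll[roll$chase_time > 0, , drop = FALSE]
  prof <- dplyr::inner_join(later, anchor, by = c("protein", "genotype"))
  prof$ratio <- prof$heavy_mean / prof$anchor_heavy
  prof <- prof[prof$ratio < 1, , drop = FALSE]
  prof <- prof[order(prof$protein, prof$genotype, prof$chase_time), ]
  out <- tibble(
    protein = prof$protein, genotype = prof$genotype,
    chase_time = prof$chase_time, anchor_heavy = prof$anchor_heavy,
    ratio = prof$ratio, n_peptides = prof$n_peptides,
    n_peptides_anchor = prof$n_peptides_anchor
  )
  class(out) <- c("turnover_profiles", class(out))
  out
}

#' Proteins quantified in both genotypes at a chase time
#'
#' @param profiles A [turnover_profiles()] tibble holding both genotypes.
#' @param chase_time Chase time (days, > 0).
#' @return Sorted character vector of accessions carrying a retained ratio
#'   at `chase_time` in both genotypes.
#' @export
common_proteins <- function(profiles, chase_time) {
  at_t <- profiles[profiles$chase_time == chase_time, , drop = FALSE]
  sort(intersect(
    at_t$protein[at_t$genotype == "MUT"],
    at_t$protein[at_t$genotype == "CTRL"]
  ))
}

#' Persisting-protein calls across genotypes
#'
#' A common protein persists at chase time t when its mutant heavy ratio
#' strictly exceeds the control ratio ("more labeled"; ties do not count).
#' Reports per-time calls and persistence fractions, the cross-time Venn
#' partition of persisting proteins, and the set persisting at every
#' requested time.
#'
#' @param profiles A [turnover_profiles()] tibble holding both genotypes.
#' @param chase_times Times to examine (default: all times in `profiles`).
#' @return Object of class `persistence_calls`: list with
#'   `calls` (protein x time tibble: mut_ratio, ctrl_ratio, common,
#'   persists), `fractions` (per time: n_common, n_persisting, fraction),
#'   `venn` (membership pattern of persisting times -> protein count),
#'   `all_times` (per protein: common_all, persists_all), and
#'   `chase_times`.
#' @export
persistence_calls <- function(profiles, chase_times = NULL) {
  if (is.null(chase_times)) chase_times <- sort(unique(profiles$chase_time))
  chase_times <- sort(chase_times)
  wide <- tidyr::pivot_wider(
    profiles[profiles$chase_time %in% chase_times,
             c("protein", "genotype", "chase_time", "ratio")],
    names_from = "genotype", values_from = "ratio"
  )
  for (g in c("MUT", "CTRL")) if (is.null(wide[[g]])) wide[[g]] <- NA_real_
  calls <- tibble(
    protein = wide$protein, chase_time = wide$chase_time,
    mut_ratio = wide$MUT, ctrl_ratio = wide$CTRL
  )
  calls$common <- !is.na(calls$mut_ratio) & !is.na(calls$ctrl_ratio)
  calls$persists <- calls$common & calls$mut_ratio > calls$ctrl_ratio
  calls <- calls[order(calls$protein, calls$chase_time), ]
  if (!any(calls$common)) {
    warn("no proteins are common to both genotypes at the requested times")
  }

  fractions <- dplyr::bind_rows(lapply(chase_times, function(t) {
    at_t <- calls[calls$chase_time == t & calls$common, , drop = FALSE]
    tibble(
      chase_time = t, n_common = nrow(at_t),
      n_persisting = sum(at_t$persists),
      fraction = if (nrow(at_t)) mean(at_t$persists) else NA_real_
    )
  }))

  pers <- calls[calls$persists, , drop = FALSE]
  venn <- if (nrow(pers)) {
    pat <- vapply(
      split(pers$chase_time, pers$protein),
      function(t) paste(sort(t), collapse = "&"), character(1)
    )
    cnt <- table(pat)
    tibble(times = names(cnt), n_proteins = as.integer(cnt))
  } else {
    tibble(times = character(0), n_proteins = integer(0))
  }

  per_prot <- split(calls, calls$protein)
  all_times <- dplyr::bind_rows(lapply(per_prot, function(d) {
    common_all <- all(chase_times %in% d$chase_time[d$common])
    tibble(
      protein = d$protein[1],
      common_all = common_all,
      persists_all = common_all && all(d$persists[d$chase_time %in% chase_times])
    )
  }))

  structure(
    list(calls = calls, fractions = fractions, venn = venn,
         all_times = all_times, chase_times = chase_times),
    class = "persistence_calls"
  )
}

#' @export
print.persistence_calls <- function(x, ...) {
  cat("Persistence calls across", length(x$chase_times), "chase times\n")
  print(x$fractions)
  n_all <- sum(x$all_times$persists_all)
  cat(sprintf("Proteins persisting at every examined time: %d\n", n_all))
  invisible(x)
}

# paired/unpaired t tests that tolerate degenerate ((near-)constant) inputs,
# which arise from noiseless data: zero spread with zero mean difference is
# reported as p = 1, zero spread with a nonzero difference as p = 0
safe_t_test <- function(x, y, paired = FALSE, var.equal = FALSE) {
  degenerate_result <- function() {
    d <- mean(x) - mean(y)
    list(statistic = if (d == 0) 0 else sign(d) * Inf,
         p.value = if (d == 0) 1 else 0)
  }
  degenerate <- if (paired) stats::sd(x - y) == 0 else
    (stats::sd(x) == 0 && stats::sd(y) == 0)
  if (degenerate) return(degenerate_result())
  ht <- tryCatch(t.test(x, y, paired = paired, var.equal = var.equal),
                 error = function(e) NULL)   # "data are essentially constant"
  if (is.null(ht)) return(degenerate_result())
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Paired comparison of mean normalized heavy intensity
#'
#' Over the proteins common to both genotypes at one chase time, runs a
#' two-tailed paired t test of the mutant versus control heavy ratios
#' (values normalized to the respective chase-start value), pairing by
#' protein.
#'
#' @param profiles A [turnover_profiles()] tibble holding both genotypes.
#' @param chase_time Chase time (days, > 0).
#' @return List: `chase_time`, `n` (pairs), `mean_mut`, `mean_ctrl`,
#'   `t`, `p_paired`.
#' @export
compare_mean_normalized_intensity <- function(profiles, chase_time) {
  common <- common_proteins(profiles, chase_time)
  if (length(common) < 2) {
    stop_insufficient("need >= 2 common proteins for the paired comparison")
  }
  at_t <- profiles[profiles$chase_time == chase_time & profiles$protein %in% common, ]
  mut <- at_t$ratio[at_t$genotype == "MUT"][match(common, at_t$protein[at_t$genotype == "MUT"])]
  ctrl <- at_t$ratio[at_t$genotype == "CTRL"][match(common, at_t$protein[at_t$genotype == "CTRL"])]
  ht <- safe_t_test(mut, ctrl, paired = TRUE)
  list(
    chase_time = chase_time, n = length(common),
    mean_mut = mean(mut), mean_ctrl = mean(ctrl),
    t = ht$statistic, p_paired = ht$p.value
  )
}

#' Peptide-level self-normalized comparison for one protein
#'
#' For each peptide of `protein` observed (heavy) at both chase time 0 and
#' `chase_time` within a genotype, computes `heavy(t) / heavy(0)` (the
#' peptide's own chase-start value as denominator, so peptide ionization
#' efficiency cancels), then compares the mutant and control peptide
#' values with a two-tailed unpaired t test.
#'
#' @param records Peptide records.
#' @param protein Protein accession.
#' @param chase_time Chase time (days, > 0).
#' @param var_equal Use the classical equal-variance t test instead of
#'   Welch's (default `FALSE`).
#' @return List: `values` (tibble peptide/genotype/value), `n_mut`,
#'   `n_ctrl`, `mean_mut`, `mean_ctrl`, `t`, `p_unpaired`.
#' @export
peptide_level_comparison <- function(records, protein, chase_time,
                                     var_equal = FALSE) {
  sel <- records[records$protein == protein &
                   records$chase_time %in% c(0, chase_time) &
                   records$heavy_area > 0, , drop = FALSE]
  # average across replicates first so each peptide contributes one value
  per_pep <- dplyr::summarise(
    dplyr::group_by(sel, .data$peptide, .data$genotype, .data$chase_time),
    heavy = mean(.data$heavy_area), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(per_pep, names_from = "chase_time",
                             values_from = "heavy", names_prefix = "t")
  t0 <- paste0("t", 0); tt <- paste0("t", chase_time)
  if (is.null(wide[[t0]]) || is.null(wide[[tt]])) {
    stop_insufficient("protein lacks matched peptides at both chase times")
  }
  wide <- wide[!is.na(wide[[t0]]) & !is.na(wide[[tt]]), , drop = FALSE]
  values <- tibble(
    peptide = wide$peptide, genotype = wide$genotype,
    value = wide[[tt]] / wide[[t0]]
  )
  mut <- values$value[values$genotype == "MUT"]
  ctrl <- values$value[values$genotype == "CTRL"]
  if (length(mut) < 2 || length(ctrl) < 2) {
    stop_insufficient("need >= 2 matched peptides per genotype")
  }
  ht <- safe_t_test(mut, ctrl, paired = FALSE, var.equal = var_equal)
  list(
    values = values, n_mut = length(mut), n_ctrl = length(ctrl),
    mean_mut = mean(mut), mean_ctrl = mean(ctrl),
    t = ht$statistic, p_unpaired = ht$p.value
  )
}

#' Median-of-ratios per-run normalization (optional)
#'
#' Scales every run (genotype x replicate x chase_time) by the median,
#' over peptides shared with the cross-run reference, of the ratio of the
#' peptide's total (heavy + light) area to its geometric-mean reference.
#' Off by default in the pipeline; provided for inputs where run-to-run
#' loading differences are suspected.
#'
#' @param records Peptide records.
#' @return Records with `heavy_area` and `light_area` rescaled per run.
#' @export
normalize_runs <- function(records) {
  records <- as_tibble(records)
  records$total <- records$heavy_area + records$light_area
  key <- paste(records$peptide, records$protein, sep = "\r")
  run <- paste(records$genotype, records$replicate, records$chase_time, sep = "\r")
  ref <- tapply(log(records$total), key, mean)        # log geometric mean
  lratio <- log(records$total) - ref[key]
  sf <- exp(tapply(lratio, run, median))
  scale <- unname(sf[run])
  records$heavy_area <- records$heavy_area / scale
  records$light_area <- records$light_area / scale
  records$total <- NULL
  records
}
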