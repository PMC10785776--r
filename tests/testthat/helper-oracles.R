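# Independent brute-force implementations of the turnover and interactome
# filtering rules, written as plain loops over data frames so they share no
# code with the package, plus random table generators for equivalence
# testing.

# -- turnover rules: anchor + >=1 later point, ratio < 1, strict persistence --

oracle_turnover_profiles <- function(records) {
  out <- data.frame(protein = character(0), genotype = character(0),
                    chase_time = numeric(0), ratio = numeric(0))
  for (p in unique(records$protein)) {
    for (g in c("MUT", "CTRL")) {
      sub <- records[records$protein == p & records$genotype == g &
                       records$heavy_area > 0, ]
      anchor_rows <- sub[sub$chase_time == 0, ]
      if (nrow(anchor_rows) == 0) next
      anchor <- mean(anchor_rows$heavy_area)
      for (t in sort(unique(sub$chase_time[sub$chase_time > 0]))) {
        r <- mean(sub$heavy_area[sub$chase_time == t]) / anchor
        if (r < 1) {
          out <- rbind(out, data.frame(protein = p, genotype = g,
                                       chase_time = t, ratio = r))
        }
      }
    }
  }
  out[order(out$protein, out$genotype, out$chase_time), , drop = FALSE]
}

oracle_persistence <- function(oracle_prof, times) {
  calls <- data.frame(protein = character(0), chase_time = numeric(0),
                      persists = logical(0))
  for (t in times) {
    at_t <- oracle_prof[oracle_prof$chase_time == t, ]
    mut <- at_t[at_t$genotype == "MUT", ]
    ctrl <- at_t[at_t$genotype == "CTRL", ]
    for (p in intersect(mut$protein, ctrl$protein)) {
      calls <- rbind(calls, data.frame(
        protein = p, chase_time = t,
        persists = mut$ratio[mut$protein == p] > ctrl$ratio[ctrl$protein == p]
      ))
    }
  }
  persists_all <- character(0)
  for (p in unique(calls$protein)) {
    sub <- calls[calls$protein == p, ]
    if (length(times) == nrow(sub) && all(sub$persists)) {
      persists_all <- c(persists_all, p)
    }
  }
  list(calls = calls[order(calls$protein, calls$chase_time), , drop = FALSE],
       persists_all = sort(persists_all))
}

# -- interactome rules: exclusivity, ratio > 3, all replicates, partition --

oracle_interactors <- function(records, genotype, threshold = 3) {
  reps <- sort(unique(records$replicate[records$genotype == genotype &
                                          records$bait == "VCP"]))
  passing <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    r <- reps[i]
    vcp <- records[records$bait == "VCP" & records$genotype == genotype &
                     records$replicate == r & records$spec_count > 0 &
                     records$protein != "VCP", ]
    igg <- records[records$bait == "IGG" & records$genotype == genotype &
                     records$replicate == r, ]
    ok <- character(0)
    for (j in seq_len(nrow(vcp))) {
      p <- vcp$protein[j]
      ic <- igg$spec_count[igg$protein == p]
      ic <- if (length(ic)) ic else 0
      if (ic == 0) {
        ok <- c(ok, p)                               # exclusive of IgG
      } else if (vcp$spec_count[j] / ic > threshold) {
        ok <- c(ok, p)                               # ratio route, strict
      }
    }
    passing[[i]] <- ok
  }
  sort(Reduce(intersect, passing))
}

oracle_interactome <- function(records, threshold = 3) {
  mut <- oracle_interactors(records, "MUT", threshold)
  ctrl <- oracle_interactors(records, "CTRL", threshold)
  list(
    mut = mut, ctrl = ctrl,
    MUT_ONLY = sort(setdiff(mut, ctrl)),
    CTRL_ONLY = sort(setdiff(ctrl, mut)),
    COMMON = sort(intersect(mut, ctrl))
  )
}

# -- random table generators -------------------------------------------------

# Small random peptide tables exercising the filter edge cases: missing
# anchors, ratios >= 1, times present in one genotype only.
random_peptide_table <- function(n_proteins = 10) {
  times <- c(0, 1, 5, 21)
  rows <- list()
  for (i in seq_len(n_proteins)) {
    p <- sprintf("P%02d", i)
    n_pep <- sample(1:3, 1)
    for (j in seq_len(n_pep)) {
      pep <- sprintf("%s_PEP%d", p, j)
      for (g in c("MUT", "CTRL")) {
        # each peptide observed at a random subset of times (anchor may be absent)
        t_obs <- times[runif(4) < 0.8]
        for (t in t_obs) {
          rows[[length(rows) + 1]] <- data.frame(
            peptide = pep, protein = p,
            heavy_area = round(runif(1, 0.5, 120), 3),  # ratios can exceed 1
            light_area = round(runif(1, 0, 100), 3),
            chase_time = t, genotype = g, replicate = 1L
          )
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  # guarantee at least one anchor so turnover_profiles' precondition holds
  if (!any(df$chase_time == 0)) df$chase_time[1] <- 0
  df
}

# Random spectral-count tables; ~25% of IgG-positive proteins are planted
# at a VCP/IgG ratio of exactly 3 to probe the strict boundary.
random_speccount_table <- function(n_proteins = 20, n_replicates = 3) {
  prots <- sprintf("Q%02d", seq_len(n_proteins))
  rows <- list()
  for (g in c("MUT", "CTRL")) {
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1]] <- data.frame(
        protein = "VCP", bait = "VCP", genotype = g, replicate = r,
        spec_count = sample(30:100, 1)
      )
      for (p in prots) {
        igg <- sample(0:4, 1)
        vcp <- if (igg > 0 && runif(1) < 0.25) 3L * igg else sample(0:15, 1)
        if (vcp > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            protein = p, bait = "VCP", genotype = g, replicate = r,
            spec_count = vcp
          )
        }
        if (igg > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            protein = p, bait = "IGG", genotype = g, replicate = r,
            spec_count = igg
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}
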