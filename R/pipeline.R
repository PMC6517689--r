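#' Step 1: homology counts for every cluster gene
#'
#' For each (cluster, member protein) pair, counts how many members of the
#' protein's family the organism carries in total (`copies_in_organism`,
#' including the gene itself) and how many of those sit inside any of the
#' organism's predicted clusters (`copies_in_clusters`). Counts are strictly
#' per organism: family members in other organisms never contribute.
#'
#' @param ds a validated `frigg_dataset` with families.
#' @return data.table with one row per cluster gene: `organism_id`,
#'   `cluster_id`, `protein_id`, `family_id`, `copies_in_organism`,
#'   `copies_in_clusters`.
#' @export
compute_homology_counts <- function(ds) {
  stopifnot(inherits(ds, "frigg_dataset"))
  if (is.null(ds$families)) {
    stop("dataset has no families; supply a family table or use ",
         "build_families_from_hits()", call. = FALSE)
  }
  members <- ds$clusters[, .(organism_id, cluster_id, protein_id)]
  if (nrow(members) == 0L) {
    return(data.table(organism_id = character(), cluster_id = character(),
                      protein_id = character(), family_id = character(),
                      copies_in_organism = integer(),
                      copies_in_clusters = integer()))
  }
  fam <- ds$families
  members <- merge(members, fam, by = c("organism_id", "protein_id"))

  per_org <- fam[, .(copies_in_organism = .N), by = .(family_id, organism_id)]
  clustered <- unique(ds$clusters[, .(organism_id, protein_id)])
  in_clust <- merge(fam, clustered, by = c("organism_id", "protein_id"))
  per_org_clust <- in_clust[, .(copies_in_clusters = .N),
                            by = .(family_id, organism_id)]

  out <- merge(members, per_org, by = c("family_id", "organism_id"))
  out <- merge(out, per_org_clust, by = c("family_id", "organism_id"),
               all.x = TRUE)
  out[is.na(copies_in_clusters), copies_in_clusters := 0L]
  out <- out[, .(organism_id, cluster_id, protein_id, family_id,
                 copies_in_organism, copies_in_clusters)]
  setorder(out, organism_id, cluster_id, protein_id)
  out[]
}

#' Family-size exemption cutoff for the alternative pattern
#'
#' The cutoff scales with dataset size: `x_input * n_organisms`. A family is
#' exempt from the copy-count constraint (and ineligible as a resistance
#' gene) iff its dataset-wide member count strictly exceeds this value.
#' With 51 organisms the recommended multipliers 2 and 3 give cutoffs of
#' 102 and 153 proteins.
#'
#' @param n_organisms number of organisms in the dataset (>= 1).
#' @param x_input positive multiplier (user input).
#' @return The cutoff, `x_input * n_organisms`.
#' @export
family_size_cutoff <- function(n_organisms, x_input) {
  if (!is.numeric(n_organisms) || length(n_organisms) != 1L ||
      n_organisms < 1) {
    stop("n_organisms must be a positive number", call. = FALSE)
  }
  if (!is.numeric(x_input) || length(x_input) != 1L || x_input <= 0) {
    stop("x_input must be positive", call. = FALSE)
  }
  x_input * n_organisms
}

# shared step-2 scanner; exempt_fams is a character vector of family ids
# whose members are unconstrained and ineligible as resistance genes
.select_clusters <- function(counts, ds, exempt_fams, pattern_label) {
  counts <- as.data.table(counts)
  empty <- data.table(cluster_id = character(), organism_id = character(),
                      resistance_protein_id = character(),
                      resistance_family_id = character(),
                      target_protein_ids = character(),
                      exempt_protein_ids = character(),
                      pattern = character())
  if (nrow(counts) == 0L) return(empty)
  cc <- copy(counts)
  cc[, exempt := family_id %chin% exempt_fams]
  # resistance-gene pattern: exactly two copies in the organism, and the
  # extra copy outside every predicted cluster (so only this one inside)
  cc[, is_res := !exempt & copies_in_organism == 2L & copies_in_clusters == 1L]
  cc[, is_single := !exempt & copies_in_organism == 1L]
  sel <- cc[, .(organism_id = organism_id[1L],
                n_res = sum(is_res),
                ok = sum(is_res) == 1L && all(exempt | is_res | is_single)),
            by = cluster_id][ok == TRUE]
  if (nrow(sel) == 0L) return(empty)
  res <- cc[is_res == TRUE][cluster_id %chin% sel$cluster_id]

  # putative targets: the resistance family's same-organism members that sit
  # outside all predicted clusters
  clustered <- unique(ds$clusters[, .(organism_id, protein_id)])
  fam <- ds$families
  free <- fam[!clustered, on = c("organism_id", "protein_id")]
  targets <- merge(res[, .(cluster_id, organism_id,
                           family_id)],
                   free, by = c("family_id", "organism_id"),
                   allow.cartesian = TRUE)
  tgt <- targets[, .(target_protein_ids = paste(sort(protein_id),
                                                collapse = ";")),
                 by = cluster_id]
  ex <- cc[exempt == TRUE & cluster_id %chin% sel$cluster_id,
           .(exempt_protein_ids = paste(sort(protein_id), collapse = ";")),
           by = cluster_id]
  out <- res[, .(cluster_id, organism_id, resistance_protein_id = protein_id,
                 resistance_family_id = family_id)]
  out <- merge(out, tgt, by = "cluster_id", all.x = TRUE)
  out <- merge(out, ex, by = "cluster_id", all.x = TRUE)
  out[is.na(target_protein_ids), target_protein_ids := ""]
  out[is.na(exempt_protein_ids), exempt_protein_ids := ""]
  out[, pattern := pattern_label]
  setorder(out, organism_id, cluster_id)
  out[]
}

#' Step 2, strict pattern: select candidate clusters
#'
#' A cluster is selected iff exactly one member has exactly one extra
#' same-organism family copy and that extra copy lies outside all predicted
#' clusters, while every other member is single-copy in the organism. The
#' copy-bearing member is the putative resistance gene; its extra-cluster
#' copy is the putative target.
#'
#' @param counts homology counts from [compute_homology_counts()].
#' @param ds the dataset the counts were computed from.
#' @return Candidate table: one row per selected cluster with columns
#'   `cluster_id`, `organism_id`, `resistance_protein_id`,
#'   `resistance_family_id`, `target_protein_ids` (semicolon-joined),
#'   `exempt_protein_ids` (always empty under strict), `pattern`.
#' @export
select_clusters_strict <- function(counts, ds) {
  .select_clusters(counts, ds, character(), "strict")
}

#' Step 2, alternative pattern: select with large-family exemption
#'
#' Members whose family's dataset-wide size strictly exceeds
#' [family_size_cutoff()] are exempt: their copy counts are ignored and
#' they cannot be designated resistance genes. The strict rule then applies
#' to the remaining members.
#'
#' @inheritParams select_clusters_strict
#' @param x_input positive family-size multiplier.
#' @return Candidate table as in [select_clusters_strict()], with
#'   `exempt_protein_ids` listing the cluster's exempted members.
#' @export
select_clusters_alternative <- function(counts, ds, x_input) {
  cutoff <- family_size_cutoff(nrow(ds$organisms), x_input)
  fam_sizes <- ds$families[, .N, by = family_id]
  exempt_fams <- fam_sizes[N > cutoff, family_id]
  .select_clusters(counts, ds, exempt_fams, "alternative")
}

#' Step 3: recurrence filter (optional)
#'
#' Retains a candidate iff its resistance family is the resistance family
#' of at least two distinct candidate clusters, mitigating single-cluster
#' prediction errors. By default recurrence is counted over clusters; set
#' `distinct_organisms = TRUE` to require the clusters to come from
#' different organisms.
#'
#' @param candidates candidate table from step 2.
#' @param distinct_organisms require recurrence across organisms?
#' @return Filtered candidate table.
#' @export
filter_recurrent <- function(candidates, distinct_organisms = FALSE) {
  cand <- as.data.table(candidates)
  if (nrow(cand) == 0L) return(cand)
  rec <- if (distinct_organisms) {
    cand[, .(n = uniqueN(organism_id)), by = resistance_family_id]
  } else {
    cand[, .(n = uniqueN(cluster_id)), by = resistance_family_id]
  }
  keep <- rec[n >= 2L, resistance_family_id]
  cand[resistance_family_id %chin% keep]
}

#' Step 4: essentiality filter
#'
#' Retains a candidate iff the fraction of all dataset organisms carrying at
#' least one member of its resistance family (anywhere in the genome,
#' cluster-resident copies included) is at least `essential_pct` percent.
#' Conserved presence across (nearly) all genomes is the operational proxy
#' for the target being essential.
#'
#' @param candidates candidate table.
#' @param ds the dataset.
#' @param essential_pct threshold in `[0, 100]`.
#' @return Filtered candidate table.
#' @export
filter_essential <- function(candidates, ds, essential_pct) {
  stopifnot(essential_pct >= 0, essential_pct <= 100)
  cand <- as.data.table(candidates)
  if (nrow(cand) == 0L) return(cand)
  n_total <- nrow(ds$organisms)
  pres <- ds$families[, .(n_org = uniqueN(organism_id)), by = family_id]
  keep <- pres[n_org / n_total >= essential_pct / 100, family_id]
  cand[resistance_family_id %chin% keep]
}

#' Step 5: single-copy-majority filter (optional)
#'
#' Removes a candidate iff strictly more than `majority_pct` percent of
#' genomes carry two or more members of its resistance family: a true target
#' should be a single essential gene in most organisms. The denominator is
#' all organisms in the dataset; set `within_family = TRUE` to restrict it
#' to organisms that possess the family at all.
#'
#' @param candidates candidate table.
#' @param ds the dataset.
#' @param majority_pct threshold in `(0, 100]`, default 50.
#' @param within_family use family-bearing organisms as denominator?
#' @return Filtered candidate table.
#' @export
filter_single_copy <- function(candidates, ds, majority_pct = 50,
                               within_family = FALSE) {
  stopifnot(majority_pct > 0, majority_pct <= 100)
  cand <- as.data.table(candidates)
  if (nrow(cand) == 0L) return(cand)
  per_org <- ds$families[, .N, by = .(family_id, organism_id)]
  stats <- per_org[, .(n_multi = sum(N >= 2L), n_with = .N), by = family_id]
  stats[, denom := if (within_family) n_with else nrow(ds$organisms)]
  drop <- stats[n_multi / denom > majority_pct / 100, family_id]
  cand[!resistance_family_id %chin% drop]
}

#' Run the full pipeline under one configuration
#'
#' Applies steps 1 through 5 as configured and records the candidate set
#' after every applied step, together with per-step cluster and
#' resistance-family counts. Candidate sets are nested: each step only
#' removes candidates.
#'
#' @param ds a validated `frigg_dataset` with families.
#' @param config a [frigg_config()].
#' @return A `frigg_run`: list with elements `config`, `counts` (the step-1
#'   table), `steps` (named list of candidate tables: `step2`, `step3` when
#'   applied, `step4`, `step5` when applied), `summary` (data.table of
#'   per-step cluster and family counts) and `signature`.
#' @export
run_pipeline <- function(ds, config = frigg_config()) {
  stopifnot(inherits(ds, "frigg_dataset"), inherits(config, "frigg_config"))
  counts <- compute_homology_counts(ds)
  steps <- list()
  steps$step2 <- if (config$pattern == "strict") {
    select_clusters_strict(counts, ds)
  } else {
    select_clusters_alternative(counts, ds, config$x_input)
  }
  current <- steps$step2
  if (!config$skip_step3) {
    current <- filter_recurrent(current, config$step3_distinct_organisms)
    steps$step3 <- current
  }
  current <- filter_essential(current, ds, config$essential_pct)
  steps$step4 <- current
  if (config$apply_step5) {
    current <- filter_single_copy(current, ds, config$majority_pct,
                                  config$step5_within_family)
    steps$step5 <- current
  }
  summary <- rbindlist(lapply(names(steps), function(nm) {
    data.table(step = nm, n_clusters = nrow(steps[[nm]]),
               n_families = uniqueN(steps[[nm]]$resistance_family_id))
  }))
  structure(list(config = config, counts = counts, steps = steps,
                 summary = summary, signature = dataset_signature(ds)),
            class = "frigg_run")
}

#' @export
print.frigg_run <- function(x, ...) {
  cat("frigg run [", config_label(x$config), "]\n", sep = "")
  print(x$summary)
  invisible(x)
}

# final candidate table of a run (last applied step)
final_candidates <- function(run) {
  stopifnot(inherits(run, "frigg_run"))
  run$steps[[length(run$steps)]]
}

#' Run the standard 12-setting grid
#'
#' Crosses the three selection patterns (strict, alternative with each
#' multiplier in `x_inputs`) with step 3 applied/skipped and with each
#' essentiality threshold in `essential_pcts`; step 5 is always applied.
#' With the defaults this is the 3 x 2 x 2 = 12-setting grid.
#'
#' @param ds a validated `frigg_dataset`.
#' @param x_inputs multipliers for the alternative pattern (default 2 and 3).
#' @param essential_pcts step-4 thresholds (default 90 and 98).
#' @param majority_pct step-5 threshold.
#' @return Named list of `frigg_run` objects, names from pattern, step-3
#'   status and essentiality threshold (e.g. `"alt2|step3*|98"`).
#' @export
run_grid <- function(ds, x_inputs = c(2, 3), essential_pcts = c(90, 98),
                     majority_pct = 50) {
  patterns <- c(list(list(pattern = "strict", x = NA_real_)),
                lapply(x_inputs, function(x)
                  list(pattern = "alternative", x = x)))
  runs <- list()
  for (p in patterns) for (skip3 in c(FALSE, TRUE)) for (ep in essential_pcts) {
    cfg <- frigg_config(pattern = p$pattern,
                        x_input = if (is.na(p$x)) 2 else p$x,
                        skip_step3 = skip3, essential_pct = ep,
                        apply_step5 = TRUE, majority_pct = majority_pct)
    runs[[config_label(cfg)]] <- run_pipeline(ds, cfg)
  }
  runs
}

#' Combine the outputs of several runs
#'
#' Takes the union of final-step resistance families across runs and
#' reports, per family, which settings recovered it (a 0/1 presence
#' matrix), plus the families found in every run.
#'
#' @param runs list of `frigg_run` objects over the same dataset.
#' @return List with `families` (character vector, the union),
#'   `presence` (data.table: `family_id` + one 0/1 column per run) and
#'   `in_all_runs` (families recovered by every setting).
#' @export
combine_runs <- function(runs) {
  stopifnot(length(runs) >= 1L, all(vapply(runs, inherits, logical(1),
                                           "frigg_run")))
  sigs <- lapply(runs, `[[`, "signature")
  if (!all(vapply(sigs, identical, logical(1), sigs[[1L]]))) {
    stop("runs come from different datasets", call. = FALSE)
  }
  if (is.null(names(runs)) || anyNA(names(runs)) || any(names(runs) == "")) {
    names(runs) <- vapply(runs, function(r) config_label(r$config),
                          character(1))
  }
  fam_sets <- lapply(runs, function(r)
    sort(unique(final_candidates(r)$resistance_family_id)))
  all_fams <- sort(unique(unlist(fam_sets)))
  presence <- data.table(family_id = all_fams)
  for (nm in names(runs)) {
    presence[, (nm) := as.integer(family_id %chin% fam_sets[[nm]])]
  }
  in_all <- if (length(all_fams)) {
    all_fams[rowSums(as.matrix(presence[, -1L])) == length(runs)]
  } else character()
  list(families = all_fams, presence = presence, in_all_runs = in_all)
}
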