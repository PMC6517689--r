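#' Context labels for curation and FASTA export
#'
#' Labels each protein relative to a run's final candidate set:
#' `StrictClust` for a designated resistance gene of a final candidate
#' cluster; `Clust` for any other protein residing in a predicted cluster;
#' `outsideSC` for a protein outside all clusters that is a same-organism
#' family member of a designated resistance gene (the putative target);
#' `0` otherwise. The `outsideSC` scope is per organism: a family member in
#' an organism with no candidate is labelled `0`.
#'
#' @param ds a `frigg_dataset`.
#' @param run a `frigg_run`.
#' @param proteins optional data.table with `organism_id`, `protein_id` to
#'   restrict labelling; defaults to the whole catalog.
#' @return data.table with columns `organism_id`, `protein_id`, `label`.
#' @export
context_labels <- function(ds, run, proteins = NULL) {
  stopifnot(inherits(ds, "frigg_dataset"), inherits(run, "frigg_run"))
  prot <- if (is.null(proteins)) {
    ds$proteins[, .(organism_id, protein_id)]
  } else {
    as.data.table(proteins)[, .(organism_id, protein_id)]
  }
  unknown <- prot[!ds$proteins, on = c("organism_id", "protein_id")]
  if (nrow(unknown)) {
    stop("protein(s) not in dataset: ",
         paste(paste(unknown$organism_id, unknown$protein_id, sep = "/"),
               collapse = ", "), call. = FALSE)
  }
  final <- final_candidates(run)
  res_keys <- final[, paste(organism_id, resistance_protein_id, sep = "~")]
  clustered <- unique(ds$clusters[, .(organism_id, protein_id)])
  # same-organism members of a final candidate's resistance family
  fam_scope <- merge(ds$families,
                     unique(final[, .(organism_id,
                                      family_id = resistance_family_id)]),
                     by = c("organism_id", "family_id"))
  scope_keys <- fam_scope[, paste(organism_id, protein_id, sep = "~")]

  out <- copy(prot)
  out[, key := paste(organism_id, protein_id, sep = "~")]
  out[, in_cluster := FALSE]
  out[clustered, in_cluster := TRUE, on = c("organism_id", "protein_id")]
  out[, label := "0"]
  out[in_cluster == TRUE, label := "Clust"]
  out[in_cluster == FALSE & key %chin% scope_keys, label := "outsideSC"]
  out[key %chin% res_keys, label := "StrictClust"]
  out[, .(organism_id, protein_id, label)]
}

#' Context label for a single protein
#'
#' Scalar convenience wrapper around [context_labels()].
#'
#' @param organism_id,protein_id the protein's key.
#' @param run a `frigg_run`.
#' @param ds a `frigg_dataset`.
#' @return One of `"StrictClust"`, `"Clust"`, `"outsideSC"`, `"0"`.
#' @export
label_protein_context <- function(organism_id, protein_id, run, ds) {
  context_labels(ds, run,
                 data.table(organism_id = organism_id,
                            protein_id = protein_id))$label
}

#' Summarize a 12-setting grid as a step-count table
#'
#' Produces the standard summary layout: rows are pipeline steps (2, 3, 4,
#' 4*, 5, 5*, where * marks step 3 skipped), columns are the selection
#' settings (strict, alternative per multiplier), and cells count distinct
#' resistance families. Step-4/5 cells pair the two essentiality thresholds
#' as `"N/M"`.
#'
#' @param runs named list of `frigg_run`s from [run_grid()].
#' @return List with `table` (the wide character table) and `long` (tidy
#'   per-run counts: setting, step3 status, essential_pct, step, n_clusters,
#'   n_families).
#' @export
summarize_run_grid <- function(runs) {
  stopifnot(length(runs) >= 1L, all(vapply(runs, inherits, logical(1),
                                           "frigg_run")))
  long <- rbindlist(lapply(runs, function(r) {
    cfg <- r$config
    s <- copy(r$summary)
    s[, `:=`(setting = if (cfg$pattern == "strict") "strict" else
               sprintf("alt%g", cfg$x_input),
             skip_step3 = cfg$skip_step3,
             essential_pct = cfg$essential_pct)]
    s
  }))
  settings <- unique(long$setting)
  eps <- sort(unique(long$essential_pct))
  if (length(eps) != 2L) {
    stop("expected exactly two essentiality thresholds in the grid, got: ",
         paste(eps, collapse = ", "), call. = FALSE)
  }

  cell <- function(setting_, step_, skip3_, ep_) {
    v <- long[setting == setting_ & step == step_ & skip_step3 == skip3_ &
                essential_pct == ep_, n_families]
    if (length(v) == 0L) {
      stop(sprintf("grid is missing setting %s / %s / essential_pct=%g",
                   setting_, if (skip3_) "step3 skipped" else "step3",
                   ep_), call. = FALSE)
    }
    v[1L]
  }
  rows <- list(
    c(step = "2", vapply(settings, function(s) {
      # step-2 count is threshold-independent; take it from any run
      as.character(cell(s, "step2", FALSE, eps[1L]))
    }, character(1))),
    c(step = "3", vapply(settings, function(s)
      as.character(cell(s, "step3", FALSE, eps[1L])), character(1))),
    c(step = "4", vapply(settings, function(s)
      sprintf("%d/%d", cell(s, "step4", FALSE, eps[1L]),
              cell(s, "step4", FALSE, eps[2L])), character(1))),
    c(step = "4*", vapply(settings, function(s)
      sprintf("%d/%d", cell(s, "step4", TRUE, eps[1L]),
              cell(s, "step4", TRUE, eps[2L])), character(1))),
    c(step = "5", vapply(settings, function(s)
      sprintf("%d/%d", cell(s, "step5", FALSE, eps[1L]),
              cell(s, "step5", FALSE, eps[2L])), character(1))),
    c(step = "5*", vapply(settings, function(s)
      sprintf("%d/%d", cell(s, "step5", TRUE, eps[1L]),
              cell(s, "step5", TRUE, eps[2L])), character(1)))
  )
  wide <- rbindlist(lapply(rows, function(r) as.list(r)))
  list(table = wide, long = long[])
}

#' Signed percent change, rounded half away from zero
#'
#' `100 * (after - before) / before`, rounded to the nearest integer with
#' halves moving away from zero (so 48.5 -> 49 and -48.5 -> -49; base R
#' `round()` would give 48 on both magnitudes).
#'
#' @param count_before baseline count, strictly positive.
#' @param count_after new count.
#' @return Signed integer percent.
#' @export
percent_change <- function(count_before, count_after) {
  if (!is.numeric(count_before) || any(count_before <= 0)) {
    stop("count_before must be strictly positive", call. = FALSE)
  }
  .round_half_away(100 * (count_after - count_before) / count_before)
}

#' Integer percentage of a total
#'
#' @param part numerator, `0 <= part <= total`.
#' @param total denominator, strictly positive.
#' @return Rounded integer percent (half away from zero).
#' @export
share_of_total <- function(part, total) {
  if (!is.numeric(total) || any(total <= 0)) {
    stop("total must be strictly positive", call. = FALSE)
  }
  if (any(part < 0) || any(part > total)) {
    stop("part must lie in [0, total]", call. = FALSE)
  }
  .round_half_away(100 * part / total)
}

.round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Export curation tables for a run
#'
#' Writes the per-step candidate tables, the label table for all proteins in
#' final candidate families, and one annotated FASTA per final resistance
#' family (when sequences are available). Also emits a one-hot label/section
#' matrix per family, usable as input to external ordination or tree tools.
#'
#' @param run a `frigg_run`.
#' @param ds the dataset.
#' @param dir output directory.
#' @param fasta write per-family FASTA files (requires sequences)?
#' @return Invisibly, the directory.
#' @export
export_run <- function(run, ds, dir, fasta = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(run$steps)) {
    fwrite(run$steps[[nm]], file.path(dir, paste0("candidates_", nm, ".tsv")),
           sep = "\t")
  }
  fwrite(run$summary, file.path(dir, "step_counts.tsv"), sep = "\t")
  final <- final_candidates(run)
  fams <- sort(unique(final$resistance_family_id))
  labels <- context_labels(ds, run)
  members <- ds$families[family_id %chin% fams]
  lab_tab <- merge(members, labels, by = c("organism_id", "protein_id"))
  setorder(lab_tab, family_id, organism_id, protein_id)
  fwrite(lab_tab[, .(family_id, organism_id, protein_id, label)],
         file.path(dir, "labels.tsv"), sep = "\t")
  onehot <- merge(lab_tab, ds$organisms[, .(organism_id, section)],
                  by = "organism_id")
  for (lv in c("StrictClust", "Clust", "0", "outsideSC")) {
    onehot[, (paste0("is_", sub("^0$", "free", lv))) :=
             as.integer(label == lv)]
  }
  fwrite(onehot, file.path(dir, "curation_matrix.tsv"), sep = "\t")
  if (fasta && any(!is.na(ds$proteins$sequence))) {
    for (f in fams) {
      write_family_fasta(f, ds, labels,
                         file.path(dir, paste0("family_", f, ".fasta")))
    }
  }
  invisible(dir)
}
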