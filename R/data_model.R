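#' Assemble and validate a frigg dataset
#'
#' Bundles the four catalog tables into a validated `frigg_dataset` object.
#' All tables are coerced to [data.table::data.table] and checked against the
#' referential-integrity invariants the pipeline relies on: unique protein
#' keys, cluster members present in the catalog, at most one cluster per
#' protein, and (when families are supplied) a true partition of the catalog.
#'
#' @param proteins data.frame with columns `organism_id`, `protein_id`,
#'   `length_aa`, `section`, `interpro_ids` (semicolon-joined, may be empty)
#'   and optionally `sequence`.
#' @param clusters data.frame with columns `cluster_id`, `organism_id`,
#'   `member_rank` (0-based), `protein_id`, `is_backbone` (0/1). May have
#'   zero rows.
#' @param families data.frame with columns `family_id`, `organism_id`,
#'   `protein_id`, or `NULL` if families will be built from BLAST hits later
#'   (see [build_families_from_hits()]).
#' @param organisms optional data.frame with columns `organism_id`, `name`,
#'   `section`; derived from the protein table (with `name = organism_id`)
#'   when absent.
#' @return A `frigg_dataset`: a list with elements `organisms`, `proteins`,
#'   `clusters`, `families`.
#' @export
frigg_dataset <- function(proteins, clusters, families = NULL,
                          organisms = NULL) {
  proteins <- as.data.table(proteins)
  clusters <- as.data.table(clusters)
  if (!is.null(families)) families <- as.data.table(families)

  .require_cols(proteins, c("organism_id", "protein_id", "length_aa",
                            "section", "interpro_ids"), "protein table")
  if (!"sequence" %in% names(proteins)) proteins[, sequence := NA_character_]
  if (nrow(clusters) == 0L) {
    clusters <- data.table(cluster_id = character(), organism_id = character(),
                           member_rank = integer(), protein_id = character(),
                           is_backbone = integer())
  }
  .require_cols(clusters, c("cluster_id", "organism_id", "member_rank",
                            "protein_id", "is_backbone"), "cluster table")
  if (!is.null(families)) {
    .require_cols(families, c("family_id", "organism_id", "protein_id"),
                  "family table")
  }

  if (is.null(organisms)) {
    organisms <- proteins[, .(name = organism_id[1L], section = section[1L]),
                          by = organism_id]
  } else {
    organisms <- as.data.table(organisms)
    .require_cols(organisms, c("organism_id", "name", "section"),
                  "organism table")
  }
  organisms <- merge(organisms[, .(organism_id, name, section)],
                     proteins[, .(n_proteins = .N), by = organism_id],
                     by = "organism_id", all.x = TRUE)
  organisms[is.na(n_proteins), n_proteins := 0L]
  setkey(organisms, organism_id)
  setkey(proteins, organism_id, protein_id)
  setorder(clusters, cluster_id, member_rank)
  if (!is.null(families)) setkey(families, family_id, organism_id, protein_id)

  ds <- structure(list(organisms = organisms, proteins = proteins,
                       clusters = clusters, families = families),
                  class = "frigg_dataset")
  validate_dataset(ds)
  ds
}

.require_cols <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a frigg dataset
#'
#' Checks the cross-table invariants and fails with an informative error
#' naming the offending records. Returns the dataset invisibly when valid.
#'
#' @param ds a `frigg_dataset`.
#' @return `ds`, invisibly.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "frigg_dataset"))
  p <- ds$proteins
  dup <- p[duplicated(p, by = c("organism_id", "protein_id"))]
  if (nrow(dup)) {
    stop("duplicate protein key(s): ",
         paste(unique(paste(dup$organism_id, dup$protein_id, sep = "/")),
               collapse = ", "), call. = FALSE)
  }
  if (any(p$length_aa <= 0L | is.na(p$length_aa))) {
    stop("protein lengths must be positive integers", call. = FALSE)
  }
  has_seq <- !is.na(p$sequence)
  if (any(has_seq & nchar(p$sequence) != p$length_aa)) {
    bad <- p[has_seq & nchar(sequence) != length_aa]
    stop("sequence length disagrees with length_aa for: ",
         paste(paste(bad$organism_id, bad$protein_id, sep = "/"),
               collapse = ", "), call. = FALSE)
  }

  cl <- ds$clusters
  if (nrow(cl)) {
    unknown <- cl[!p, on = c("organism_id", "protein_id")]
    if (nrow(unknown)) {
      stop("cluster member(s) absent from protein catalog: ",
           paste(unique(paste(unknown$organism_id, unknown$protein_id,
                              sep = "/")), collapse = ", "), call. = FALSE)
    }
    multi <- cl[, .(n_clusters = uniqueN(cluster_id)),
                by = .(organism_id, protein_id)][n_clusters > 1L]
    if (nrow(multi)) {
      stop("protein(s) assigned to more than one cluster: ",
           paste(paste(multi$organism_id, multi$protein_id, sep = "/"),
                 collapse = ", "), call. = FALSE)
    }
    mism <- cl[!ds$organisms, on = "organism_id"]
    if (nrow(mism)) {
      stop("cluster(s) reference unknown organism(s): ",
           paste(unique(mism$organism_id), collapse = ", "), call. = FALSE)
    }
  }

  fam <- ds$families
  if (!is.null(fam)) {
    dupf <- fam[duplicated(fam, by = c("organism_id", "protein_id"))]
    if (nrow(dupf)) {
      stop("protein(s) in more than one family: ",
           paste(unique(paste(dupf$organism_id, dupf$protein_id, sep = "/")),
                 collapse = ", "), call. = FALSE)
    }
    uncovered <- p[!fam, on = c("organism_id", "protein_id")]
    if (nrow(uncovered)) {
      stop("protein(s) not assigned to any family: ",
           paste(head(paste(uncovered$organism_id, uncovered$protein_id,
                            sep = "/"), 10L), collapse = ", "), call. = FALSE)
    }
    phantom <- fam[!p, on = c("organism_id", "protein_id")]
    if (nrow(phantom)) {
      stop("family member(s) absent from protein catalog: ",
           paste(paste(phantom$organism_id, phantom$protein_id, sep = "/"),
                 collapse = ", "), call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.frigg_dataset <- function(x, ...) {
  cat("frigg dataset:\n")
  cat(sprintf("  organisms: %d (%d sections)\n", nrow(x$organisms),
              uniqueN(x$organisms$section)))
  cat(sprintf("  proteins:  %d\n", nrow(x$proteins)))
  cat(sprintf("  clusters:  %d (%d cluster genes)\n",
              uniqueN(x$clusters$cluster_id), nrow(x$clusters)))
  if (is.null(x$families)) {
    cat("  families:  <none - supply a family table or build from hits>\n")
  } else {
    cat(sprintf("  families:  %d\n", uniqueN(x$families$family_id)))
  }
  invisible(x)
}

#' Pipeline run configuration
#'
#' Collects the tunable parameters of a single pipeline run.
#'
#' @param pattern cluster selection pattern at step 2: `"strict"` (every
#'   gene single-copy except one with exactly one extra-cluster paralog) or
#'   `"alternative"` (genes of large families are exempt from the copy
#'   constraint and ineligible as resistance genes).
#' @param x_input family-size multiplier for the alternative pattern: a
#'   family is exempt when its dataset-wide size strictly exceeds
#'   `x_input * n_organisms`. Values below 1.5 trigger a warning (the risk
#'   of exempting true resistance families becomes high).
#' @param skip_step3 skip the recurrence filter (step 3)?
#' @param essential_pct step-4 threshold: minimum percent of organisms that
#'   must carry the resistance family. Typical values 90-100.
#' @param apply_step5 apply the single-copy-majority filter (step 5)?
#' @param majority_pct step-5 threshold: a family is removed when strictly
#'   more than this percent of genomes carry two or more copies.
#' @param step3_distinct_organisms require the recurrent clusters of step 3
#'   to come from distinct organisms (off by default; recurrence is counted
#'   over clusters).
#' @param step5_within_family compute the step-5 fraction over organisms
#'   that possess the family instead of over all organisms (off by default).
#' @param random_seed integer seed recorded for provenance (used only by
#'   synthetic-data workflows).
#' @return A `frigg_config` list.
#' @export
frigg_config <- function(pattern = c("strict", "alternative"),
                         x_input = 2,
                         skip_step3 = FALSE,
                         essential_pct = 90,
                         apply_step5 = TRUE,
                         majority_pct = 50,
                         step3_distinct_organisms = FALSE,
                         step5_within_family = FALSE,
                         random_seed = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(is.numeric(x_input), length(x_input) == 1L, x_input > 0,
            is.numeric(essential_pct), essential_pct >= 0,
            essential_pct <= 100,
            is.numeric(majority_pct), majority_pct > 0, majority_pct <= 100,
            is.logical(skip_step3), is.logical(apply_step5))
  if (pattern == "alternative" && x_input < 1.5) {
    warning("x_input below 1.5: high risk of exempting true resistance ",
            "gene families", call. = FALSE)
  }
  structure(list(pattern = pattern, x_input = x_input,
                 skip_step3 = isTRUE(skip_step3),
                 essential_pct = essential_pct,
                 apply_step5 = isTRUE(apply_step5),
                 majority_pct = majority_pct,
                 step3_distinct_organisms = isTRUE(step3_distinct_organisms),
                 step5_within_family = isTRUE(step5_within_family),
                 random_seed = random_seed),
            class = "frigg_config")
}

#' @export
print.frigg_config <- function(x, ...) {
  cat(sprintf(
    "frigg config: pattern=%s%s, step3=%s, essential_pct=%g, step5=%s (majority_pct=%g)\n",
    x$pattern,
    if (x$pattern == "alternative") sprintf(" (x=%g)", x$x_input) else "",
    if (x$skip_step3) "skipped" else "applied",
    x$essential_pct,
    if (x$apply_step5) "applied" else "skipped",
    x$majority_pct))
  invisible(x)
}

# short label used in grid/run naming, e.g. "strict|step3|90" / "alt2|step3*|98"
config_label <- function(cfg) {
  pat <- if (cfg$pattern == "strict") "strict" else
    sprintf("alt%g", cfg$x_input)
  sprintf("%s|%s|%g", pat, if (cfg$skip_step3) "step3*" else "step3",
          cfg$essential_pct)
}

# minimal fingerprint used to refuse combining runs from different datasets
dataset_signature <- function(ds) {
  list(n_org = nrow(ds$organisms),
       n_prot = nrow(ds$proteins),
       n_clust = uniqueN(ds$clusters$cluster_id),
       n_fam = if (is.null(ds$families)) NA_integer_ else
         uniqueN(ds$families$family_id),
       first_keys = paste(head(sort(ds$proteins$protein_id), 3L),
                          collapse = ","))
}
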