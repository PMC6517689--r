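#' Parse tabular BLASTp hits
#'
#' Reads a BLAST tabular file (the standard 12-column `outfmt 6` dialect:
#' qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore; an extended dialect with trailing `qlen`/`slen`
#' columns is also accepted). Sequence identifiers must be
#' `organism_id~protein_id` keys resolvable in the catalog. Self-hits are
#' discarded and multiple hits for the same ordered (query, subject) pair
#' are collapsed to the best one: highest percent identity, ties broken by
#' the largest query+subject coverage sum.
#'
#' @param blast_tab_path path to the tabular hit file.
#' @param length_lookup data.table with columns `organism_id`, `protein_id`,
#'   `length_aa` (e.g. a dataset's `$proteins`); used when the file lacks
#'   qlen/slen columns, and to validate identifiers.
#' @return data.table of directed hits with columns `qseqid`, `sseqid`,
#'   `pident`, `qstart`, `qend`, `sstart`, `send`, `qlen`, `slen`,
#'   `cov_sum` (percent query coverage + percent subject coverage).
#' @export
parse_hits <- function(blast_tab_path, length_lookup) {
  hits <- fread(blast_tab_path, sep = "\t", header = FALSE)
  if (nrow(hits) == 0L) return(.empty_hits())
  if (!ncol(hits) %in% c(12L, 14L)) {
    stop("expected 12- or 14-column BLAST tabular input, got ", ncol(hits),
         " columns", call. = FALSE)
  }
  std <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
           "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  setnames(hits, c(std, if (ncol(hits) == 14L) c("qlen", "slen")))
  num_cols <- c("pident", "qstart", "qend", "sstart", "send")
  bad <- hits[, Reduce(`|`, lapply(.SD, function(x)
    is.na(suppressWarnings(as.numeric(x))))), .SDcols = num_cols]
  if (any(bad)) {
    stop("malformed hit row(s) at line(s): ",
         paste(head(which(bad), 10L), collapse = ", "), call. = FALSE)
  }
  for (cn in num_cols) set(hits, j = cn, value = as.numeric(hits[[cn]]))
  hits[, `:=`(qseqid = as.character(qseqid), sseqid = as.character(sseqid))]

  lk <- as.data.table(length_lookup)[, .(
    key = paste(organism_id, protein_id, sep = "~"), length_aa)]
  unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), lk$key)
  if (length(unknown)) {
    stop("hit identifier(s) not in catalog: ",
         paste(head(unknown, 10L), collapse = ", "), call. = FALSE)
  }
  if (!"qlen" %in% names(hits)) {
    hits[lk, qlen := i.length_aa, on = c(qseqid = "key")]
    hits[lk, slen := i.length_aa, on = c(sseqid = "key")]
  } else {
    hits[, `:=`(qlen = as.numeric(qlen), slen = as.numeric(slen))]
  }

  hits <- hits[qseqid != sseqid]
  if (nrow(hits) == 0L) return(.empty_hits())
  bad_coord <- hits[qstart > qend | qend > qlen | sstart > send | send > slen]
  if (nrow(bad_coord)) {
    stop("alignment coordinates outside sequence bounds for pair(s): ",
         paste(head(paste(bad_coord$qseqid, bad_coord$sseqid, sep = " -> "),
                    5L), collapse = ", "), call. = FALSE)
  }
  hits[, cov_sum := 100 * (qend - qstart + 1) / qlen +
         100 * (send - sstart + 1) / slen]
  # best hit per ordered pair: max identity, then max coverage sum
  setorder(hits, qseqid, sseqid, -pident, -cov_sum)
  hits <- hits[, .SD[1L], by = .(qseqid, sseqid)]
  hits[, .(qseqid, sseqid, pident, qstart, qend, sstart, send, qlen, slen,
           cov_sum)]
}

.empty_hits <- function() {
  data.table(qseqid = character(), sseqid = character(), pident = numeric(),
             qstart = numeric(), qend = numeric(), sstart = numeric(),
             send = numeric(), qlen = numeric(), slen = numeric(),
             cov_sum = numeric())
}

#' Qualifying undirected homology edges
#'
#' An undirected edge between proteins a and b qualifies iff BOTH directed
#' hits a->b and b->a are present and EACH independently satisfies the
#' identity and coverage thresholds: percent identity >= `min_identity` and
#' (percent query coverage + percent subject coverage) >= `min_coverage_sum`.
#' The per-direction reading is the stricter, symmetric interpretation of
#' "bidirectional"; within-organism hits are eligible (paralogs must end up
#' in one family, the pipeline's copy counts depend on it).
#'
#' @param hits directed hits from [parse_hits()].
#' @param min_identity minimum percent identity (default 50).
#' @param min_coverage_sum minimum query+subject coverage sum in percent
#'   (default 130).
#' @return data.table of undirected edges with columns `key_a`, `key_b`
#'   (`organism_id~protein_id` keys, `key_a` < `key_b`).
#' @export
qualifying_edges <- function(hits, min_identity = 50,
                             min_coverage_sum = 130) {
  h <- as.data.table(hits)
  if (nrow(h) == 0L) {
    return(data.table(key_a = character(), key_b = character()))
  }
  h <- h[pident >= min_identity & cov_sum >= min_coverage_sum]
  h[, `:=`(key_a = pmin(qseqid, sseqid), key_b = pmax(qseqid, sseqid))]
  both <- h[, .(ndir = uniqueN(qseqid)), by = .(key_a, key_b)][ndir >= 2L]
  both[, .(key_a, key_b)]
}

#' Single-linkage protein families from homology edges
#'
#' Families are the connected components of the undirected edge graph over
#' the full catalog; proteins with no qualifying edge form singleton
#' families. Family identifiers are deterministic: `F` plus a zero-padded
#' index assigned in order of each component's lexicographically smallest
#' member key, so the partition is invariant to input row order.
#'
#' @param edges data.table from [qualifying_edges()] (columns `key_a`,
#'   `key_b`).
#' @param all_proteins data.table with columns `organism_id`, `protein_id`
#'   covering every edge endpoint.
#' @return Family table: data.table with columns `family_id`, `organism_id`,
#'   `protein_id`.
#' @export
single_linkage_families <- function(edges, all_proteins) {
  prot <- as.data.table(all_proteins)[, .(organism_id, protein_id)]
  keys <- sort(prot[, paste(organism_id, protein_id, sep = "~")])
  edges <- as.data.table(edges)
  if (nrow(edges)) {
    missing <- setdiff(unique(c(edges$key_a, edges$key_b)), keys)
    if (length(missing)) {
      stop("edge endpoint(s) not in protein set: ",
           paste(head(missing, 10L), collapse = ", "), call. = FALSE)
    }
    g <- igraph::graph_from_data_frame(
      edges[, .(key_a, key_b)], directed = FALSE,
      vertices = data.frame(name = keys))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_along(keys)
    names(comp) <- keys
  }
  dt <- data.table(pkey = names(comp), comp = as.integer(comp))
  # canonical ids: order components by their smallest member key
  dt[, rep_key := min(pkey), by = comp]
  reps <- sort(unique(dt$rep_key))
  width <- max(6L, nchar(length(reps)))
  dt[, family_id := sprintf(paste0("F%0", width, "d"),
                            match(rep_key, reps))]
  dt[, c("organism_id", "protein_id") := tstrsplit(pkey, "~", fixed = TRUE)]
  out <- dt[, .(family_id, organism_id, protein_id)]
  setorder(out, family_id, organism_id, protein_id)
  out[]
}

#' Build families from a BLAST tabular file and attach them to a dataset
#'
#' Convenience wrapper: [parse_hits()] + [qualifying_edges()] +
#' [single_linkage_families()], returning a new validated dataset whose
#' `$families` is the constructed partition.
#'
#' @param ds a `frigg_dataset` (families may be `NULL`).
#' @param blast_tab_path BLAST tabular hit file.
#' @param min_identity,min_coverage_sum thresholds, see
#'   [qualifying_edges()].
#' @return A `frigg_dataset` with families attached.
#' @export
build_families_from_hits <- function(ds, blast_tab_path, min_identity = 50,
                                     min_coverage_sum = 130) {
  stopifnot(inherits(ds, "frigg_dataset"))
  hits <- parse_hits(blast_tab_path, ds$proteins)
  edges <- qualifying_edges(hits, min_identity, min_coverage_sum)
  fam <- single_linkage_families(edges, ds$proteins)
  frigg_dataset(ds$proteins, ds$clusters, fam, ds$organisms)
}
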