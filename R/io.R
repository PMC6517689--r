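#' Load a dataset from its TSV tables
#'
#' Reads the protein, cluster and (optionally) family tables, attaches
#' sequences from FASTA files when given, and returns a validated
#' [frigg_dataset()]. Column schemas:
#'
#' * protein table: `organism_id`, `protein_id`, `length_aa`, `section`,
#'   `interpro_ids` (semicolon-joined, may be empty)
#' * cluster table: `cluster_id`, `organism_id`, `member_rank` (0-based),
#'   `protein_id`, `is_backbone` (0/1)
#' * family table: `family_id`, `organism_id`, `protein_id`
#' * organism table (optional): `organism_id`, `name`, `section`
#'
#' FASTA records are matched to catalog proteins by a
#' `organism_id~protein_id` identifier (first whitespace-delimited token of
#' the header).
#'
#' @param protein_table_path,cluster_table_path,family_table_path,organism_table_path
#'   paths to the TSV tables; the family and organism tables may be `NULL`.
#' @param fasta_paths character vector of FASTA paths, or `NULL`.
#' @param quiet suppress the loaded-counts message?
#' @return A validated `frigg_dataset`.
#' @export
load_dataset <- function(protein_table_path, cluster_table_path,
                         family_table_path = NULL, fasta_paths = NULL,
                         organism_table_path = NULL, quiet = FALSE) {
  for (pth in c(protein_table_path, cluster_table_path, family_table_path,
                fasta_paths, organism_table_path)) {
    if (!file.exists(pth)) stop("file not found: ", pth, call. = FALSE)
  }
  chr_cols <- function(dt, cols) {
    for (cn in intersect(cols, names(dt))) set(dt, j = cn,
                                               value = as.character(dt[[cn]]))
    dt
  }
  id_cols <- c("organism_id", "protein_id", "cluster_id", "family_id",
               "section", "interpro_ids", "name")
  proteins <- chr_cols(fread(protein_table_path, sep = "\t"), id_cols)
  if ("interpro_ids" %in% names(proteins)) {
    proteins[is.na(interpro_ids), interpro_ids := ""]
  }
  clusters <- chr_cols(fread(cluster_table_path, sep = "\t"), id_cols)
  families <- if (!is.null(family_table_path)) {
    chr_cols(fread(family_table_path, sep = "\t"), id_cols)
  }
  organisms <- if (!is.null(organism_table_path)) {
    chr_cols(fread(organism_table_path, sep = "\t"), id_cols)
  }

  if (!is.null(fasta_paths)) {
    seqs <- do.call(c, lapply(fasta_paths, Biostrings::readAAStringSet))
    ids <- sub("\\s.*$", "", names(seqs))
    seq_dt <- data.table(seq_key = ids, sequence = as.character(seqs))
    seq_dt[, c("organism_id", "protein_id") := tstrsplit(seq_key, "~",
                                                         fixed = TRUE)]
    proteins <- merge(proteins, seq_dt[, .(organism_id, protein_id, sequence)],
                      by = c("organism_id", "protein_id"), all.x = TRUE)
  }

  ds <- frigg_dataset(proteins, clusters, families, organisms)
  if (!quiet) {
    message(sprintf(
      "loaded %d organisms, %d proteins, %d clusters (%d cluster genes)",
      nrow(ds$organisms), nrow(ds$proteins),
      uniqueN(ds$clusters$cluster_id), nrow(ds$clusters)))
  }
  ds
}

#' Write a dataset back to TSV (and optionally FASTA)
#'
#' Emits `proteins.tsv`, `clusters.tsv`, `organisms.tsv`, `families.tsv`
#' (when present) and, when sequences are available, `proteins.fasta` with
#' `organism_id~protein_id` identifiers. Inverse of [load_dataset()].
#'
#' @param ds a `frigg_dataset`.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "frigg_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteins.tsv"),
             clusters = file.path(dir, "clusters.tsv"),
             organisms = file.path(dir, "organisms.tsv"))
  fwrite(ds$proteins[, .(organism_id, protein_id, length_aa, section,
                         interpro_ids)],
         paths[["proteins"]], sep = "\t")
  fwrite(ds$clusters, paths[["clusters"]], sep = "\t")
  fwrite(ds$organisms[, .(organism_id, name, section)],
         paths[["organisms"]], sep = "\t")
  if (!is.null(ds$families)) {
    paths["families"] <- file.path(dir, "families.tsv")
    fam <- copy(ds$families)
    setorder(fam, family_id, organism_id, protein_id)
    fwrite(fam, paths[["families"]], sep = "\t")
  }
  if (any(!is.na(ds$proteins$sequence))) {
    paths["fasta"] <- file.path(dir, "proteins.fasta")
    withseq <- ds$proteins[!is.na(sequence)]
    setorder(withseq, organism_id, protein_id)
    aa <- Biostrings::AAStringSet(withseq$sequence)
    names(aa) <- paste(withseq$organism_id, withseq$protein_id, sep = "~")
    Biostrings::writeXStringSet(aa, paths[["fasta"]], width = 80L)
  }
  invisible(paths)
}

#' Export one protein family as annotated FASTA
#'
#' Writes every member of a family as a FASTA record whose header carries
#' the curation metadata, pipe-delimited in fixed order:
#' `organism_name|section|protein_id|copies|label`, where `copies` is the
#' number of family members in that organism and `label` is the context
#' label (`StrictClust`, `Clust`, `0` or `outsideSC`, see
#' [context_labels()]). Records are ordered by (organism_id, protein_id).
#'
#' @param family_id the family to export.
#' @param ds a `frigg_dataset` with sequences for all family members.
#' @param context_labels data.table with columns `organism_id`,
#'   `protein_id`, `label`, as produced by [context_labels()].
#' @param out_path output FASTA path.
#' @return `out_path`, invisibly.
#' @export
write_family_fasta <- function(family_id, ds, context_labels, out_path) {
  stopifnot(inherits(ds, "frigg_dataset"), !is.null(ds$families))
  fid <- family_id
  fam <- ds$families[list(fid), on = "family_id", nomatch = NULL]
  if (nrow(fam) == 0L) stop("unknown family_id: ", fid, call. = FALSE)
  members <- merge(fam, ds$proteins[, .(organism_id, protein_id, sequence)],
                   by = c("organism_id", "protein_id"))
  if (anyNA(members$sequence)) {
    bad <- members[is.na(sequence)]
    stop("family member(s) lack sequences: ",
         paste(paste(bad$organism_id, bad$protein_id, sep = "/"),
               collapse = ", "), call. = FALSE)
  }
  members[, copies := .N, by = organism_id]
  members <- merge(members, ds$organisms[, .(organism_id, name, section)],
                   by = "organism_id")
  members <- merge(members,
                   as.data.table(context_labels)[, .(organism_id, protein_id,
                                                     label)],
                   by = c("organism_id", "protein_id"), all.x = TRUE)
  if (anyNA(members$label)) {
    bad <- members[is.na(label)]
    stop("no context label for member(s): ",
         paste(paste(bad$organism_id, bad$protein_id, sep = "/"),
               collapse = ", "), call. = FALSE)
  }
  setorder(members, organism_id, protein_id)
  aa <- Biostrings::AAStringSet(members$sequence)
  names(aa) <- members[, paste(name, section, protein_id, copies, label,
                               sep = "|")]
  Biostrings::writeXStringSet(aa, out_path, width = 80L)
  invisible(out_path)
}

#' Parse the headers of a family FASTA written by [write_family_fasta()]
#'
#' @param path FASTA path.
#' @return data.table with columns `organism_name`, `section`, `protein_id`,
#'   `copies`, `label`, `sequence`.
#' @export
read_family_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- tstrsplit(names(aa), "|", fixed = TRUE)
  if (length(parts) != 5L) {
    stop("malformed family FASTA header(s) in ", path, call. = FALSE)
  }
  data.table(organism_name = parts[[1L]], section = parts[[2L]],
             protein_id = parts[[3L]], copies = as.integer(parts[[4L]]),
             label = parts[[5L]], sequence = as.character(aa))
}
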