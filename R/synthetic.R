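#' Scenario specification for the synthetic generator
#'
#' Each scenario plants one resistance-gene architecture (or decoy) with a
#' known expected fate in the pipeline:
#'
#' * `true_resistance_recurrent`: a conserved single-copy family duplicated
#'   into clusters of two (or more) host organisms; survives every step
#'   (fate `"final"`).
#' * `fellutamide_like_singleton`: the same architecture in a single host;
#'   eliminated by the recurrence filter only (fate `"eliminated@step3"`,
#'   i.e. final whenever step 3 is skipped).
#' * `mpa_like_step2_decoy`: the cluster additionally carries a
#'   tailoring gene with a small-family genome homolog, so two members have
#'   homologs and the cluster fails selection under both patterns (fate
#'   `"eliminated@step2"`).
#' * `nonessential_dup_step4_decoy`: the duplicated family is present in
#'   too few organisms to count as essential (fate `"eliminated@step4"`).
#' * `multicopy_step5_decoy`: the duplicated family is conserved but
#'   multi-copy in a majority of organisms (fate `"eliminated@step5"`).
#' * `tailoring_large_family`: the cluster carries a member of a family
#'   larger than every exemption cutoff; blocking under strict, exempt (and
#'   selected) under the alternative pattern (fate `"final@alternative"`).
#'
#' @param kind one of the six scenario kinds above.
#' @param n_clusters number of planted clusters (host organisms), default 2
#'   for recurrent kinds, 1 for the singleton kinds.
#' @param family_orgs (`nonessential_dup_step4_decoy`) number of organisms
#'   carrying the family; default `floor(0.75 * n_organisms)`.
#' @param n_multi_orgs (`multicopy_step5_decoy`) number of organisms with
#'   two or more family copies; default `floor(n_organisms / 2) + 1`.
#' @param large_family_size (`tailoring_large_family`) total size of the
#'   large family; default `3 * n_organisms + 6` (above the cutoff for
#'   multipliers up to 3).
#' @return A `frigg_scenario` list.
#' @export
scenario_spec <- function(kind = c("true_resistance_recurrent",
                                   "fellutamide_like_singleton",
                                   "mpa_like_step2_decoy",
                                   "nonessential_dup_step4_decoy",
                                   "multicopy_step5_decoy",
                                   "tailoring_large_family"),
                          n_clusters = NULL, family_orgs = NULL,
                          n_multi_orgs = NULL, large_family_size = NULL) {
  kind <- match.arg(kind)
  if (is.null(n_clusters)) {
    n_clusters <- if (kind %in% c("fellutamide_like_singleton",
                                  "mpa_like_step2_decoy")) 1L else 2L
  }
  structure(list(kind = kind, n_clusters = as.integer(n_clusters),
                 family_orgs = family_orgs, n_multi_orgs = n_multi_orgs,
                 large_family_size = large_family_size),
            class = "frigg_scenario")
}

#' The default six-scenario suite
#'
#' One instance of every scenario kind, with default sizing.
#'
#' @return List of [scenario_spec()]s.
#' @export
default_scenarios <- function() {
  lapply(c("true_resistance_recurrent", "fellutamide_like_singleton",
           "mpa_like_step2_decoy", "nonessential_dup_step4_decoy",
           "multicopy_step5_decoy", "tailoring_large_family"),
         scenario_spec)
}

#' Generate a synthetic multi-genome dataset with planted architectures
#'
#' Builds a deterministic dataset emulating the structure of real
#' multi-genome input: organisms grouped in taxonomic sections; a backbone
#' of conserved single-copy ("essential") families spanning all organisms;
#' organism-private singleton proteins; background secondary-metabolite
#' clusters of 4-19 genes whose members are organism-unique; and the
#' requested planted scenarios with their ground-truth manifest. Family
#' assignment is emitted as ground truth; [generate_blast_hits()] can
#' additionally fabricate a BLAST tabular file consistent with it.
#'
#' @param n_organisms number of organisms (>= 2).
#' @param n_sections number of taxonomic sections organisms are spread over.
#' @param scenarios list of [scenario_spec()]s (default: all six kinds).
#' @param n_essential number of conserved single-copy background families.
#' @param n_private organism-private singleton proteins per organism.
#' @param n_background_clusters background clusters per organism.
#' @param cluster_size_range size range of background clusters.
#' @param sequences generate amino-acid sequences (required for FASTA
#'   export tests; lengths are always generated)?
#' @param seed integer seed; fixed seed + fixed spec gives byte-identical
#'   output.
#' @param dir if non-`NULL`, write the dataset tables and
#'   `truth_manifest.tsv` there.
#' @return List with `dataset` (a validated `frigg_dataset`) and `manifest`
#'   (data.table: `instance_id`, `scenario_kind`, `cluster_id`,
#'   `organism_id`, `resistance_protein_id`, `family_id`, `expected_fate`).
#' @export
generate_dataset <- function(n_organisms = 8, n_sections = 3,
                             scenarios = default_scenarios(),
                             n_essential = 25, n_private = 8,
                             n_background_clusters = 3,
                             cluster_size_range = c(4, 19),
                             sequences = TRUE, seed = 1, dir = NULL) {
  stopifnot(n_organisms >= 2, n_sections >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  sections <- c("Nidulantes", "Flavi", "Nigri", "Fumigati", "Terrei",
                "Candidi", "Usti", "Versicolores")
  sections <- rep_len(sections, n_sections)
  orgs <- sprintf("org%02d", seq_len(n_organisms))
  org_section <- sections[((seq_len(n_organisms) - 1L) %% n_sections) + 1L]
  names(org_section) <- orgs

  st <- new.env(parent = emptyenv())
  st$prot <- list()        # organism_id, protein_id, family (internal)
  st$clust <- list()       # cluster_id, organism_id, member_rank, protein_id, is_backbone
  st$pid <- stats::setNames(integer(n_organisms), orgs)
  st$fid <- 0L
  st$cid <- 0L

  new_family <- function() {
    st$fid <- st$fid + 1L
    sprintf("tmpfam%05d", st$fid)
  }
  add_protein <- function(org, family) {
    st$pid[[org]] <- st$pid[[org]] + 1L
    pid <- sprintf("p%04d", st$pid[[org]])
    st$prot[[length(st$prot) + 1L]] <-
      list(organism_id = org, protein_id = pid, family = family)
    pid
  }
  add_cluster <- function(org, pids) {
    st$cid <- st$cid + 1L
    cid <- sprintf("c%04d", st$cid)
    st$clust[[length(st$clust) + 1L]] <-
      data.table(cluster_id = cid, organism_id = org,
                 member_rank = seq_along(pids) - 1L, protein_id = pids,
                 is_backbone = as.integer(seq_along(pids) == 1L))
    cid
  }
  # a planted cluster: backbone + tailoring singleton genes + extra members
  planted_cluster <- function(org, special_pids, n_filler = NULL) {
    if (is.null(n_filler)) n_filler <- sample(3:5, 1L)
    filler <- vapply(seq_len(n_filler), function(i)
      add_protein(org, new_family()), character(1))
    add_cluster(org, c(filler[1L], special_pids, filler[-1L]))
  }
  # conserved family: one free-standing copy in each of the given organisms
  conserved_family <- function(in_orgs) {
    fam <- new_family()
    for (o in in_orgs) add_protein(o, fam)
    fam
  }

  # --- background ---
  for (i in seq_len(n_essential)) conserved_family(orgs)
  for (o in orgs) {
    for (i in seq_len(n_private)) add_protein(o, new_family())
    for (i in seq_len(n_background_clusters)) {
      sz <- sample(cluster_size_range[1L]:cluster_size_range[2L], 1L)
      pids <- vapply(seq_len(sz), function(j) add_protein(o, new_family()),
                     character(1))
      add_cluster(o, pids)
    }
  }

  # --- planted scenarios ---
  manifest <- list()
  inst_counter <- stats::setNames(integer(0), character(0))
  add_instances <- function(kind, cids, hosts, res_pids, fam) {
    for (j in seq_along(cids)) {
      k <- if (kind %in% names(inst_counter)) inst_counter[[kind]] + 1L else 1L
      inst_counter[[kind]] <<- k
      fate <- switch(kind,
        true_resistance_recurrent = "final",
        fellutamide_like_singleton = "eliminated@step3",
        mpa_like_step2_decoy = "eliminated@step2",
        nonessential_dup_step4_decoy = "eliminated@step4",
        multicopy_step5_decoy = "eliminated@step5",
        tailoring_large_family = "final@alternative")
      manifest[[length(manifest) + 1L]] <<- data.table(
        instance_id = sprintf("%s_%02d", kind, k), scenario_kind = kind,
        cluster_id = cids[j], organism_id = hosts[j],
        resistance_protein_id = res_pids[j], family_id = fam,
        expected_fate = fate)
    }
  }

  for (sc in scenarios) {
    stopifnot(inherits(sc, "frigg_scenario"))
    if (sc$n_clusters > n_organisms) {
      stop(sprintf("scenario %s needs %d distinct host organisms, dataset has %d",
                   sc$kind, sc$n_clusters, n_organisms), call. = FALSE)
    }
    hosts <- sample(orgs, sc$n_clusters)

    if (sc$kind %in% c("true_resistance_recurrent",
                       "fellutamide_like_singleton")) {
      fam <- conserved_family(orgs)
      res_pids <- vapply(hosts, function(o) add_protein(o, fam), character(1))
      cids <- vapply(seq_along(hosts), function(j)
        planted_cluster(hosts[j], res_pids[j]), character(1))
      add_instances(sc$kind, cids, hosts, res_pids, fam)

    } else if (sc$kind == "mpa_like_step2_decoy") {
      fam <- conserved_family(orgs)
      # small family (3 members) with a free genome homolog in the host:
      # a second cluster member with a homolog sinks the cluster at step 2
      small <- new_family()
      other <- sample(setdiff(orgs, hosts[1L]), 1L)
      add_protein(other, small)           # remote member
      add_protein(hosts[1L], small)       # host free-standing homolog
      decoy_pid <- add_protein(hosts[1L], small)  # cluster-resident copy
      res_pid <- add_protein(hosts[1L], fam)
      cid <- planted_cluster(hosts[1L], c(res_pid, decoy_pid))
      add_instances(sc$kind, cid, hosts[1L], res_pid, fam)

    } else if (sc$kind == "nonessential_dup_step4_decoy") {
      n_with <- sc$family_orgs %||% max(sc$n_clusters,
                                        floor(0.75 * n_organisms))
      if (n_with >= 0.9 * n_organisms) {
        stop("nonessential_dup_step4_decoy: family_orgs too large to fail ",
             "the 90% essentiality threshold", call. = FALSE)
      }
      in_orgs <- unique(c(hosts, sample(setdiff(orgs, hosts),
                                        max(0L, n_with - length(hosts)))))
      fam <- conserved_family(in_orgs)
      res_pids <- vapply(hosts, function(o) add_protein(o, fam), character(1))
      cids <- vapply(seq_along(hosts), function(j)
        planted_cluster(hosts[j], res_pids[j]), character(1))
      add_instances(sc$kind, cids, hosts, res_pids, fam)

    } else if (sc$kind == "multicopy_step5_decoy") {
      fam <- conserved_family(orgs)
      n_multi <- sc$n_multi_orgs %||% (floor(n_organisms / 2) + 1L)
      if (n_multi <= n_organisms / 2) {
        stop("multicopy_step5_decoy: n_multi_orgs must exceed half the ",
             "organisms to fail step 5", call. = FALSE)
      }
      extra_multi <- sample(setdiff(orgs, hosts),
                            max(0L, n_multi - length(hosts)))
      for (o in extra_multi) add_protein(o, fam)  # free second copies
      res_pids <- vapply(hosts, function(o) add_protein(o, fam), character(1))
      cids <- vapply(seq_along(hosts), function(j)
        planted_cluster(hosts[j], res_pids[j]), character(1))
      add_instances(sc$kind, cids, hosts, res_pids, fam)

    } else if (sc$kind == "tailoring_large_family") {
      fam <- conserved_family(orgs)
      lf_size <- sc$large_family_size %||% (3L * n_organisms + 6L)
      lf <- new_family()
      res_pids <- character(length(hosts))
      cids <- character(length(hosts))
      placed <- 0L
      for (j in seq_along(hosts)) {
        o <- hosts[j]
        res_pids[j] <- add_protein(o, fam)
        lf_in_cluster <- add_protein(o, lf)
        # two extra free copies keep the large-family member well away from
        # the resistance pattern under the strict reading
        add_protein(o, lf); add_protein(o, lf)
        placed <- placed + 3L
        cids[j] <- planted_cluster(o, c(res_pids[j], lf_in_cluster))
      }
      while (placed < lf_size) {
        o <- orgs[(placed %% n_organisms) + 1L]
        add_protein(o, lf)
        placed <- placed + 1L
      }
      add_instances(sc$kind, cids, hosts, res_pids, fam)
    }
  }

  # --- assemble tables ---
  prot <- rbindlist(lapply(st$prot, as.data.table))
  clusters <- rbindlist(st$clust)
  if (nrow(clusters) == 0L) clusters <- data.table(
    cluster_id = character(), organism_id = character(),
    member_rank = integer(), protein_id = character(),
    is_backbone = integer())
  manifest <- if (length(manifest)) rbindlist(manifest) else data.table(
    instance_id = character(), scenario_kind = character(),
    cluster_id = character(), organism_id = character(),
    resistance_protein_id = character(), family_id = character(),
    expected_fate = character())

  # canonical family ids, same convention as single_linkage_families():
  # F + zero-padded index ordered by the smallest member key
  prot[, key := paste(organism_id, protein_id, sep = "~")]
  prot[, rep_key := min(key), by = family]
  reps <- sort(unique(prot$rep_key))
  width <- max(6L, nchar(length(reps)))
  prot[, family_id := sprintf(paste0("F%0", width, "d"),
                              match(rep_key, reps))]
  fam_map <- unique(prot[, .(family, family_id)])
  setnames(manifest, "family_id", "family")
  manifest <- merge(manifest, fam_map, by = "family")
  manifest[, family := NULL]
  setorder(manifest, instance_id)
  manifest <- manifest[, .(instance_id, scenario_kind, cluster_id,
                           organism_id, resistance_protein_id, family_id,
                           expected_fate)]

  # lengths, annotations, sequences
  prot[, length_aa := sample(80:200, .N, replace = TRUE)]
  ipr_pool <- c("IPR002401", "IPR013217", "IPR001128", "IPR011701",
                "IPR001789", "IPR000182")
  prot[, interpro_ids := ifelse(runif(.N) < 0.3,
                                sample(ipr_pool, .N, replace = TRUE), "")]
  if (sequences) {
    alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    prot[, sequence := {
      parent_len <- length_aa[1L]
      parent <- paste(sample(alphabet, parent_len, replace = TRUE),
                      collapse = "")
      vapply(seq_len(.N), function(i) {
        if (i == 1L) return(parent)
        mutate_sequence(parent, target_identity = runif(1L, 65, 90))
      }, character(1))
    }, by = family_id]
    prot[, length_aa := nchar(sequence)]
  } else {
    prot[, sequence := NA_character_]
  }

  proteins <- prot[, .(organism_id, protein_id, length_aa,
                       section = org_section[organism_id],
                       interpro_ids, sequence)]
  organisms <- data.table(organism_id = orgs,
                          name = sprintf("Aspergillus synthetica %s",
                                         sub("^org", "", orgs)),
                          section = unname(org_section))
  families <- prot[, .(family_id, organism_id, protein_id)]
  setorder(families, family_id, organism_id, protein_id)
  ds <- frigg_dataset(proteins, clusters, families, organisms)

  if (!is.null(dir)) {
    write_dataset(ds, dir)
    fwrite(manifest, file.path(dir, "truth_manifest.tsv"), sep = "\t")
  }
  list(dataset = ds, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Mutate an amino-acid sequence to an exact target identity
#'
#' Applies point substitutions (never indels) at positions sampled without
#' replacement so that the child's exact identity to the parent equals
#' `round(target_identity / 100 * nchar(parent)) / nchar(parent)`.
#'
#' @param parent_sequence nonempty amino-acid string.
#' @param target_identity percent identity in `(0, 100]`.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(parent_sequence, target_identity, seed = NULL) {
  stopifnot(is.character(parent_sequence), nchar(parent_sequence) >= 1L,
            target_identity > 0, target_identity <= 100)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  chars <- strsplit(parent_sequence, "")[[1L]]
  len <- length(chars)
  n_keep <- round(target_identity / 100 * len)
  if (n_keep < 0L || n_keep > len) {
    stop("target identity out of achievable range", call. = FALSE)
  }
  n_sub <- len - n_keep
  if (n_sub == 0L) return(parent_sequence)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  pos <- sample.int(len, n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Fabricate a BLAST tabular file consistent with a family partition
#'
#' Emits 12-column tabular hits whose qualifying bidirectional edges
#' reconstruct the dataset's ground-truth families via single linkage:
#' consecutive members of each family are linked by reciprocal
#' full-coverage hits above the thresholds. Sub-threshold cross-family
#' hits and unreciprocated high-identity hits are added as decoys that a
#' correct edge filter must ignore.
#'
#' @param ds a `frigg_dataset` with families.
#' @param path output path for the tabular file (`NULL` to just return the
#'   table).
#' @param n_decoys number of decoy hit pairs of each kind.
#' @param seed integer seed.
#' @return The hit table (invisibly when `path` is given).
#' @export
generate_blast_hits <- function(ds, path = NULL, n_decoys = 25, seed = 1) {
  stopifnot(inherits(ds, "frigg_dataset"), !is.null(ds$families))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  memb <- merge(ds$families, ds$proteins[, .(organism_id, protein_id,
                                             length_aa)],
                by = c("organism_id", "protein_id"))
  memb[, key := paste(organism_id, protein_id, sep = "~")]
  setorder(memb, family_id, key)

  mk_hit <- function(q, s, qlen, slen, pident) {
    data.table(qseqid = q, sseqid = s, pident = pident,
               length = qlen, mismatch = round(qlen * (100 - pident) / 100),
               gapopen = 0L, qstart = 1L, qend = qlen, sstart = 1L,
               send = slen, evalue = 1e-50, bitscore = 200)
  }
  rows <- list()
  memb[, {
    if (.N >= 2L) {
      for (i in seq_len(.N - 1L)) {
        ident <- runif(1L, 55, 95)
        rows[[length(rows) + 1L]] <<- mk_hit(key[i], key[i + 1L],
                                             length_aa[i], length_aa[i + 1L],
                                             round(ident, 1))
        rows[[length(rows) + 1L]] <<- mk_hit(key[i + 1L], key[i],
                                             length_aa[i + 1L], length_aa[i],
                                             round(ident, 1))
      }
    }
    NULL
  }, by = family_id]

  # decoys: sub-threshold reciprocal pairs and one-directional strong hits
  n_prot <- nrow(memb)
  if (n_prot >= 4L && n_decoys > 0L) {
    for (d in seq_len(n_decoys)) {
      ij <- sample.int(n_prot, 2L)
      a <- memb[ij[1L]]; b <- memb[ij[2L]]
      if (a$family_id != b$family_id) {
        ident <- runif(1L, 25, 45)
        rows[[length(rows) + 1L]] <- mk_hit(a$key, b$key, a$length_aa,
                                            b$length_aa, round(ident, 1))
        rows[[length(rows) + 1L]] <- mk_hit(b$key, a$key, b$length_aa,
                                            a$length_aa, round(ident, 1))
      }
      ij <- sample.int(n_prot, 2L)
      a <- memb[ij[1L]]; b <- memb[ij[2L]]
      if (a$family_id != b$family_id) {
        rows[[length(rows) + 1L]] <- mk_hit(a$key, b$key, a$length_aa,
                                            b$length_aa,
                                            round(runif(1L, 80, 95), 1))
      }
    }
  }
  hits <- rbindlist(rows)
  if (!is.null(path)) {
    fwrite(hits, path, sep = "\t", col.names = FALSE)
    return(invisible(hits))
  }
  hits[]
}

#' Expected per-run fate implied by a manifest fate
#'
#' Translates a planted instance's manifest fate into what a specific run
#' configuration should observe (see [observed_fate()] for the vocabulary).
#'
#' @param fate manifest fate string.
#' @param config a [frigg_config()].
#' @return One of `"final"`, `"absent@step2"`, `"eliminated@step3"`,
#'   `"eliminated@step4"`, `"eliminated@step5"`.
#' @export
expected_fate_for_run <- function(fate, config) {
  switch(fate,
    "final" = "final",
    "eliminated@step2" = "absent@step2",
    "eliminated@step3" = if (config$skip_step3) "final" else
      "eliminated@step3",
    "eliminated@step4" = "eliminated@step4",
    "eliminated@step5" = if (config$apply_step5) "eliminated@step5" else
      "final",
    "final@alternative" = if (config$pattern == "strict") "absent@step2" else
      "final",
    stop("unknown fate: ", fate, call. = FALSE))
}

#' Observed fate of a cluster in a run
#'
#' Reports where (if anywhere) a cluster dropped out of a run's candidate
#' sets: `"absent@step2"` if never selected, `"eliminated@stepK"` for the
#' first applied step K that removed it, else `"final"`.
#'
#' @param run a `frigg_run`.
#' @param cluster_id the cluster to trace.
#' @return Fate string.
#' @export
observed_fate <- function(run, cluster_id) {
  stopifnot(inherits(run, "frigg_run"))
  cid <- cluster_id
  steps <- run$steps
  if (!cid %chin% steps$step2$cluster_id) return("absent@step2")
  for (nm in setdiff(names(steps), "step2")) {
    if (!cid %chin% steps[[nm]]$cluster_id) {
      return(paste0("eliminated@", nm))
    }
  }
  "final"
}
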