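# Independent brute-force oracles, written as plain loops directly from the
# method's definitions. Deliberately naive and structurally unlike the
# data.table implementation they check.

# -- graph oracles -----------------------------------------------------------

# connected components by breadth-first traversal over an adjacency list
oracle_components_bfs <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$key_a[i]; b <- edges$key_b[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (start in nodes) {
    if (!is.na(comp[[start]])) next
    k <- k + 1L
    queue <- start
    comp[[start]] <- k
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(comp[[w]])) {
          comp[[w]] <- k
          queue <- c(queue, w)
        }
      }
    }
  }
  split(names(comp), comp)
}

# second independent implementation: union-find with path compression
oracle_components_unionfind <- function(edges, nodes) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges$key_a[i]); rb <- find(edges$key_b[i])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# canonical form of a partition: sorted list of sorted member vectors
canonical_partition <- function(groups) {
  groups <- unname(lapply(groups, sort))
  groups[order(vapply(groups, `[`, character(1), 1L))]
}

partition_from_family_table <- function(fam) {
  keys <- paste(fam$organism_id, fam$protein_id, sep = "~")
  canonical_partition(split(keys, fam$family_id))
}

# -- pipeline oracles --------------------------------------------------------

# plain-loop homology counts: for every cluster gene, count same-organism
# family members, and how many of those sit in any predicted cluster
oracle_counts <- function(ds) {
  fam_of <- setNames(ds$families$family_id,
                     paste(ds$families$organism_id, ds$families$protein_id,
                           sep = "~"))
  clustered_keys <- unique(paste(ds$clusters$organism_id,
                                 ds$clusters$protein_id, sep = "~"))
  rows <- list()
  for (i in seq_len(nrow(ds$clusters))) {
    org <- ds$clusters$organism_id[i]
    pid <- ds$clusters$protein_id[i]
    f <- fam_of[[paste(org, pid, sep = "~")]]
    same_org <- ds$families[ds$families$family_id == f &
                              ds$families$organism_id == org, ]
    keys <- paste(same_org$organism_id, same_org$protein_id, sep = "~")
    rows[[i]] <- data.frame(
      organism_id = org, cluster_id = ds$clusters$cluster_id[i],
      protein_id = pid, family_id = f,
      copies_in_organism = nrow(same_org),
      copies_in_clusters = sum(keys %in% clustered_keys))
  }
  out <- do.call(rbind, rows)
  out[order(out$organism_id, out$cluster_id, out$protein_id), ]
}

# step 2, straight from the prose: only one of the (non-exempt) genes has a
# homolog in the genome; it has exactly one; that homolog is outside every
# predicted cluster; exempt genes are ineligible as resistance genes
oracle_select <- function(ds, pattern = "strict", x_input = 2) {
  fam_sizes <- table(ds$families$family_id)
  cutoff <- x_input * nrow(ds$organisms)
  exempt_fams <- if (pattern == "alternative") {
    names(fam_sizes)[fam_sizes > cutoff]
  } else character()
  fam_of <- setNames(ds$families$family_id,
                     paste(ds$families$organism_id, ds$families$protein_id,
                           sep = "~"))
  clustered_keys <- unique(paste(ds$clusters$organism_id,
                                 ds$clusters$protein_id, sep = "~"))
  out <- list()
  for (cid in unique(ds$clusters$cluster_id)) {
    mem <- ds$clusters[ds$clusters$cluster_id == cid, ]
    org <- mem$organism_id[1L]
    copies <- integer(nrow(mem))
    nonexempt <- logical(nrow(mem))
    free_copy <- vector("list", nrow(mem))
    for (j in seq_len(nrow(mem))) {
      f <- fam_of[[paste(org, mem$protein_id[j], sep = "~")]]
      same_org <- ds$families[ds$families$family_id == f &
                                ds$families$organism_id == org, ]
      copies[j] <- nrow(same_org)
      nonexempt[j] <- !(f %in% exempt_fams)
      others <- setdiff(same_org$protein_id, mem$protein_id[j])
      free_copy[[j]] <- others[!(paste(org, others, sep = "~") %in%
                                   clustered_keys)]
    }
    with_homolog <- which(nonexempt & copies >= 2L)
    if (length(with_homolog) != 1L) next
    j <- with_homolog
    if (copies[j] != 2L) next
    if (length(free_copy[[j]]) != 1L) next   # the extra copy must be free
    out[[cid]] <- data.frame(
      cluster_id = cid, organism_id = org,
      resistance_protein_id = mem$protein_id[j],
      resistance_family_id = fam_of[[paste(org, mem$protein_id[j],
                                           sep = "~")]],
      target_protein_ids = free_copy[[j]])
  }
  if (!length(out)) {
    return(data.frame(cluster_id = character(), organism_id = character(),
                      resistance_protein_id = character(),
                      resistance_family_id = character(),
                      target_protein_ids = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$organism_id, res$cluster_id), ]
}

oracle_recurrent <- function(cands) {
  keep <- character()
  for (f in unique(cands$resistance_family_id)) {
    if (length(unique(cands$cluster_id[cands$resistance_family_id == f])) >= 2L) {
      keep <- c(keep, f)
    }
  }
  cands[cands$resistance_family_id %in% keep, ]
}

oracle_essential <- function(cands, ds, pct) {
  orgs <- ds$organisms$organism_id
  keep <- character()
  for (f in unique(cands$resistance_family_id)) {
    n_with <- sum(vapply(orgs, function(o)
      any(ds$families$family_id == f & ds$families$organism_id == o),
      logical(1)))
    if (n_with / length(orgs) >= pct / 100) keep <- c(keep, f)
  }
  cands[cands$resistance_family_id %in% keep, ]
}

oracle_single_copy <- function(cands, ds, majority_pct = 50) {
  orgs <- ds$organisms$organism_id
  keep <- character()
  for (f in unique(cands$resistance_family_id)) {
    n_multi <- sum(vapply(orgs, function(o)
      sum(ds$families$family_id == f &
            ds$families$organism_id == o) >= 2L, logical(1)))
    if (!(n_multi / length(orgs) > majority_pct / 100)) keep <- c(keep, f)
  }
  cands[cands$resistance_family_id %in% keep, ]
}

# -- fixtures ----------------------------------------------------------------

# tiny hand-built dataset: 2 organisms; orgA has a strict-conformant
# cluster (cl1: pb backbone singleton, pr resistance with free homolog pt)
# and a rejected cluster (cl2: two members with genome homologs)
tiny_dataset <- function(sequences = FALSE) {
  proteins <- data.frame(
    organism_id = c(rep("orgA", 8L), rep("orgB", 3L)),
    protein_id = c("pb", "pr", "pt", "px1", "px2", "py1", "py2", "pz",
                   "qa", "qb", "qc"),
    length_aa = 100L,
    section = rep(c("SecOne", "SecTwo"), c(8L, 3L)),
    interpro_ids = "",
    stringsAsFactors = FALSE)
  if (sequences) {
    set.seed(42)
    alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    proteins$sequence <- vapply(seq_len(nrow(proteins)), function(i)
      paste(sample(alpha, 100L, replace = TRUE), collapse = ""),
      character(1))
  }
  clusters <- data.frame(
    cluster_id = c("cl1", "cl1", "cl2", "cl2"),
    organism_id = "orgA",
    member_rank = c(0L, 1L, 0L, 1L),
    protein_id = c("pb", "pr", "px1", "py1"),
    is_backbone = c(1L, 0L, 1L, 0L),
    stringsAsFactors = FALSE)
  families <- data.frame(
    family_id = c("Fb", "Fr", "Fr", "Fx", "Fx", "Fy", "Fy", "Fz",
                  "Fr", "Fq1", "Fq2"),
    organism_id = c(rep("orgA", 8L), rep("orgB", 3L)),
    protein_id = c("pb", "pr", "pt", "px1", "px2", "py1", "py2", "pz",
                   "qa", "qb", "qc"),
    stringsAsFactors = FALSE)
  frigg_dataset(proteins, clusters, families)
}

# random raw dataset (independent of the synthetic module): random family
# partition plus random disjoint clusters, for oracle-equivalence sweeps
random_dataset <- function(seed) {
  set.seed(seed)
  n_org <- sample(3:8, 1L)
  orgs <- sprintf("o%02d", seq_len(n_org))
  prot <- list()
  for (o in orgs) {
    n_p <- sample(15:35, 1L)
    prot[[o]] <- data.frame(organism_id = o,
                            protein_id = sprintf("p%03d", seq_len(n_p)),
                            length_aa = sample(80:300, n_p, replace = TRUE),
                            section = "SecX", interpro_ids = "",
                            stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, prot)
  n_fam <- sample(ceiling(nrow(proteins) / 6):nrow(proteins), 1L)
  fam_ids <- sprintf("F%03d", sample.int(n_fam, nrow(proteins),
                                         replace = TRUE))
  families <- data.frame(family_id = fam_ids,
                         organism_id = proteins$organism_id,
                         protein_id = proteins$protein_id,
                         stringsAsFactors = FALSE)
  clus <- list()
  cid <- 0L
  for (o in orgs) {
    pool <- proteins$protein_id[proteins$organism_id == o]
    n_c <- sample(1:4, 1L)
    for (k in seq_len(n_c)) {
      if (length(pool) < 3L) break
      sz <- sample(3:min(8L, length(pool)), 1L)
      mem <- sample(pool, sz)
      pool <- setdiff(pool, mem)
      cid <- cid + 1L
      clus[[cid]] <- data.frame(cluster_id = sprintf("c%03d", cid),
                                organism_id = o,
                                member_rank = seq_along(mem) - 1L,
                                protein_id = mem,
                                is_backbone = as.integer(seq_along(mem) == 1L),
                                stringsAsFactors = FALSE)
    }
  }
  clusters <- do.call(rbind, clus)
  frigg_dataset(proteins, clusters, families)
}

# random edge set over n proteins for family-builder oracle sweeps
random_edges <- function(n, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("o01~p%03d", seq_len(n))
  if (n_edges == 0L) {
    return(list(nodes = nodes,
                edges = data.frame(key_a = character(),
                                   key_b = character())))
  }
  pairs <- unique(t(replicate(n_edges, sort(sample(nodes, 2L)))))
  list(nodes = nodes,
       edges = data.frame(key_a = pairs[, 1L], key_b = pairs[, 2L],
                          stringsAsFactors = FALSE))
}

cand_key <- function(cands) {
  sort(paste(cands$cluster_id, cands$resistance_protein_id, sep = ":"))
}
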