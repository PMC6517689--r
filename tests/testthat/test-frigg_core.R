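test_that("homology counts match manual enumeration on the tiny dataset", {
  ds <- tiny_dataset()
  counts <- compute_homology_counts(ds)
  cnt <- function(pid) as.list(counts[protein_id == pid,
                                      .(copies_in_organism,
                                        copies_in_clusters)])
  # pb: singleton family inside cl1 -> (1, 1)
  expect_equal(cnt("pb"), list(copies_in_organism = 1L,
                               copies_in_clusters = 1L))
  # pr: family {pr in cl1, pt free, qa in orgB} -> per-organism (2, 1)
  expect_equal(cnt("pr"), list(copies_in_organism = 2L,
                               copies_in_clusters = 1L))
  expect_equal(cnt("px1"), list(copies_in_organism = 2L,
                                copies_in_clusters = 1L))
  # one row per cluster gene, counts bounded
  expect_equal(nrow(counts), nrow(ds$clusters))
  expect_true(all(counts$copies_in_clusters >= 1L))
  expect_true(all(counts$copies_in_clusters <= counts$copies_in_organism))
})

test_that("a 3-copies / 2-in-clusters family is reported as (3, 2)", {
  proteins <- data.frame(organism_id = "o1",
                         protein_id = c("a1", "a2", "a3", "b1", "b2"),
                         length_aa = 100L, section = "S", interpro_ids = "")
  clusters <- data.frame(cluster_id = c("c1", "c1", "c2", "c2"),
                         organism_id = "o1", member_rank = c(0L, 1L, 0L, 1L),
                         protein_id = c("a1", "b1", "a2", "b2"),
                         is_backbone = c(1L, 0L, 1L, 0L))
  families <- data.frame(family_id = c("FA", "FA", "FA", "FB", "FB"),
                         organism_id = "o1",
                         protein_id = c("a1", "a2", "a3", "b1", "b2"))
  ds <- frigg_dataset(proteins, clusters, families)
  counts <- compute_homology_counts(ds)
  expect_equal(counts[protein_id == "a1", copies_in_organism], 3L)
  expect_equal(counts[protein_id == "a1", copies_in_clusters], 2L)
  expect_equal(counts[protein_id == "b1", copies_in_organism], 2L)
  expect_equal(counts[protein_id == "b1", copies_in_clusters], 2L)
})

test_that("family_size_cutoff is x times the organism count, with guards", {
  expect_equal(family_size_cutoff(5, 2), 10)
  expect_error(family_size_cutoff(0, 2), "positive")
  expect_error(family_size_cutoff(5, 0), "positive")
  expect_error(family_size_cutoff(5, -1), "positive")
})

test_that("strict selection accepts the conformant cluster and rejects others", {
  ds <- tiny_dataset()
  counts <- compute_homology_counts(ds)
  sel <- select_clusters_strict(counts, ds)
  # cl1: pb single-copy, pr with exactly one free homolog -> selected
  expect_equal(sel$cluster_id, "cl1")
  expect_equal(sel$resistance_protein_id, "pr")
  expect_equal(sel$resistance_family_id, "Fr")
  expect_equal(sel$target_protein_ids, "pt")
  expect_equal(sel$exempt_protein_ids, "")
  # cl2 has two members with genome homologs -> rejected (not in output)
  expect_false("cl2" %in% sel$cluster_id)
})

test_that("a cluster whose extra copy sits in a cluster is not selected", {
  # family FA has both copies inside clusters: no free target
  proteins <- data.frame(organism_id = "o1",
                         protein_id = c("a1", "a2", "b1", "b2"),
                         length_aa = 100L, section = "S", interpro_ids = "")
  clusters <- data.frame(cluster_id = c("c1", "c1", "c2", "c2"),
                         organism_id = "o1", member_rank = c(0L, 1L, 0L, 1L),
                         protein_id = c("b1", "a1", "b2", "a2"),
                         is_backbone = c(1L, 0L, 1L, 0L))
  families <- data.frame(family_id = c("FA", "FA", "FB1", "FB2"),
                         organism_id = "o1",
                         protein_id = c("a1", "a2", "b1", "b2"))
  ds <- frigg_dataset(proteins, clusters, families)
  sel <- select_clusters_strict(compute_homology_counts(ds), ds)
  expect_equal(nrow(sel), 0L)
})

test_that("an MPA-like cluster with a duplicated small-family tailoring gene fails step 2", {
  # four genes: backbone (single), P450 (single), methyltransferase with one
  # extra genome copy (small family), candidate with one extra copy
  proteins <- data.frame(
    organism_id = "o1",
    protein_id = c("pks", "p450", "mt", "mt2", "res", "target"),
    length_aa = 100L, section = "S", interpro_ids = "")
  clusters <- data.frame(cluster_id = "mpa", organism_id = "o1",
                         member_rank = 0:3,
                         protein_id = c("pks", "p450", "mt", "res"),
                         is_backbone = c(1L, 0L, 0L, 0L))
  families <- data.frame(
    family_id = c("Fpks", "Fp450", "Fmt", "Fmt", "Fres", "Fres"),
    organism_id = "o1",
    protein_id = c("pks", "p450", "mt", "mt2", "res", "target"))
  ds <- frigg_dataset(proteins, clusters, families)
  counts <- compute_homology_counts(ds)
  expect_equal(nrow(select_clusters_strict(counts, ds)), 0L)
  # the methyltransferase family is far below any sensible cutoff, so the
  # alternative pattern does not rescue the cluster either
  expect_equal(nrow(select_clusters_alternative(counts, ds, 2)), 0L)
})

test_that("alternative pattern exempts large families, strict does not", {
  # 5 organisms; an 11-member tailoring family rides along in the cluster
  orgs <- sprintf("o%d", 1:5)
  tail_rows <- data.frame(organism_id = rep(orgs, c(3L, 2L, 2L, 2L, 2L)),
                          protein_id = sprintf("t%02d", 1:11))
  proteins <- rbind(
    data.frame(organism_id = "o1", protein_id = c("bb", "res"),
               stringsAsFactors = FALSE),
    data.frame(organism_id = orgs, protein_id = "ess",
               stringsAsFactors = FALSE),
    tail_rows)
  proteins$length_aa <- 100L; proteins$section <- "S"
  proteins$interpro_ids <- ""
  clusters <- data.frame(cluster_id = "cl", organism_id = "o1",
                         member_rank = 0:2,
                         protein_id = c("bb", "res", "t01"),
                         is_backbone = c(1L, 0L, 0L))
  families <- data.frame(
    family_id = c("Fbb", rep("Fess", 6L), rep("Ftail", 11L)),
    organism_id = c("o1", "o1", orgs, tail_rows$organism_id),
    protein_id = c("bb", "res", rep("ess", 5L), tail_rows$protein_id))
  ds <- frigg_dataset(proteins, clusters, families)
  counts <- compute_homology_counts(ds)

  # strict: the tailoring gene has homologs -> rejected
  expect_equal(nrow(select_clusters_strict(counts, ds)), 0L)
  # x = 2: cutoff 10 < 11 -> family exempt, cluster selected
  sel <- select_clusters_alternative(counts, ds, 2)
  expect_equal(sel$cluster_id, "cl")
  expect_equal(sel$resistance_protein_id, "res")
  expect_equal(sel$exempt_protein_ids, "t01")
  # x = 3: cutoff 15 >= 11 -> exemption lost, cluster rejected
  expect_equal(nrow(select_clusters_alternative(counts, ds, 3)), 0L)
})

test_that("alternative selection reduces to strict when the cutoff tops all families", {
  for (seed in c(21, 22, 23)) {
    gen <- generate_dataset(n_organisms = 6, seed = seed, sequences = FALSE)
    ds <- gen$dataset
    counts <- compute_homology_counts(ds)
    biggest <- max(table(ds$families$family_id))
    x_big <- biggest / nrow(ds$organisms) + 1
    alt <- select_clusters_alternative(counts, ds, x_big)
    strict <- select_clusters_strict(counts, ds)
    expect_equal(cand_key(alt), cand_key(strict))
  }
})

test_that("the recurrence filter keeps only families shared by >= 2 candidate clusters", {
  cands <- data.table(
    cluster_id = c("c1", "c2", "c3"),
    organism_id = c("o1", "o2", "o1"),
    resistance_protein_id = c("r1", "r2", "r3"),
    resistance_family_id = c("FA", "FA", "FB"),
    target_protein_ids = "", exempt_protein_ids = "", pattern = "strict")
  kept <- filter_recurrent(cands)
  expect_setequal(kept$cluster_id, c("c1", "c2"))
  expect_equal(nrow(filter_recurrent(cands[0L])), 0L)

  # same-organism recurrence counts by default, not with the organism flag
  same_org <- copy(cands)[, organism_id := "o1"]
  expect_equal(nrow(filter_recurrent(same_org)), 2L)
  expect_equal(nrow(filter_recurrent(same_org, distinct_organisms = TRUE)),
               0L)
})

test_that("essentiality boundary arithmetic: 46 of 51 organisms", {
  orgs <- sprintf("o%02d", 1:51)
  with_fam <- orgs[1:46]
  proteins <- rbind(
    data.frame(organism_id = with_fam, protein_id = "e1"),
    data.frame(organism_id = orgs, protein_id = "filler"))
  proteins$length_aa <- 100L; proteins$section <- "S"
  proteins$interpro_ids <- ""
  families <- rbind(
    data.frame(family_id = "FE", organism_id = with_fam, protein_id = "e1"),
    data.frame(family_id = paste0("S", orgs), organism_id = orgs,
               protein_id = "filler"))
  ds <- frigg_dataset(proteins, data.frame()[0, ], families)
  cand <- data.table(cluster_id = "c", organism_id = "o01",
                     resistance_protein_id = "e1",
                     resistance_family_id = "FE",
                     target_protein_ids = "", exempt_protein_ids = "",
                     pattern = "strict")
  # 46/51 = 90.2% >= 90 -> retained; < 98 -> removed
  expect_equal(nrow(filter_essential(cand, ds, 90)), 1L)
  expect_equal(nrow(filter_essential(cand, ds, 98)), 0L)
  expect_equal(nrow(filter_essential(cand, ds, 100)), 0L)
})

test_that("step-5 majority boundary is strict: exactly half stays, 26/51 goes", {
  orgs <- sprintf("o%02d", 1:52)
  mk_ds <- function(orgs, multi_orgs) {
    single <- setdiff(orgs, multi_orgs)
    proteins <- rbind(
      data.frame(organism_id = orgs, protein_id = "m1",
                 stringsAsFactors = FALSE),
      if (length(multi_orgs)) data.frame(organism_id = multi_orgs,
                                         protein_id = "m2",
                                         stringsAsFactors = FALSE))
    proteins$length_aa <- 100L; proteins$section <- "S"
    proteins$interpro_ids <- ""
    families <- data.frame(family_id = "FM",
                           organism_id = proteins$organism_id,
                           protein_id = proteins$protein_id)
    frigg_dataset(proteins, data.frame()[0, ], families)
  }
  cand <- data.table(cluster_id = "c", organism_id = "o01",
                     resistance_protein_id = "m1",
                     resistance_family_id = "FM",
                     target_protein_ids = "", exempt_protein_ids = "",
                     pattern = "strict")
  # 26 of 51 organisms multi-copy: 50.98% > 50 -> removed
  ds <- mk_ds(orgs[1:51], orgs[1:26])
  expect_equal(nrow(filter_single_copy(cand, ds, 50)), 0L)
  # exactly half (26 of 52): not "more than 50%" -> retained
  ds <- mk_ds(orgs, orgs[1:26])
  expect_equal(nrow(filter_single_copy(cand, ds, 50)), 1L)
  # all single-copy -> retained
  ds <- mk_ds(orgs[1:51], character())
  expect_equal(nrow(filter_single_copy(cand, ds, 50)), 1L)
})

test_that("run_pipeline produces nested candidate sets and a faithful summary", {
  gen <- generate_dataset(seed = 31, sequences = FALSE)
  for (cfg in list(frigg_config(), frigg_config("alternative", x_input = 2),
                   frigg_config(skip_step3 = TRUE, essential_pct = 98),
                   frigg_config("alternative", x_input = 3,
                                apply_step5 = FALSE))) {
    run <- run_pipeline(gen$dataset, cfg)
    sets <- lapply(run$steps, function(s) s$cluster_id)
    for (i in seq_along(sets)[-1L]) {
      expect_true(all(sets[[i]] %in% sets[[i - 1L]]))
    }
    expect_equal(run$summary$n_clusters,
                 vapply(run$steps, nrow, integer(1)), ignore_attr = TRUE)
    expect_equal(run$summary$n_families,
                 vapply(run$steps, function(s)
                   uniqueN(s$resistance_family_id), integer(1)),
                 ignore_attr = TRUE)
    expect_equal(names(run$steps),
                 c("step2", if (!cfg$skip_step3) "step3", "step4",
                   if (cfg$apply_step5) "step5"))
  }
})

test_that("filters are monotone in their parameters", {
  gen <- generate_dataset(seed = 37, sequences = FALSE)
  ds <- gen$dataset
  counts <- compute_homology_counts(ds)
  cands <- select_clusters_alternative(counts, ds, 2)
  prev <- nrow(cands) + 1L
  for (pct in c(0, 50, 90, 98, 100)) {
    n <- nrow(filter_essential(cands, ds, pct))
    expect_lte(n, prev)
    prev <- n
  }
  prev <- -1L
  for (pct in c(10, 25, 50, 75, 100)) {
    n <- nrow(filter_single_copy(cands, ds, pct))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("combine_runs unions final families and refuses foreign runs", {
  gen <- generate_dataset(seed = 41, sequences = FALSE)
  runs <- run_grid(gen$dataset)
  expect_length(runs, 12L)
  combined <- combine_runs(runs)
  # brute-force union oracle over the final step of each run
  fams <- sort(unique(unlist(lapply(runs, function(r)
    r$steps[[length(r$steps)]]$resistance_family_id))))
  expect_equal(combined$families, fams)
  expect_equal(combined$presence$family_id, fams)
  expect_equal(ncol(combined$presence), 13L)
  # per-cell check against each run's own final set
  for (nm in names(runs)) {
    fin <- unique(runs[[nm]]$steps[[length(runs[[nm]]$steps)]]$resistance_family_id)
    expect_equal(combined$presence[[nm]],
                 as.integer(combined$presence$family_id %in% fin))
  }
  # in_all_runs: flagged families occur in every run
  mat <- as.matrix(combined$presence[, -1L])
  expect_equal(combined$in_all_runs,
               combined$presence$family_id[rowSums(mat) == 12L])

  # identical runs: union equals either
  two <- combine_runs(runs[c(1L, 1L)])
  expect_equal(two$families,
               sort(unique(runs[[1L]]$steps$step5$resistance_family_id)))

  other <- generate_dataset(seed = 42, n_organisms = 5, sequences = FALSE)
  foreign <- run_pipeline(other$dataset, frigg_config())
  expect_error(combine_runs(c(runs[1L], list(foreign))),
               "different datasets")
})

test_that("every step matches its brute-force oracle on random datasets", {
  # part of the oracle-equivalence sweep; the full 100-dataset sweep runs in
  # the acceptance suite
  for (i in 1:10) {
    ds <- random_dataset(seed = 500 + i)
    counts <- compute_homology_counts(ds)
    oc <- oracle_counts(ds)
    got <- as.data.frame(counts[order(organism_id, cluster_id, protein_id)])
    rownames(oc) <- NULL
    expect_equal(got, oc)
    for (pat in c("strict", "alternative")) {
      x <- sample(c(1.5, 2, 3), 1L)
      sel <- if (pat == "strict") select_clusters_strict(counts, ds) else
        select_clusters_alternative(counts, ds, x)
      osel <- oracle_select(ds, pat, x)
      expect_equal(cand_key(sel), cand_key(osel))
      expect_equal(cand_key(filter_recurrent(sel)),
                   cand_key(oracle_recurrent(osel)))
      pct <- sample(c(50, 90, 98), 1L)
      expect_equal(cand_key(filter_essential(sel, ds, pct)),
                   cand_key(oracle_essential(osel, ds, pct)))
      expect_equal(cand_key(filter_single_copy(sel, ds)),
                   cand_key(oracle_single_copy(osel, ds)))
    }
  }
})
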