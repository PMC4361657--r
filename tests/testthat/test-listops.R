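test_that("unique/shared split follows the unidirectional rule", {
  tol <- gene_list(c("g1", "g2"), c("up", "up"))
  ntol <- gene_list(c("g1", "g3"), c("up", "down"))
  u <- derive_unique_lists(tol, ntol)
  expect_equal(u$shared$probe_id, "g1")
  expect_equal(u$unique_tol$probe_id, "g2")
  expect_equal(u$unique_ntol$probe_id, "g3")
  # disjoint lists: nothing shared
  u2 <- derive_unique_lists(gene_list("a", "up"), gene_list("b", "down"))
  expect_equal(nrow(u2$shared), 0)
  expect_equal(u2$unique_tol$probe_id, "a")
  # opposite directions are NOT shared and stay in both unique lists
  u3 <- derive_unique_lists(gene_list("g", "up"), gene_list("g", "down"))
  expect_equal(nrow(u3$shared), 0)
  expect_equal(u3$unique_tol$probe_id, "g")
  expect_equal(u3$unique_ntol$probe_id, "g")
})

test_that("final lists intersect two-group with the unique lists", {
  two <- gene_list(c("g1", "g2", "g3"), c("up", "up", "down"))
  fr <- derive_final_lists(two, gene_list("g1", "up"),
                           gene_list("g3", "up"))
  expect_equal(fr$final_tol$probe_id, "g1")
  expect_equal(fr$final_ntol$probe_id, "g3")
  # non-TOL-unique 'up' matching two-group 'down' is consistent (two-group
  # is TOL-vs-nonTOL), so no conflict flagged for g3
  expect_equal(fr$direction_conflicts, character(0))
  # conflicting direction retained but flagged, vs-control direction kept
  fr2 <- derive_final_lists(two, gene_list("g1", "down"), gene_list(),
                            NULL, NULL)
  expect_equal(fr2$final_tol$probe_id, "g1")
  expect_equal(fr2$final_tol$direction, "down")
  expect_equal(fr2$direction_conflicts, "g1")
  expect_equal(nrow(derive_final_lists(gene_list(), gene_list("a", "up"),
                                       gene_list())$final_tol), 0)
})

test_that("filter algebra invariants hold on random list fixtures", {
  set.seed(77)
  genes <- sprintf("g%03d", 1:60)
  rand_list <- function() {
    n <- sample(0:30, 1)
    gene_list(sample(genes, n), sample(c("up", "down"), n, replace = TRUE))
  }
  key <- function(gl) paste(gl$probe_id, gl$direction)
  for (i in 1:250) {
    a <- rand_list(); b <- rand_list(); two <- rand_list()
    u <- derive_unique_lists(a, b)
    expect_true(all(key(u$shared) %in% key(a)))
    expect_true(all(key(u$shared) %in% key(b)))
    expect_length(intersect(key(u$shared), key(u$unique_tol)), 0)
    expect_length(intersect(key(u$shared), key(u$unique_ntol)), 0)
    expect_setequal(c(key(u$shared), key(u$unique_tol)), key(a))
    expect_setequal(c(key(u$shared), key(u$unique_ntol)), key(b))
    fr <- derive_final_lists(two, u$unique_tol, u$unique_ntol)
    expect_true(all(fr$final_tol$probe_id %in% two$probe_id))
    expect_true(all(fr$final_tol$probe_id %in% u$unique_tol$probe_id))
    expect_true(all(fr$final_ntol$probe_id %in% two$probe_id))
    expect_true(all(fr$final_ntol$probe_id %in% u$unique_ntol$probe_id))
  }
})

test_that("agent confounding check: null overlap, positive control, skip rule", {
  cfg <- sam_config(n_perm = 60, seed = 31)
  # no agent-linked probes planted: every agent list is empty, overlap 0
  d0 <- generate_dataset(sim_config(n_probes = 600, n_tol_up = 20,
                                    n_tol_down = 20, n_ntol_up = 0,
                                    n_ntol_down = 0, n_confounded = 0,
                                    lineage_sets = c(none = 0),
                                    agent_names = c("CNI", "MMF"),
                                    seed = 30))
  p0 <- patients_of(d0)
  fit0 <- run_sam(p0$x, p0$labels, cfg)
  chk0 <- agent_confound_check(d0$x, d0$annotation, fit0$called, cfg)
  expect_setequal(names(chk0), c("CNI", "MMF"))
  for (ag in names(chk0)) expect_equal(chk0[[ag]]$overlap, 0)
  # positive control: strongly agent-linked probes inside the tested list
  d <- generate_dataset(sim_config(n_probes = 600, n_tol_up = 0,
                                   n_tol_down = 0, n_ntol_up = 0,
                                   n_ntol_down = 0, n_confounded = 0,
                                   lineage_sets = c(none = 0),
                                   agent_names = c("CNI", "MMF"),
                                   n_agent_probes = 15,
                                   agent_effect_log2 = 2.5, seed = 31))
  agent_probes <- d$truth$probe_id[d$truth$category == "AGENT:CNI"]
  fake_pheno <- gene_list(agent_probes, rep("up", length(agent_probes)))
  chk2 <- agent_confound_check(d$x, d$annotation, fake_pheno, cfg)
  expect_gte(chk2$CNI$agent_list_size, 10)
  expect_gte(chk2$CNI$overlap, 10)
  expect_true(all(chk2$CNI$overlap_ids %in% agent_probes))
  # an agent with one exposed sample is skipped with a warning
  ann <- d$annotation
  ntl <- which(ann$group == "NONTOL")
  ann$agents[ntl] <- ""
  ann$agents[ntl[1]] <- "rare"
  expect_warning(chk3 <- agent_confound_check(d$x, ann, fake_pheno, cfg),
                 "skipped")
  expect_length(chk3, 0)
})

test_that("paired analysis calls constant-ratio probes exactly", {
  set.seed(12)
  d <- generate_dataset(sim_config(n_probes = 80, n_tol_up = 0,
                                   n_tol_down = 0, n_ntol_up = 0,
                                   n_ntol_down = 0, n_confounded = 0,
                                   lineage_sets = c(none = 0),
                                   pairing = TRUE, seed = 13))
  ann <- d$annotation
  x <- d$x
  pairs <- ann[!is.na(ann$pair_id), ]
  tol_ids <- pairs$sample_id[pairs$group == "TOL"]
  # probe 1: exact +1 log2 ratio in every pair -> called up at fold 2
  for (pid in unique(pairs$pair_id)) {
    two <- pairs[pairs$pair_id == pid, ]
    x["probe_0001", two$sample_id[two$group == "TOL"]] <-
      x["probe_0001", two$sample_id[two$group == "NONTOL"]] + 1
  }
  gl <- paired_analysis(x, ann, min_fold = 1.5, alpha = 0.05)
  expect_true("probe_0001" %in% gl$probe_id)
  expect_equal(gl$direction[gl$probe_id == "probe_0001"], "up")
  # the exact signed-rank p for 15 concordant pairs is 2 * 2^-15
  r <- rep(1, 15)
  expect_equal(wilcox.test(r + rnorm(15, 0, 1e-6), mu = 0,
                           exact = TRUE)$p.value, 2 / 2^15)
  # sign flip reverses directions, keeps membership
  gl2 <- paired_analysis(-x, ann, min_fold = 1.5, alpha = 0.05)
  expect_setequal(gl2$probe_id, gl$probe_id)
  expect_equal(gl2$direction[gl2$probe_id == "probe_0001"], "down")
  expect_error(paired_analysis(x, d$annotation[1:6, ]), "pair")
})

test_that("concordance counts direction-matched membership", {
  a <- gene_list(c("g1", "g2", "g3", "g4"), c("up", "up", "down", "up"))
  b <- gene_list(c("g1", "g3"), c("up", "up"))
  expect_equal(concordance(a, b), 0.25)
  expect_equal(concordance(a, a), 1.0)
  expect_equal(concordance(a, gene_list("z", "up")), 0.0)
  expect_error(concordance(gene_list(), a), "non-empty")
})
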