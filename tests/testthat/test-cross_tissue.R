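dm_frame <- function(ids, deltas) {
  data.frame(probe_id = ids, delta = deltas, stringsAsFactors = FALSE)
}

test_that("overlap intersects the tissue DMCpG sets minus multimap probes", {
  expect_setequal(overlap_dmcpgs(c("a", "b", "c"), c("b", "c", "d")), c("b", "c"))
  expect_length(overlap_dmcpgs(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_dmcpgs(c("b", "c"), c("b", "c"), multimap_blacklist = "c"),
               "b")
})

test_that("direction consistency keeps strictly same-sign deltas only", {
  a <- dm_frame(c("p1", "p2", "p3"), c(-0.12, 0.10, 0.0))
  l <- dm_frame(c("p1", "p2", "p3"), c(-0.11, -0.06, 0.08))
  out <- direction_consistent(c("p1", "p2", "p3"), a, l)
  expect_equal(out$probe_id, "p1")
  expect_equal(out$direction, "hypo")
  expect_equal(out$delta_adipose, -0.12)
  expect_error(direction_consistent("p9", a, l), "p9")
})

test_that("the promoter island/shore filter uses the any-hit rule", {
  cand <- data.frame(
    probe_id = c("c1", "c2", "c3"),
    delta_adipose = c(-0.12, -0.10, -0.11),
    delta_leukocyte = c(-0.11, -0.06, -0.07),
    direction = "hypo", stringsAsFactors = FALSE
  )
  ann <- data.frame(
    probe_id = c("c1", "c2", "c3"),
    chromosome = "1", position = c(10L, 20L, 30L),
    gene_names = c("FGFRL1;FGFRL1;FGFRL1", "MIR1204;PVT1", "GENEX"),
    gene_regions = c("TSS1500;TSS1500;TSS1500", "TSS200;Body", "Body"),
    cpg_context = c("Island", "S_Shore", "OpenSea"),
    probe_class = "cg", snp_within_10bp = FALSE, multi_mapping = FALSE,
    stringsAsFactors = FALSE
  )
  out <- region_filter(cand, ann)
  expect_setequal(out$probe_id, c("c1", "c2"))
  # filtering the already-filtered set changes nothing (idempotence)
  expect_equal(region_filter(out, ann)$probe_id, out$probe_id)
})

test_that("signature selection enforces the strict per-tissue magnitude rule", {
  cand <- data.frame(
    probe_id = c("s1", "s2", "s3"),
    delta_adipose = c(-0.12, 0.12, -0.10),
    delta_leukocyte = c(-0.11, 0.05, -0.04),
    stringsAsFactors = FALSE
  )
  expect_equal(signature_select(cand, similarity_tol = 0.04)$probe_id, "s1")
  expect_equal(signature_select(cand)$probe_id, "s1")   # 0.05 is not > 0.05
  expect_equal(nrow(signature_select(cand[3, ])), 0)
  expect_equal(signature_select(signature_select(cand))$probe_id, "s1")
})

test_that("hierarchical clustering separates block-structured samples", {
  set.seed(5)
  beta <- cbind(matrix(0.1 + rnorm(50 * 6, 0, 0.01), 50, 6),
                matrix(0.9 + rnorm(50 * 4, 0, 0.01), 50, 4))
  colnames(beta) <- sprintf("s%02d", 1:10)
  rownames(beta) <- paste0("p", 1:50)
  cl <- hierarchical_cluster(beta, k = 2)
  expect_length(unique(cl$labels[1:6]), 1)
  expect_length(unique(cl$labels[7:10]), 1)
  expect_false(cl$labels[1] == cl$labels[10])

  # permuting input columns leaves memberships unchanged
  perm <- sample(10)
  cl2 <- hierarchical_cluster(beta[, perm], k = 2)
  expect_equal(cl2$labels[names(cl$labels)], cl$labels)

  expect_warning(flat <- hierarchical_cluster(matrix(0.5, 5, 3,
    dimnames = list(NULL, c("a", "b", "c")))), "constant")
  expect_equal(unname(flat$labels), rep(1L, 3))
})

test_that("clusters on planted-effect cohorts recover the groups (Rand > 0.9)", {
  s <- small_cohort(n_probes = 2500, frac_effect = 0.08, delta = 0.15, seed = 17)
  stage <- run_dm_stage(s$manifest, s$cohort, "leukocyte")
  sig <- stage$calls$probe_id
  expect_gt(length(sig), 50)
  cl <- hierarchical_cluster(stage$filtered$beta[sig, ], k = 2)
  grp <- s$cohort$samples$group[match(names(cl$labels),
                                      s$cohort$samples$sample_id)]
  expect_gt(rand_index(cl$labels, grp), 0.9)
})

test_that("the reference candidate table passes the cascade as a regression fixture", {
  fix <- cross_tissue_candidates()
  expect_equal(nrow(fix), 22)
  dm_a <- dm_frame(fix$probe_id, fix$delta_adipose)
  dm_l <- dm_frame(fix$probe_id, fix$delta_leukocyte)

  consistent <- direction_consistent(fix$probe_id, dm_a, dm_l)
  expect_equal(nrow(consistent), 22)    # every printed row is same-direction

  promoter <- region_filter(consistent, fix)
  expect_equal(nrow(promoter), 21)      # only the 3'UTR-annotated probe drops
  expect_false("cg11381564" %in% promoter$probe_id)

  sig <- signature_select(promoter, min_abs_delta_each = 0.05)
  expect_false("cg07496545" %in% sig$probe_id)  # leukocyte delta exactly 0.05
  expect_true(all(c("cg25932599", "cg22712983", "cg07576222") %in% sig$probe_id))

  # cascade is order-correct: each stage can only shrink the set
  expect_true(nrow(sig) <= nrow(promoter))
  expect_true(nrow(promoter) <= nrow(consistent))
  expect_true(nrow(consistent) <= length(fix$probe_id))
})

test_that("venn counts summarise the overlap cascade", {
  a <- c("p1", "p2", "p3")
  l <- c("p2", "p3", "p4", "p5")
  common <- overlap_dmcpgs(a, l)
  consistent <- direction_consistent(common,
                                     dm_frame(a, c(0.1, 0.2, -0.1)),
                                     dm_frame(l, c(0.2, 0.1, -0.3, 0.1)))
  v <- venn_counts(a, l, common, consistent)
  expect_equal(v$adipose_only, 1)
  expect_equal(v$leukocyte_only, 2)
  expect_equal(v$common, 2)
  expect_equal(v$same_direction, 1)    # p3 has opposite signs
  expect_equal(v$hyper, 1)
  expect_equal(v$hypo, 0)
})
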