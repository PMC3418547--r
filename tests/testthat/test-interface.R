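# Region assignment, divergence reports, clustering significance,
# decoding-state classification, binding compatibility and switch-loop
# inventories.

test_that("region assignment returns every containing interval", {
  tab <- region_table()
  expect_true("switch_loop" %in% assign_region(301, tab))
  expect_true("helix_alpha7" %in% assign_region(301, tab))
  expect_true("recognition_loop" %in% assign_region(186, tab))
  expect_true("domain2" %in% assign_region(186, tab))
  expect_identical(assign_region(9999, tab), character(0))
  expect_error(region_table(switch_loop = c(301, 286)),
               class = "validation_error")
  expect_error(region_table(motifs = list(GGQ = c(5000, 5002))),
               class = "validation_error")
})

test_that("divergence report reproduces the 20/2/1/1 regional partition", {
  g <- gen_alignment(study_alignment_recipe(seed = 1))
  pos <- detect_discriminating_positions(g$alignment)
  ins <- detect_insertions(g$alignment)
  rep <- divergence_report(pos, insertions = ins)
  expect_equal(rep$counts[["domain2"]], 20)
  expect_equal(rep$counts[["switch_loop"]], 2)
  expect_equal(rep$counts[["domain1"]], 1)
  expect_equal(rep$counts[["domain3"]], 1)
  # totals conserved over the disjoint primary assignment
  expect_equal(sum(rep$counts), rep$n_positions)

  empty <- divergence_report(pos[0, , drop = FALSE])
  expect_true(all(empty$counts == 0))

  # planted positions inside one declared region all count there
  one <- pos[pos$ref_position %in% as.character(150:205), , drop = FALSE]
  rep1 <- divergence_report(one)
  expect_equal(rep1$counts[["domain2"]], nrow(one))
  expect_equal(sum(rep1$counts), nrow(one))
})

test_that("divergence report flags structural context when a model is given", {
  g <- gen_alignment(study_alignment_recipe(seed = 1))
  pos <- detect_discriminating_positions(g$alignment)
  m <- rf_switch_loop_model("rf1")        # has residues 286-301 only
  rep <- divergence_report(pos, model = m, chain = "R")
  sw <- rep$positions$ref_position %in% c("298", "301")
  expect_true(all(rep$positions$in_model[sw]))
  expect_false(any(rep$positions$in_model[!sw]))
  expect_error(divergence_report(pos, model = m), class = "precondition_error")
})

test_that("clustering p-value behaves as a permutation test", {
  # extended chain with a planted tight cluster at residues 1..5
  n <- 60
  xyz <- cbind(seq_len(n) * 6, 0, 0)
  xyz[1:5, 1] <- seq(0, 2, length.out = 5)   # tight
  atoms <- data.frame(chain = "A", resno = seq_len(n), resname = "GLY",
                      atom = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  m <- structure_model(atoms)
  expect_lte(clustering_pvalue(m, "A", 1:5, n_permutations = 1000, seed = 1),
             0.01)
  # whole chain: null identical to observed -> p = 1
  expect_equal(clustering_pvalue(m, "A", seq_len(n), n_permutations = 200,
                                 seed = 1), 1)
  expect_error(clustering_pvalue(m, "A", 1:2), class = "precondition_error")
  expect_error(clustering_pvalue(m, "A", 1:5, n_permutations = 10),
               class = "precondition_error")
  # p-values roughly uniform for random subsets
  set.seed(99)
  ps <- replicate(200, clustering_pvalue(m, "A", sample(n, 6),
                                         n_permutations = 100,
                                         seed = sample.int(1e6, 1)))
  # discrete add-one p-values tie at multiples of 1/101; the KS distance
  # from that discreteness is far below the rejection threshold
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("decoding-state classifier is self-consistent and pose-invariant", {
  tpl <- decoding_center_templates()
  for (s in names(tpl)) {
    expect_equal(as.character(classify_decoding_state(tpl[[s]])), s)
  }
  set.seed(3)
  for (s in names(tpl)) {
    moved <- apply_transform(tpl[[s]], random_rigid_transform())
    expect_equal(as.character(classify_decoding_state(moved)), s)
  }
  # missing nucleotide -> resolution error
  broken <- tpl$stacked
  broken$atoms <- broken$atoms[broken$atoms$resno != 1493, ]
  expect_error(classify_decoding_state(broken), class = "resolution_error")
})

test_that("mtRF1 compatibility flips between stacked and recognized states", {
  mtrf1 <- rf_switch_loop_model("mtrf1")
  v_stacked <- binding_compatibility(mtrf1, decoding_center_template("stacked"))
  expect_true(v_stacked$compatible)
  expect_equal(nrow(v_stacked$clashes), 0)
  v_rec <- binding_compatibility(mtrf1, decoding_center_template("recognized"))
  expect_false(v_rec$compatible)
  # the clashes are the RT-insert arginine against A-1493
  expect_true(all(grepl("^R:115A:", v_rec$clashes$atom_a) |
                    grepl("^R:115A:", v_rec$clashes$atom_b)))
  expect_true(any(grepl("^A:1493:", v_rec$clashes$atom_a) |
                    grepl("^A:1493:", v_rec$clashes$atom_b)))
  # canonical rf1 is compatible with the recognized state
  rf1 <- rf_switch_loop_model("rf1")
  expect_true(binding_compatibility(rf1,
                                    decoding_center_template("recognized"))$compatible)
  # verdict consistency: compatible <=> empty clash list
  expect_identical(v_rec$compatible, nrow(v_rec$clashes) == 0L)
})

test_that("compatibility verdict is monotone in the clash threshold", {
  mtrf1 <- rf_switch_loop_model("mtrf1")
  ribo <- decoding_center_template("recognized")
  thresholds <- c(0.1, 0.4, 1.0, 2.0, 3.5)
  compat <- vapply(thresholds, function(th)
    binding_compatibility(mtrf1, ribo, overlap_threshold = th)$compatible,
    logical(1))
  expect_true(all(diff(as.integer(compat)) >= 0))
})

test_that("far-away release factor is trivially compatible", {
  far <- structure_model(data.frame(
    chain = "R", resno = 1:3, resname = "GLY", atom = "CA",
    x = 500 + 1:3 * 4, y = 500, z = 500, stringsAsFactors = FALSE))
  v <- binding_compatibility(far, decoding_center_template("recognized"))
  expect_true(v$compatible)
  expect_equal(nrow(v$clashes), 0)
})

test_that("switch-loop inventory labels partners by class", {
  # canonical complex: Glu-297 <-> A-1493 and Thr-295 <-> A-1914
  c_rf1 <- synthetic_rf_complex("rf1", "recognized")
  inv1 <- switch_loop_interactions(c_rf1)
  expect_true(any(inv1$loop_position == 297 & inv1$partner == "A:1493:N6" &
                    inv1$partner_class == "decoding_center"))
  expect_true(any(inv1$loop_position == 295 & inv1$loop_atom == "OG1" &
                    inv1$partner == "B:1914:N1" &
                    inv1$partner_class == "decoding_center"))

  # mtRF1 with empty A-site: R-RTi takes over at position 295
  c_mt <- synthetic_rf_complex("mtrf1", "stacked")
  inv2 <- switch_loop_interactions(c_mt, insert_residues = "115A")
  ins_bonds <- inv2[inv2$partner_class == "insert", ]
  expect_true(any(ins_bonds$loop_position == 295 & ins_bonds$loop_atom == "O"))
  # without the insert annotation the same bonds are intramolecular
  inv2b <- switch_loop_interactions(c_mt)
  expect_false(any(inv2b$partner_class == "insert"))

  # a loop with no partner within the window gives an empty inventory
  lonely <- rf_switch_loop_model("mtrf1")
  lonely$atoms <- lonely$atoms[lonely$atoms$resno >= 286, ]  # drop R-RTi
  inv3 <- switch_loop_interactions(lonely)
  expect_equal(nrow(inv3), 0)
})

test_that("helix-capping partners are classified as such", {
  atoms <- rbind(
    data.frame(chain = "R", resno = 290, resname = "SER", atom = "OG",
               x = 0, y = 0, z = 0, stringsAsFactors = FALSE),
    data.frame(chain = "R", resno = 301, resname = "ARG", atom = "NH1",
               x = 2.9, y = 0, z = 0, stringsAsFactors = FALSE))
  m <- structure_model(atoms)
  inv <- switch_loop_interactions(m)
  expect_equal(nrow(inv), 1)
  expect_equal(inv$partner_class, "helix_capping")
  expect_equal(inv$loop_position, 290)
})

test_that("interaction replacement reports matches both ways", {
  c_rf1 <- synthetic_rf_complex("rf1", "recognized")
  inv1 <- switch_loop_interactions(c_rf1)
  self <- interaction_replacement(inv1, inv1)
  expect_true(all(self$matched))
  expect_true(all(self$same_partner))

  dropped <- inv1[inv1$loop_position != 297, , drop = FALSE]
  rep2 <- interaction_replacement(inv1, dropped)
  expect_equal(sum(!rep2$matched), 1)
  expect_equal(rep2$loop_position[!rep2$matched], 297)

  # the A-1493-mediated position-295 interaction of the canonical
  # complex is replaced (different partner) by R-RTi in mtRF1
  c_mt <- synthetic_rf_complex("mtrf1", "stacked")
  inv2 <- switch_loop_interactions(c_mt, insert_residues = "115A")
  rep3 <- interaction_replacement(inv1, inv2)
  row295 <- rep3[rep3$loop_position == 295, ]
  expect_true(row295$matched)
  expect_false(row295$same_partner)
  expect_match(row295$partners_b, "R:115A")
  expect_false(rep3$matched[rep3$loop_position == 297])
})
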