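test_that("the collinear worked example scores 87.5 / 87.5 / 75.0", {
  ref <- ca_model(c(0, 4, 8))
  mod <- ca_model(c(0, 4, 9))
  for (method in c("fast", "reference")) {
    p <- compute_lddt(ref, mod, method = method)
    expect_equal(unname(p$per_residue), c(87.5, 87.5, 75.0))
    expect_equal(p$model_level, 250 / 3, tolerance = 1e-12)
  }
})

test_that("inclusion pairs follow the reference-structure radius rule", {
  ref <- ca_model(c(0, 4, 8))
  p1 <- inclusion_pairs(ref, 1)
  expect_setequal(p1$resno_j, c(2, 3))
  expect_equal(sort(p1$d_ref), c(4, 8))
  # spacing 20: residue 1 has no partner within 15
  far <- ca_model(c(0, 20, 40))
  expect_equal(nrow(inclusion_pairs(far, 1)), 0)
  single <- ca_model(matrix(c(0, 0, 0), 1))
  expect_equal(nrow(inclusion_pairs(single, 1)), 0)
  expect_error(inclusion_pairs(ref, 99), "not present")
})

test_that("self-scoring and rigid motions give exactly 100", {
  ref <- make_backbone(20, seed = 1)
  p <- compute_lddt(ref, ref)
  expect_true(all(p$per_residue == 100))
  expect_equal(p$model_level, 100)
  set.seed(7)
  moved <- transform_model(ref, random_rotation(), rnorm(3, sd = 20))
  p2 <- compute_lddt(ref, moved, lddt_config(mode = "all_atom"))
  expect_true(all(p2$per_residue == 100))
})

test_that("scoring is asymmetric in reference and model", {
  # a pair at 14.5 A in one frame but 15.5 A in the other crosses the
  # inclusion radius in only one direction
  a <- ca_model(c(0, 7, 14.5))
  b <- ca_model(c(0, 7, 15.5))
  pab <- compute_lddt(a, b)
  pba <- compute_lddt(b, a)
  expect_false(isTRUE(all.equal(pab$per_residue, pba$per_residue)))
})

test_that("atoms absent from the model are dropped from both sides of the ratio", {
  ref <- make_backbone(8, seed = 2)
  # model = reference minus all CB atoms: remaining distances are perfect
  at <- ref$atoms[ref$atoms$elety != "CB", ]
  mod <- structure_model(at, sequence = ref$sequence)
  p <- compute_lddt(ref, mod, lddt_config(mode = "all_atom"))
  expect_true(all(p$per_residue == 100))
})

test_that("per-residue scores are rationals over 4 x n_pairs", {
  set.seed(3)
  ref <- make_backbone(10, seed = 31)
  dec <- make_decoy(ref, synthetic_spec(10, data.frame(start = 1, end = 10,
                                                       sigma = 2)), seed = 5)
  p <- compute_lddt(ref, dec$model)
  for (i in seq_len(10)) {
    np <- nrow(inclusion_pairs(ref, i))
    expect_equal(p$per_residue[[i]] * 4 * np / 100,
                 round(p$per_residue[[i]] * 4 * np / 100), tolerance = 1e-9)
  }
})

test_that("fast and brute-force scorers agree on random decoys", {
  for (k in 1:12) {
    L <- sample(5:30, 1)
    ref <- make_backbone(L, seed = 100 + k)
    dec <- make_decoy(ref, synthetic_spec(L, data.frame(start = 1, end = L,
                                                        sigma = 1.5)),
                      seed = 200 + k)
    for (mode in c("calpha", "all_atom")) {
      cfg <- lddt_config(mode = mode)
      expect_equal(compute_lddt(ref, dec$model, cfg, "fast")$per_residue,
                   compute_lddt(ref, dec$model, cfg, "reference")$per_residue,
                   tolerance = 1e-12)
    }
  }
})

test_that("sequence separation and threshold options are honored", {
  ref <- ca_model(c(0, 4, 8))
  mod <- ca_model(c(0, 4, 9))
  # min separation 1 removes the (1,2),(2,3) neighbor pairs
  cfg <- lddt_config(min_sequence_separation = 1)
  p <- compute_lddt(ref, mod, cfg)
  # residue 1: only pair (1,3), diff 1.0 -> 3/4
  expect_equal(p$per_residue[["1"]], 75)
  # single threshold
  cfg2 <- lddt_config(thresholds = 2)
  p2 <- compute_lddt(ref, mod, cfg2)
  expect_equal(unname(p2$per_residue), c(100, 100, 100))
})

test_that("residue and model errors follow the absolute-difference rules", {
  pr <- function(v) egnnqa:::new_lddt_profile(setNames(v, seq_along(v)))
  pred <- pr(c(90, 80, 70))
  true <- pr(c(87.5, 87.5, 75))
  expect_equal(residue_error(pred, true, 1), 2.5)
  expect_equal(residue_error(pr(70), pr(75), 1), 5)
  expect_equal(residue_error(pred, pred, 2), 0)
  expect_equal(model_error(pred, true), 5)
  expect_equal(model_error(true, true), 0)
  # intersection rule: only residues defined in both contribute
  a <- egnnqa:::new_lddt_profile(c("1" = 90, "2" = 80, "3" = NA))
  b <- egnnqa:::new_lddt_profile(c("1" = NA, "2" = 70, "3" = 75))
  expect_equal(model_error(a, b), 10)
  expect_error(model_error(pr(50), egnnqa:::new_lddt_profile(c("9" = 50))),
               "no residue")
})

test_that("category boundaries assign downward", {
  expect_equal(lddt_category(c(91, 90, 70.5, 70, 50.5, 50, 0, 100)),
               c(">90", "70-90", "70-90", "50-70", "50-70", "<50", "<50", ">90"))
  expect_error(lddt_category(101), "must lie")
  expect_error(lddt_category(-1), "must lie")
})
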