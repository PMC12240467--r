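# a GPR-only model (no stoichiometry rows) carrying the worked-example rules,
# used to exercise knockout -> blocked-reaction semantics
toy_table_model <- function() {
  toy <- toy_fixture()
  rxns <- names(toy$gpr_strings)
  metabolic_model(id = "toy_table", metabolites = character(0),
                  reactions = rxns, S = matrix(0, 0, length(rxns)),
                  lb = rep(0, length(rxns)), ub = rep(1000, length(rxns)),
                  gpr_strings = toy$gpr_strings, genes = toy$genes)
}

test_that("max_biomass solves the growth LP and flags degenerate models", {
  m <- diamond_model()
  expect_equal(max_biomass(m), 10, tolerance = 1e-8)
  expect_equal(max_biomass(apply_medium(m, "R_up")), 0)
  m2 <- m; m2$biomass_reaction <- NA_character_
  expect_error(max_biomass(m2), "no biomass reaction")
})

test_that("lethality and coupling targets are built and validated", {
  m <- diamond_model()
  t <- build_lethality_target(m, p = 0.01)
  expect_equal(t$biomass_max, 10, tolerance = 1e-8)
  expect_equal(t$b, 0.1, tolerance = 1e-10)
  # limit case p = 1 still feasible (wild type attains the maximum)
  expect_s3_class(build_lethality_target(m, p = 1), "target_spec")
  expect_error(build_lethality_target(m, p = 0), "p > 0")
  expect_error(build_lethality_target(apply_medium(m, "R_up")),
               "maximal biomass is 0")
  # coupling target with the product being biomass itself: empty region
  expect_error(build_coupling_target(m, "R_bio"), "infeasible")
  expect_error(build_coupling_target(m, "R_none"), "not in model")

  mc <- coupling_toy_model()
  tc <- build_coupling_target(mc, "R_ex_p", p = 0.01)
  expect_equal(nrow(tc$A), 3)  # v_r = 0 encoded as two inequality rows
})

test_that("blocked_reactions follows the GPR truth table", {
  m <- toy_table_model()
  expect_equal(blocked_reactions(m, "g0"), c("r0", "r7"))
  expect_equal(blocked_reactions(m, "g5"), character(0))
  expect_equal(blocked_reactions(m, character(0)), character(0))
  expect_equal(blocked_reactions(m, c("g5", "g6", "g7")), "r7")
  expect_equal(blocked_reactions(m, c("g1", "g3")), c("r1", "r2", "r4", "r9"))
  expect_error(blocked_reactions(m, "gX"), "unknown gene")
})

test_that("is_gcs/find_witness satisfy the oracle contract on the toy", {
  toy <- toy_fixture()
  orc <- enumerated_oracle(toy$supports, toy$reaction_families, toy$genes)
  expect_true(orc$is_gcs("g0"))
  expect_false(orc$is_gcs("g1"))
  expect_true(orc$is_gcs(toy$genes))  # cutting everything cuttable cuts T
  expect_null(orc$find_witness("g0"))
  w <- orc$find_witness("g1")
  expect_false(is_cutset_for_mode("g1", orc$mode_family(w$support)))
  w3 <- orc$find_witness("g3")
  expect_false(is_cutset_for_mode("g3", orc$mode_family(w3$support)))
})

test_that("LP is_gcs and witnesses are mutually consistent on the diamond", {
  m <- diamond_model()
  t <- build_lethality_target(m, p = 0.01)
  expect_false(is_gcs(t, "g1"))
  expect_true(is_gcs(t, c("g1", "g2")))
  expect_true(is_gcs(t, c("g4", "g5")))
  expect_null(find_witness(t, c("g4", "g5")))

  w <- find_witness(t, "g1")
  # witness satisfies the target rows and carries no flux through blocked rxns
  expect_true(all(t$A %*% w$flux >= t$b - 1e-7))
  expect_true(all(abs(w$flux[blocked_reactions(m, "g1")]) < 1e-7))
  expect_true(all(abs(m$S %*% w$flux) < 1e-7))
})

test_that("LP oracle agrees with the enumerated elementary-mode oracle", {
  m <- diamond_model()
  t <- build_lethality_target(m, p = 0.01)
  fams <- model_reaction_families(m)
  orc <- enumerated_oracle(diamond_efm_supports(), fams, m$genes)
  for (G in all_subsets(m$genes, 3)) {
    expect_equal(is_gcs(t, G), orc$is_gcs(G),
                 info = paste(G, collapse = ","))
  }
})

test_that("classify_intervention separates the two intervention classes", {
  mc <- coupling_toy_model()
  bm <- max_biomass(mc)
  expect_equal(bm, 10, tolerance = 1e-8)
  # blocking the plain route leaves growth via the co-producing route
  expect_equal(classify_intervention(mc, "ga", p = 0.01, biomass_max = bm),
               "coupling-enforcing")
  # blocking biomass directly kills growth
  expect_equal(classify_intervention(mc, "gb", p = 0.01, biomass_max = bm),
               "biomass-blocking")
  # empty knockout: growth equals wild type
  expect_equal(classify_intervention(mc, character(0), p = 0.01,
                                     biomass_max = bm), "coupling-enforcing")
})

test_that("coupling workflow finds and classifies the toy interventions", {
  mc <- coupling_toy_model()
  tc <- build_coupling_target(mc, "R_ex_p", p = 0.01)
  catalog <- compute_gmcs(lp_oracle(tc), k_max = 2)
  catalog <- classify_catalog(catalog, mc, p = 0.01)
  sets <- catalog_sets(catalog)
  expect_true(family_equal(gene_set_family(sets),
                           gene_set_family(list("ga", "gb"))))
  expect_equal(unname(catalog$classification[gmcskit:::set_key("ga")]),
               "coupling-enforcing")
  expect_equal(unname(catalog$classification[gmcskit:::set_key("gb")]),
               "biomass-blocking")
})

test_that("max growth under knockout agrees with scipy on the coupling toy", {
  mc <- coupling_toy_model()
  for (G in list(character(0), "ga", "gb", c("ga", "gc"))) {
    lb <- mc$lb; ub <- mc$ub
    blocked <- blocked_reactions(mc, G)
    lb[blocked] <- 0; ub[blocked] <- 0
    obj <- as.numeric(mc$reactions == mc$biomass_reaction)
    ref <- scipy_lp(obj, as.matrix(mc$S), rep(0, nrow(mc$S)), lb, ub)
    mine <- gmcskit:::lp_solve(obj, Aeq = as.matrix(mc$S),
                               beq = rep(0, nrow(mc$S)), lb = lb, ub = ub)
    expect_equal(mine$status, ref$status)
    expect_equal(mine$objval, ref$objval, tolerance = 1e-6)
  }
})
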