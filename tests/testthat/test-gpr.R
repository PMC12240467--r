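test_that("parse_gpr handles precedence, synonyms, and the empty rule", {
  e <- parse_gpr("g0 and (g5 or g6 or g7)")
  expect_equal(e$kind, "and")
  expect_equal(e$children[[1]]$gene, "g0")
  expect_equal(e$children[[2]]$kind, "or")
  expect_equal(vapply(e$children[[2]]$children, function(c) c$gene, ""),
               c("g5", "g6", "g7"))

  e9 <- parse_gpr("(g1 and g2) or (g3 and g4)")
  expect_equal(e9$kind, "or")
  expect_true(all(vapply(e9$children, function(c) c$kind, "") == "and"))

  # and binds tighter than or
  e2 <- parse_gpr("a or b and c")
  expect_equal(e2$kind, "or")
  expect_equal(e2$children[[2]]$kind, "and")

  # symbol synonyms, case-insensitive keywords
  expect_equal(format(parse_gpr("a & b | c")), format(parse_gpr("a AND b OR c")))

  expect_equal(parse_gpr("")$kind, "empty")
  expect_equal(parse_gpr(NA_character_)$kind, "empty")

  # idempotent under re-serialization
  for (s in c("g0 and (g5 or g6 or g7)", "(g1 and g2) or (g3 and g4)",
              "a or b and c", "(a or b) and (c or d) and e")) {
    expect_equal(format(parse_gpr(format(parse_gpr(s)))), format(parse_gpr(s)))
  }
})

test_that("parse_gpr reports the offending position on malformed rules", {
  expect_error(parse_gpr("g1 and (g2 or g3"), "unbalanced.*position 8")
  expect_error(parse_gpr("g1 and"), "end of rule")
  expect_error(parse_gpr("g1 g2"), "unexpected 'g2' at position 4")
  expect_error(parse_gpr("and g1"), "expected gene")
  expect_error(parse_gpr("g1 or ) g2"), "position 7")
})

test_that("to_dnf produces absorbed, equivalent summands", {
  t9 <- to_dnf(parse_gpr("(g1 and g2) or (g3 and g4)"))
  expect_setequal(vapply(t9, paste, "", collapse = ","), c("g1,g2", "g3,g4"))

  expect_equal(to_dnf(parse_gpr("g4")), list("g4"))

  # distribution case, frozen from truth-table equivalence over a,b,c:
  # AND(OR(a,b), c) is true iff (a&c)|(b&c)
  td <- to_dnf(parse_gpr("(a or b) and c"))
  expect_setequal(vapply(td, paste, "", collapse = ","), c("a,c", "b,c"))

  # absorption: a or (a and b) == a
  expect_equal(to_dnf(parse_gpr("a or (a and b)")), list("a"))

  expect_error(to_dnf(parse_gpr("")), "empty rule")
  # explosion guard fires loudly
  wide <- paste(sprintf("(a%d or b%d)", 1:8, 1:8), collapse = " and ")
  expect_error(to_dnf(parse_gpr(wide), max_terms = 10), "rule too complex")
})

test_that("dnf_to_cnf_factors matches worked and brute-force factorizations", {
  f9 <- dnf_to_cnf_factors(list(c("g1", "g2"), c("g3", "g4")))
  expect_true(family_equal(f9, gene_set_family(list(
    c("g1", "g3"), c("g1", "g4"), c("g2", "g3"), c("g2", "g4")))))

  expect_true(family_equal(dnf_to_cnf_factors(list("a")),
                           gene_set_family(list("a"))))

  # frozen from brute-force hitting-set enumeration of the two terms
  f <- dnf_to_cnf_factors(list(c("a", "b", "c", "d"), c("a", "b", "c", "e")))
  expect_true(family_equal(f, gene_set_family(list("a", "b", "c", c("d", "e")))))

  expect_error(dnf_to_cnf_factors(list()), "empty term list")
})

test_that("reaction_gmcs covers CNF rules, caps, and the empty rule", {
  r7 <- parse_gpr("g0 and (g5 or g6 or g7)")
  expect_true(family_equal(reaction_gmcs(r7),
                           gene_set_family(list("g0", c("g5", "g6", "g7")))))
  expect_true(family_equal(reaction_gmcs(r7, k = 1),
                           gene_set_family(list("g0"))))
  expect_equal(length(reaction_gmcs(parse_gpr(""))), 0L)
  # cap applied after reduction: capped family is the <=k slice of uncapped
  r <- parse_gpr("(a and b) or (a and c) or d")
  unc <- reaction_gmcs(r)
  for (k in 1:3) {
    expect_true(family_equal(
      reaction_gmcs(r, k = k),
      gene_set_family(unc$members[lengths(unc$members) <= k])))
  }
})

test_that("reduce_family is idempotent, order-invariant, minimal", {
  expect_true(family_equal(reduce_family(list(c("g0"), c("g0", "g1"))),
                           gene_set_family(list("g0"))))
  expect_equal(length(reduce_family(list())), 0L)

  toy <- toy_fixture()
  fam <- reduce_family(unlist(lapply(toy$reaction_families[c("r0", "r1", "r4", "r7")],
                                     as.list), recursive = FALSE))
  expect_true(family_equal(fam, gene_set_family(list(
    "g0", "g1", "g3", c("g5", "g6", "g7")))))

  set.seed(7)
  for (i in 1:10) {
    members <- lapply(1:8, function(j) sample(letters[1:6], sample.int(4, 1)))
    a <- reduce_family(members)
    b <- reduce_family(sample(members))
    expect_true(family_equal(a, b))
    expect_true(family_equal(a, reduce_family(a)))
    # every kept member is minimal, every dropped member contains a kept one
    for (m in members) {
      covered <- any(vapply(a$members, function(h) all(h %in% m), NA))
      expect_true(covered)
    }
  }
})

test_that("evaluate_gpr implements knockout semantics", {
  r7 <- parse_gpr("g0 and (g5 or g6 or g7)")
  expect_false(evaluate_gpr(r7, "g0"))
  expect_true(evaluate_gpr(r7, "g5"))
  expect_false(evaluate_gpr(r7, c("g5", "g6", "g7")))
  expect_true(evaluate_gpr(r7, character(0)))
  expect_true(evaluate_gpr(parse_gpr(""), c("g0", "g1")))
})

test_that("property: CNF from dnf_to_cnf_factors is truth-table equivalent", {
  set.seed(42)
  for (rep in 1:25) {
    genes <- paste0("x", seq_len(sample(3:7, 1)))
    rule <- parse_gpr(random_rule(genes, depth = 3))
    used <- gpr_genes(rule)
    cnf <- dnf_to_cnf_factors(to_dnf(rule))
    n <- length(used)
    for (mask in 0:(2^n - 1)) {
      true_genes <- used[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      expect_equal(cnf_eval(cnf, true_genes),
                   evaluate_gpr(rule, setdiff(used, true_genes)))
    }
  }
})

test_that("property: reaction_gmcs equals brute-force minimal falsifiers", {
  set.seed(43)
  for (rep in 1:15) {
    genes <- paste0("y", seq_len(sample(3:6, 1)))
    rule <- parse_gpr(random_rule(genes, depth = 3))
    used <- gpr_genes(rule)
    falsifiers <- Filter(function(G) !evaluate_gpr(rule, G),
                         all_subsets(used, length(used)))
    expect_true(family_equal(reaction_gmcs(rule), gene_set_family(falsifiers)))
  }
})
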