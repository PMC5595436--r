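test_that("formula parsing handles counts, implicit ones and bad input", {
  expect_equal(unclass(parse_formula("C12H22O11"))[c("C", "H", "O")],
               c(C = 12L, H = 22L, O = 11L))
  f <- parse_formula("NH3")
  expect_equal(unclass(f)[c("N", "H")], c(N = 1L, H = 3L))
  expect_equal(unclass(f)[["C"]], 0L)
  expect_error(parse_formula("C12H22O11X"), "unknown element")
  expect_error(parse_formula("C0H2"), "zero or negative")
  expect_error(parse_formula(""), "non-empty")
})

test_that("formula masses match tabulated atomic values", {
  expect_identical(formula_mass(parse_formula("C6H12O6"), "nominal"), 180)
  expect_equal(formula_mass(parse_formula("C12H22O11")), 342.1162,
               tolerance = 0.0005 / 342)
  expect_equal(formula_mass(chem_formula()), 0)
})

test_that("formula arithmetic is element-wise and never goes negative", {
  a <- parse_formula("C6H12O6")
  expect_equal(formula_add(a, a), parse_formula("C12H24O12"))
  expect_equal(formula_subtract(parse_formula("C12H22O11"), a),
               parse_formula("C6H10O5"))
  expect_error(formula_subtract(a, parse_formula("C7H12O6")), "negative")
})

test_that("composition mass and chain-count bounds follow the sugar core", {
  comp <- compose_acylsugar("sucrose", c("aiC5", "aiC5", "aiC5"))
  expect_equal(comp$neutral_mass, 594.2887, tolerance = 0.001 / 594)
  bare <- compose_acylsugar("sucrose", character())
  expect_equal(bare$neutral_mass, formula_mass(parse_formula("C12H22O11")))
  expect_error(compose_acylsugar("hexose", rep("C2", 6)), "too many chains")
})

test_that("composition mass is additive in the chains to 1e-9 Da", {
  set.seed(42)
  ab <- default_chain_alphabet()
  for (rep in 1:20) {
    a <- sample(ab$label, sample(0:3, 1), replace = TRUE)
    b <- sample(ab$label, sample(1:3, 1), replace = TRUE)
    lhs <- compose_acylsugar("sucrose", c(a, b))$neutral_mass
    rhs <- compose_acylsugar("sucrose", a)$neutral_mass +
      sum(vapply(b, function(l)
        formula_mass(chain_net_addition(acyl_chain(l)$carbons)), numeric(1)))
    expect_equal(lhs, rhs, tolerance = 1e-9 / lhs)
  }
})

test_that("branch isomers are mass-degenerate and share a name", {
  x <- compose_acylsugar("sucrose", c("iC5", "iC5", "C2"))
  y <- compose_acylsugar("sucrose", c("aiC5", "aiC5", "C2"))
  expect_identical(x$neutral_mass, y$neutral_mass)
  expect_identical(acylsugar_name(x), acylsugar_name(y))
})

test_that("acylsugar names print and parse as the field's Sn:m(...) strings", {
  expect_identical(acylsugar_name(compose_acylsugar("sucrose", c("iC5", "iC5", "iC5"))),
                   "S3:15(5,5,5)")
  expect_identical(acylsugar_name(compose_acylsugar("sucrose", "iC6")), "S1:6(6)")
  p <- parse_acylsugar_name("S4:17(2,5,5,5)")
  expect_identical(p$n_chains, 4L)
  expect_identical(p$total_carbons, 17L)
  expect_identical(p$carbons, c(2L, 5L, 5L, 5L))
  expect_error(parse_acylsugar_name("S4:17"), "malformed")
  expect_error(parse_acylsugar_name("S2:9(4,6)"), "does not match sum")
})

test_that("name -> parse -> name round-trips for random compositions", {
  set.seed(7)
  ab <- default_chain_alphabet()
  for (rep in 1:50) {
    n <- sample(0:8, 1)
    comp <- compose_acylsugar("sucrose", sample(ab$label, n, replace = TRUE))
    nm <- acylsugar_name(comp)
    p <- parse_acylsugar_name(nm)
    expect_identical(p$n_chains, n)
    expect_identical(p$carbons, sort(as.integer(comp$chains$carbons)))
    expect_identical(acylsugar_name(composition_from_name(nm)), nm)
  }
})

test_that("nominal mass equals rounded monoisotopic mass for CHNO species", {
  ab <- default_chain_alphabet()
  forms <- c(lapply(unique(ab$carbons), chain_net_addition),
             list(sugar_core("sucrose")$formula, sugar_core("hexose")$formula,
                  compose_acylsugar("sucrose", rep("nC12", 2))$formula))
  for (f in forms)
    expect_identical(formula_mass(f, "nominal"), round(formula_mass(f)))
})

test_that("adduct m/z shifts match independent ion-mass arithmetic", {
  expect_equal(adduct_mz(594.2887, "[M+NH4]+"), 612.3231, tolerance = 0.001 / 612)
  expect_equal(adduct_mz(0, "[M-H]-"), -1.0073, tolerance = 0.001)
  expect_equal(adduct_mz(594.2887, "[M+HCOO]-"), 639.2868, tolerance = 0.001 / 639)
  expect_error(adduct_mz(594, "[M+NH4]+", polarity = "-"), "polarity")
})

test_that("chain alphabets load from JSON and match the built-in default", {
  path <- system.file("extdata", "chain_alphabet.json", package = "acylsugar")
  ab <- load_chain_alphabet(path)
  def <- default_chain_alphabet()
  expect_identical(ab$label, def$label)
  expect_identical(ab$carbons, def$carbons)
  expect_identical(ab$branch, def$branch)
})
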