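test_that("decomposition recovers a constructed composition exactly", {
  ab <- default_chain_alphabet()
  aiC5_only <- ab[ab$label == "aiC5", , drop = FALSE]
  comp <- compose_acylsugar("sucrose", c("aiC5", "aiC5", "aiC5"))
  hits <- decompose_mass(adduct_mz(comp, "[M+HCOO]-"), "[M+HCOO]-", tol_ppm = 5,
                         alphabet = aiC5_only, min_chains = 3)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$name, "S3:15(5,5,5)")
})

test_that("a di-acylsucrose mass expands to its carbon partitions", {
  ab <- default_chain_alphabet()
  short <- ab[ab$set == "short", , drop = FALSE]
  comp <- compose_acylsugar("sucrose", c("C2", "C8"))
  hits <- decompose_mass(adduct_mz(comp, "[M+HCOO]-"), "[M+HCOO]-", tol_ppm = 5,
                         alphabet = short, min_chains = 2, max_chains = 2)
  expect_setequal(hits$carbons, c("2,8", "4,6", "5,5"))
})

test_that("the chain-count floor rejects the bare sugar", {
  mz <- adduct_mz(formula_mass(parse_formula("C12H22O11")), "[M+HCOO]-")
  expect_identical(nrow(decompose_mass(mz, "[M+HCOO]-", tol_ppm = 5)), 0L)
})

test_that("decomposition equals exhaustive enumeration on random targets", {
  set.seed(11)
  ab <- default_chain_alphabet()
  add <- adduct("[M+HCOO]-")
  for (rep in 1:25) {
    # half the targets sit on a real composition (plus jitter), half are random
    target <- if (rep %% 2 == 0) {
      comp <- compose_acylsugar("sucrose",
                                sample(ab$label, sample(2:6, 1), replace = TRUE))
      adduct_mz(comp, add) * (1 + runif(1, -4e-6, 4e-6))
    } else runif(1, 450, 1500)
    got <- sort(unique(decompose_mass(target, add, tol_ppm = 5)$name))
    expect_identical(got, oracle_decompose(target, add, 5))
  }
})

test_that("every annotation is sound and tolerance/alphabet are monotone", {
  set.seed(12)
  ab <- default_chain_alphabet()
  short <- ab[ab$set == "short", , drop = FALSE]
  add <- adduct("[M+HCOO]-")
  for (rep in 1:10) {
    comp <- compose_acylsugar("sucrose",
                              sample(ab$label, sample(2:6, 1), replace = TRUE))
    mz <- adduct_mz(comp, add) * (1 + runif(1, -3e-6, 3e-6))
    tight <- decompose_mass(mz, add, tol_ppm = 2)
    loose <- decompose_mass(mz, add, tol_ppm = 10)
    expect_true(all(abs(loose$mz - mz) / mz * 1e6 <= 10))
    expect_true(all(tight$name %in% loose$name))
    expect_true(all(decompose_mass(mz, add, tol_ppm = 5, alphabet = short)$name
                    %in% decompose_mass(mz, add, tol_ppm = 5)$name))
  }
})

test_that("branch expansion only multiplies labels, never partitions", {
  comp <- compose_acylsugar("sucrose", c("iC5", "iC6"))
  mz <- adduct_mz(comp, "[M+HCOO]-")
  collapsed <- decompose_mass(mz, "[M+HCOO]-", 5, min_chains = 2, max_chains = 2)
  expanded <- decompose_mass(mz, "[M+HCOO]-", 5, min_chains = 2, max_chains = 2,
                             collapse_branch = FALSE)
  expect_true(nrow(expanded) >= nrow(collapsed))
  expect_setequal(unique(expanded$carbons), unique(collapsed$carbons))
})

test_that("positive-mode fragments include the 197 Da hexose + NH3 loss", {
  comp <- compose_acylsugar("sucrose", c("iC5", "iC5", "iC5"))
  pred <- predict_fragments(comp, adduct("[M+NH4]+"),
                            ring_split = list(integer()))
  # precursor minus (hexose + ammonia), frozen from the atomic-mass table:
  # 612.3226 - 197.0899 = 415.2326
  expect_equal(pred$fragments$mz[1], 415.2326, tolerance = 0.001 / 415)
  expect_match(pred$fragments$description[1], "hexose \\+ NH3")
})

test_that("ring-split hypotheses move furanose chains into the neutral loss", {
  comp <- compose_acylsugar("sucrose", c("C2", "iC5", "iC5"))
  pred <- predict_fragments(comp, adduct("[M+NH4]+"))
  # hypotheses: no chains, {2}, {5}, {2,5}, {5,5} on the furanose ring
  expect_identical(nrow(pred$fragments), 5L)
  expect_true(all(diff(sort(pred$fragments$mz, decreasing = TRUE)) < 0))
})

test_that("single-chain negative-mode loss lands on the deacylated sugar ion", {
  comp <- compose_acylsugar("sucrose", "iC6")
  pred <- predict_fragments(comp, adduct("[M-H]-"))
  sucrose_ion <- adduct_mz(formula_mass(parse_formula("C12H22O11")), "[M-H]-")
  expect_true(any(abs(pred$fragments$mz - sucrose_ion) < 1e-9))
})

test_that("all predicted fragments sit below the precursor, both modes", {
  set.seed(13)
  ab <- default_chain_alphabet()
  for (rep in 1:10) {
    comp <- compose_acylsugar("sucrose",
                              sample(ab$label, sample(1:6, 1), replace = TRUE))
    for (add in list(adduct("[M-H]-"), adduct("[M+NH4]+"))) {
      pred <- predict_fragments(comp, add)
      expect_true(all(pred$fragments$mz < pred$precursor_mz))
      expect_true(all(pred$fragments$mz > 0))
    }
  }
  expect_error(predict_fragments(compose_acylsugar("sucrose", character())),
               "chainless")
})

test_that("fragment scoring is the matched fraction of predictions", {
  comp <- compose_acylsugar("sucrose", c("C2", "iC5", "iC5", "iC6"))
  pred <- predict_fragments(comp, adduct("[M-H]-"))
  expect_identical(score_annotation(pred$fragments$mz, pred, 5), 1)
  expect_identical(score_annotation(numeric(), pred, 5), 0)
  expect_identical(nrow(pred$fragments), 4L)  # 3 distinct chain losses + sugar ion
  expect_identical(score_annotation(pred$fragments$mz[1:2], pred, 5), 0.5)
})

test_that("the acylsugar-likeness screen accepts real masses, rejects others", {
  comp <- compose_acylsugar("sucrose", c("iC5", "iC5", "iC5"))
  expect_true(acylsugar_like(adduct_mz(comp, "[M+HCOO]-")))
  expect_false(acylsugar_like(651.004))  # near-zero mass defect
  expect_false(acylsugar_like(100))      # below the theoretical m/z range
})
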