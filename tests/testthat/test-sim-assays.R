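test_that("assay categories are realised as configured", {
  w <- small_world()
  expect_equal(sum(w$panel$assays$category_true == 4), 1)
  expect_equal(sum(w$panel$assays$category_true == 5), 1)
  expect_equal(nrow(w$panel$assays), w$cfg$n_assays)
})

test_that("category-5 assays sit at amphidiploid-monomorphic sites", {
  w <- small_world()
  df <- w$panel$assays
  c5 <- df[df$category_true == 5, ]
  expect_true(all(c5$amph_a == c5$amph_c))
  expect_true(all(c5$detect_a == c5$detect_c))
})

test_that("category-4 assays carry footprint interference on exactly the blocked subgenome", {
  w <- small_world()
  df <- w$panel$assays
  c4 <- df[df$category_true == 4, ]
  expect_true(all(xor(is.na(c4$detect_a), is.na(c4$detect_c))))
  fp <- w$panel$footprint_bp
  for (i in seq_len(nrow(c4))) {
    acc <- if (is.na(c4$detect_a[i])) w$amph$acc_snps_a else w$amph$acc_snps_c
    pos <- if (is.na(c4$detect_a[i])) c4$a_pos[i] else c4$c_pos[i]
    expect_true(any(acc$pos != pos & abs(acc$pos - pos) <= fp))
  }
})

test_that("an infeasible category mix errors with the shortfall listed", {
  cfg <- small_config(region_length_bp = 20000, n_assays = 40,
                      assay_category_mix = c(0, 0, 0, 0, 1))
  pair <- simulate_progenitor_pair(cfg)
  amph <- derive_amphidiploid(pair)
  lib <- suppressMessages(simulate_bac_library(amph, cfg))
  expect_error(simulate_assay_panel(amph, lib, cfg), "category 5")
})

test_that("a pure category-1 mix classifies as all category 1 from its evidence", {
  cfg <- small_config(assay_category_mix = c(1, 0, 0, 0, 0), seed = 5)
  pair <- simulate_progenitor_pair(cfg)
  amph <- derive_amphidiploid(pair)
  lib <- suppressMessages(simulate_bac_library(amph, cfg))
  panel <- simulate_assay_panel(amph, lib, cfg)
  cats <- classify_assays(simulate_reference_panel(panel))
  expect_true(all(cats$category == "1"))
})

test_that("reference-panel evidence follows the category patterns", {
  w <- small_world()
  ev <- simulate_reference_panel(w$panel)
  df <- w$panel$assays
  for (i in seq_len(nrow(df))) {
    a <- BASES[df$base_a[i]]; c_ <- BASES[df$base_c[i]]
    if (df$category_true[i] == 1) {
      expect_equal(unname(unlist(ev[i, c("rapa_acc1", "rapa_acc2",
                                         "rapa_wgs")])), rep(a, 3))
      expect_equal(ev$express_call[i], paste0(a, "/", c_))
    } else if (df$category_true[i] == 5) {
      expect_equal(ev$bac_a[i], ev$bac_c[i])
      expect_false(grepl("/", ev$express_call[i]))
    } else if (df$category_true[i] == 4) {
      expect_false(grepl("/", ev$express_call[i]))
      expect_false(ev$bac_a[i] == ev$bac_c[i])
    }
  }
})

test_that("the validation oracle reports physical presence with the right subgenome", {
  w <- small_world()
  oracle <- make_validation_oracle(w$panel, w$lib)
  df <- w$panel$assays
  lay <- w$lib$layout
  cl <- w$lib$clones
  pos_a <- lay$a_start + df$a_pos[1] - 1
  hit <- cl[cl$start <= pos_a & cl$end > pos_a, ][1, ]
  expect_equal(oracle(hit$clone_id, df$assay_id[1]),
               list(outcome = "present", subgenome = "A"))
  miss <- cl[cl$subgenome == "bg", ][1, ]
  expect_equal(oracle(miss$clone_id, df$assay_id[1])$outcome, "absent")
  expect_error(oracle("nope", df$assay_id[1]), "unknown clone")
  expect_error(oracle(hit$clone_id, "nope"), "unknown assay")
})

test_that("masked amplicons return untestable for the masked subgenome only", {
  w <- small_world()
  df <- w$panel$assays
  masked <- stats::setNames("A", df$assay_id[1])
  oracle <- make_validation_oracle(w$panel, w$lib, masked = masked)
  lay <- w$lib$layout
  cl <- w$lib$clones
  pos_a <- lay$a_start + df$a_pos[1] - 1
  hit <- cl[cl$start <= pos_a & cl$end > pos_a, ][1, ]
  expect_equal(oracle(hit$clone_id, df$assay_id[1], subgenome = "A")$outcome,
               "untestable")
  # claims about the unmasked subgenome still resolve
  expect_equal(oracle(hit$clone_id, df$assay_id[1], subgenome = "C")$outcome,
               "present")
})
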