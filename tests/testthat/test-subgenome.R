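test_that("published evidence rows classify to their published categories", {
  ev <- table3_evidence()
  cats <- classify_assays(ev)
  expected <- ifelse(ev$published_category == "3", "pending3",
                     ifelse(ev$published_category == "4", "pending4",
                            ev$published_category))
  expect_equal(cats$category, expected,
               info = paste(ev$assay_id, collapse = ","))
})

test_that("category-1 and 2 rows map nucleotides to the right subgenomes", {
  ev <- table3_evidence()
  cats <- classify_assays(ev)
  map_of <- function(aid) {
    r <- cats[cats$assay_id == aid, ]
    stats::setNames(c(r$sub1, r$sub2), c(r$nt1, r$nt2))
  }
  expect_equal(map_of("637-11"), c(A = "C", G = "A"))   # call pair A/G
  expect_equal(map_of("386-8"), c(T = "C", C = "A"))
  expect_equal(map_of("637-5"), c(A = "C", C = "A"))
  expect_equal(map_of("479-18"), c(C = "C", G = "A"))   # amplicon S fallback
  cat5 <- cats[cats$assay_id == "11424", ]
  expect_true(is.na(cat5$sub1) && is.na(cat5$sub2))
})

test_that("all-missing evidence is unassigned unless WGS-only mapping is allowed", {
  ev <- table3_evidence()
  r <- ev[ev$assay_id == "11303", ]
  expect_equal(classify_assay(r)$category, "unassigned")
  with_wgs <- classify_assay(r, allow_alignment_only = TRUE)
  expect_equal(with_wgs$category, "unassigned")
  expect_equal(c(with_wgs$sub1, with_wgs$sub2), c("A", "C"))
  expect_equal(c(with_wgs$nt1, with_wgs$nt2), c("G", "A"))
})

test_that("a side claiming both nucleotides with the other side silent is a contradiction", {
  ev <- data.frame(assay_id = "x", rapa_acc1 = "A", rapa_acc2 = "G",
                   rapa_wgs = "A", ole_acc1 = "nd", ole_acc2 = "nd",
                   ole_wgs = "nd", ole_gss = "nd", express_call = "A/G",
                   express_amplicon = "R", bac_a = "A", bac_c = "G")
  res <- classify_assay(ev)
  expect_true(res$contradiction)
  expect_equal(res$category, "unassigned")
})

test_that("pending categories resolve by clone majority vote under quorum", {
  categories <- data.frame(
    assay_id = c("cat1a", "cat1b", "pend"),
    category = c("1", "1", "pending3"),
    nt1 = c("A", "A", "A"), nt2 = c("G", "G", "G"),
    sub1 = c("A", "A", NA), sub2 = c("C", "C", NA),
    detected_nt = NA_character_, contradiction = FALSE,
    stringsAsFactors = FALSE)
  defs <- data.frame(assay_id = categories$assay_id,
                     nt1 = "A", nt2 = "G", stringsAsFactors = FALSE)
  clones_a <- sprintf("a%02d", 1:10)
  clones_c <- sprintf("c%02d", 1:10)
  st <- rbind(
    data.frame(clone_id = clones_a, assay_id = "cat1a", class = "allele1"),
    data.frame(clone_id = clones_c, assay_id = "cat1b", class = "allele2"),
    data.frame(clone_id = clones_a, assay_id = "pend", class = "allele1"),
    data.frame(clone_id = clones_c, assay_id = "pend", class = "allele2"))
  done <- infer_pending(categories, st, defs)
  expect_equal(done$category[3], "3")
  expect_equal(c(done$sub1[3], done$sub2[3]), c("A", "C"))
  # idempotent, and never alters the category-1 rows
  expect_identical(infer_pending(done, st, defs), done)
  expect_equal(done$category[1:2], c("1", "1"))

  # a 50/50 split fails quorum
  st2 <- rbind(st[st$assay_id != "pend", ],
               data.frame(clone_id = c(clones_a[1:2], clones_c[1:2]),
                          assay_id = "pend", class = "allele1"))
  done2 <- infer_pending(categories, st2, defs)
  expect_equal(done2$category[3], "unassigned")
})

test_that("single-nucleotide pending assays become category 4 with one mapped nucleotide", {
  categories <- data.frame(
    assay_id = c("anchor", "one_nt"),
    category = c("1", "pending4"),
    nt1 = c("A", NA), nt2 = c("G", NA),
    sub1 = c("A", NA), sub2 = c("C", NA),
    detected_nt = c(NA, "T"), contradiction = FALSE,
    stringsAsFactors = FALSE)
  defs <- data.frame(assay_id = c("anchor", "one_nt"),
                     nt1 = c("A", "T"), nt2 = c("G", "C"),
                     stringsAsFactors = FALSE)
  ids <- sprintf("cl%02d", 1:5)
  st <- rbind(data.frame(clone_id = ids, assay_id = "anchor",
                         class = "allele1"),
              data.frame(clone_id = ids, assay_id = "one_nt",
                         class = "allele1"))
  done <- infer_pending(categories, st, defs)
  expect_equal(done$category[2], "4")
  expect_equal(done$sub1[2], "A")
  expect_true(is.na(done$sub2[2]))
})

test_that("clone assignment takes the consensus and reports mixed implications", {
  categories <- data.frame(
    assay_id = c("m1", "m2", "m3"), category = "1",
    nt1 = "A", nt2 = "G", sub1 = "A", sub2 = "C",
    detected_nt = NA_character_, contradiction = FALSE,
    stringsAsFactors = FALSE)
  defs <- data.frame(assay_id = categories$assay_id, nt1 = "A",
                     nt2 = "G", stringsAsFactors = FALSE)
  st <- data.frame(clone_id = c("x", "x", "x", "y", "y", "y"),
                   assay_id = rep(c("m1", "m2", "m3"), 2),
                   class = c("allele1", "allele1", "allele1",
                             "allele1", "allele1", "allele2"))
  asg <- assign_clones(st, categories, defs)
  expect_equal(asg$clones$label[asg$clones$clone_id == "x"], "A")
  expect_false(asg$clones$conflict[asg$clones$clone_id == "x"])
  expect_true(asg$clones$conflict[asg$clones$clone_id == "y"])
  expect_equal(asg$conflicts$clone_id, "y")
  expect_equal(asg$clones$label[asg$clones$clone_id == "y"], "A")  # 2 vs 1
})

test_that("simulated panels recover their true categories through inference", {
  w <- small_world()
  sig <- simulate_pool_signals(w$panel, w$lib, w$design,
                               noise = noise_free())
  scr <- screen_library(classify_pools(sig), w$design)
  defs <- assay_defs(w$panel)
  cats <- infer_pending(classify_assays(simulate_reference_panel(w$panel)),
                        scr$score_table, defs)
  got <- as.integer(cats$category[match(w$panel$assays$assay_id,
                                        cats$assay_id)])
  expect_equal(got, w$panel$assays$category_true)
})
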