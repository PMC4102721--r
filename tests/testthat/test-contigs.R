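# hand-built marker order and a table-driven oracle for contig tests
morder10 <- data.frame(assay_id = sprintf("m%02d", 1:10), order = 1:10,
                       pos = (1:10) * 1000)

table_oracle <- function(presence, masked = NULL) {
  # presence: data.frame clone_id, assay_id, subgenome
  function(clone_id, assay_id, subgenome = NULL) {
    if (!is.null(subgenome) && !is.null(masked) &&
        assay_id %in% names(masked) &&
        identical(unname(masked[assay_id]), subgenome))
      return(list(outcome = "untestable", subgenome = NA_character_))
    hit <- presence[presence$clone_id == clone_id &
                      presence$assay_id == assay_id, ]
    if (nrow(hit) == 0) return(list(outcome = "absent",
                                    subgenome = NA_character_))
    list(outcome = "present", subgenome = hit$subgenome[1])
  }
}

scores <- function(clone_id, assays, class = "allele1") {
  data.frame(index = 0L, clone_id = clone_id, assay_id = assays,
             class = class, stringsAsFactors = FALSE)
}

cat1_categories <- function(assays) {
  data.frame(assay_id = assays, category = "1", nt1 = "A", nt2 = "G",
             sub1 = "A", sub2 = "C", detected_nt = NA_character_,
             contradiction = FALSE, stringsAsFactors = FALSE)
}

test_that("selection applies criteria A, B and C with promiscuity discounting", {
  st <- rbind(
    scores("fourA", c("m02", "m03", "m04", "m05")),
    scores("promisc4", c("m04", "m05", "m06", "m09")),
    scores("sepB", c("m03", "m07")),
    scores("midpair", c("m05", "m06")),
    scores("endC", c("m01", "m02")),
    scores("lone", "m06"),
    # m09 becomes promiscuous: give it many one-score clones
    scores(sprintf("bulk%02d", 1:30), "m09"))
  sel <- select_candidates(st, morder10, promiscuity_limit = 20)
  row <- function(id) sel[sel$clone_id == id, ]
  expect_true(row("fourA")$crit_a)
  expect_equal(row("fourA")$criterion, "A")
  expect_false(row("promisc4")$crit_a)      # one score discounted -> 3 left
  expect_false(row("promisc4")$selected)    # m04..m06 too close for B
  expect_true(row("sepB")$crit_b)           # 3 intervening markers
  expect_equal(row("sepB")$criterion, "B")
  expect_false(row("midpair")$selected)     # adjacent mid-region pair
  expect_true(row("endC")$crit_c)
  expect_equal(row("endC")$criterion, "C")
  expect_false(row("lone")$selected)
  expect_equal(attr(sel, "promiscuous"), "m09")
})

test_that("criterion B demands the configured marker separation", {
  st <- scores("x", c("m03", "m07"))
  sel <- select_candidates(st, morder10, separation_min = 2)
  expect_true(sel$crit_b[sel$clone_id == "x"])
  sel4 <- select_candidates(st, morder10, separation_min = 4)
  expect_false(sel4$selected[sel4$clone_id == "x"])
})

test_that("validation splits scores into confirmed, false and untestable", {
  st <- rbind(scores("x", c("m01", "m02", "m03", "m04")),
              scores("y", c("m01", "m02", "m03", "m04")))
  cats <- cat1_categories(morder10$assay_id)
  defs <- cats[, c("assay_id", "nt1", "nt2")]
  presence <- data.frame(clone_id = "x",
                         assay_id = c("m01", "m02", "m03", "m04"),
                         subgenome = "A")
  sel <- c("x", "y")
  val <- validate_scores(st, sel, cats, defs, table_oracle(presence))
  expect_equal(nrow(val$confirmed), 4)
  expect_equal(nrow(val$false_positives), 4)
  expect_equal(val$clone_labels$label[val$clone_labels$clone_id == "x"],
               "A")
  # an all-absent oracle makes every score a false positive
  val0 <- validate_scores(st, sel, cats, defs,
                          table_oracle(presence[0, ]))
  expect_equal(nrow(val0$false_positives), 8)
  # masked amplicons confirm nothing and refute nothing
  valm <- validate_scores(st, sel, cats, defs,
                          table_oracle(presence,
                                       masked = c(m01 = "A")))
  expect_equal(nrow(valm$untestable), 2)
  expect_equal(nrow(valm$confirmed), 3)
})

test_that("contigs are connected components under shared confirmed markers", {
  confirmed <- data.frame(
    clone_id = c("X", "X", "X", "Y", "Y", "Z", "Z"),
    assay_id = c("m01", "m02", "m03", "m03", "m04", "m06", "m07"),
    subgenome = "A")
  labels <- data.frame(clone_id = c("X", "Y", "Z"), label = "A")
  cs <- build_contigs(confirmed, morder10, labels)
  expect_length(cs$contigs, 2)
  expect_setequal(cs$contigs[[1]]$members, c("X", "Y"))
  expect_equal(c(cs$contigs[[1]]$first, cs$contigs[[1]]$last), c(1, 4))
  expect_equal(cs$contigs[[2]]$members, "Z")
  expect_equal(contig_counts(cs), c(A = 2L, C = 0L))
})

test_that("marker-skipping clones are reported, never corrected", {
  confirmed <- data.frame(clone_id = c("X", "X"),
                          assay_id = c("m02", "m05"), subgenome = "A")
  labels <- data.frame(clone_id = "X", label = "A")
  cs <- build_contigs(confirmed, morder10, labels)
  expect_equal(cs$violations$missing_order, c(3, 4))
  expect_equal(nrow(cs$confirmed), 2)
})

test_that("refinement recovers interior and adjacent false negatives until a fixed point", {
  confirmed <- data.frame(clone_id = c("X", "X"),
                          assay_id = c("m02", "m04"), subgenome = "A")
  labels <- data.frame(clone_id = "X", label = "A")
  truth <- data.frame(clone_id = "X",
                      assay_id = sprintf("m%02d", 1:6), subgenome = "A")
  cs <- build_contigs(confirmed, morder10, labels)
  ref <- refine_contigs(cs, table_oracle(truth))
  got <- ref$contig_set$confirmed
  # the full true span m01..m06 is recovered, including ends found
  # only after the first extension
  expect_setequal(got$assay_id[got$clone_id == "X"],
                  sprintf("m%02d", 1:6))
  expect_setequal(ref$false_negatives$assay_id,
                  c("m01", "m03", "m05", "m06"))
  # no violations remain after integration
  expect_equal(nrow(ref$contig_set$violations), 0)
})

test_that("bridging merges contigs through a gap-spanning unselected clone", {
  confirmed <- data.frame(
    clone_id = c("L", "L", "R", "R"),
    assay_id = c("m01", "m02", "m07", "m08"), subgenome = "A")
  labels <- data.frame(clone_id = c("L", "R"), label = "A")
  cs <- build_contigs(confirmed, morder10, labels)
  expect_length(cs$contigs, 2)
  # clone B spans m02..m07 but was never selected; it is in the score
  # table through end markers
  st <- rbind(scores("L", c("m01", "m02")), scores("R", c("m07", "m08")),
              scores("B", c("m02", "m05")))
  truth <- rbind(confirmed,
                 data.frame(clone_id = "B",
                            assay_id = sprintf("m%02d", 2:7),
                            subgenome = "A"))
  br <- bridge_contigs(cs, st, table_oracle(truth))
  expect_length(br$contig_set$contigs, 1)
  expect_true("B" %in% br$contig_set$contigs[[1]]$members)
  expect_equal(br$report$diagnosis, "bridged")
  expect_equal(br$report$bridged_by, "B")
})

test_that("unbridgeable gaps persist and are diagnosed", {
  confirmed <- data.frame(
    clone_id = c("L", "L", "R", "R"),
    assay_id = c("m01", "m02", "m07", "m08"), subgenome = "A")
  labels <- data.frame(clone_id = c("L", "R"), label = "A")
  cs <- build_contigs(confirmed, morder10, labels)
  st <- rbind(scores("L", c("m01", "m02")), scores("R", c("m07", "m08")))
  br <- bridge_contigs(cs, st, table_oracle(confirmed))
  expect_length(br$contig_set$contigs, 2)
  expect_equal(br$report$diagnosis, "no_candidates")
  # a candidate that maps elsewhere is reported as such
  st2 <- rbind(st, scores("E", c("m02", "m06")))
  off <- rbind(confirmed, data.frame(clone_id = "E", assay_id = "m06",
                                     subgenome = "offtarget"))
  br2 <- bridge_contigs(cs, st2, table_oracle(off))
  expect_equal(br2$report$diagnosis, "candidates_map_elsewhere")
})

test_that("the contig diagram marks confirmed markers across each member's span", {
  confirmed <- data.frame(clone_id = c("X", "X"),
                          assay_id = c("m02", "m04"), subgenome = "A")
  labels <- data.frame(clone_id = "X", label = "A")
  cs <- build_contigs(confirmed, morder10, labels)
  dg <- contig_diagram(cs)
  row <- grep("X", dg, value = TRUE)
  expect_match(row, "#=#")
})
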