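make_hsps <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(query_id = sample(sprintf("q%02d", 1:12), n, replace = TRUE),
             subject_id = sample(c("chrC1", "chrC2"), n, replace = TRUE,
                                 prob = c(0.8, 0.2)),
             s_start = sample(0:900000, n),
             length_bp = sample(100:2000, n, replace = TRUE),
             identity_pct = runif(n, 85, 100)) |>
    transform(s_end = s_start + length_bp)
}

test_that("HSP filtering applies the length, identity, region and off-target rules", {
  region <- list(subject_id = "chrC1", start = 0, end = 1000000)
  base <- data.frame(query_id = "q1", subject_id = "chrC1",
                     s_start = 1000, s_end = 1499, length_bp = 499,
                     identity_pct = 99)
  expect_equal(nrow(filter_hsps(base, region)), 0)      # length boundary
  base$length_bp <- 500
  base$s_end <- 1500
  expect_equal(nrow(filter_hsps(base, region)), 1)      # inclusive at 500
  # a 600 bp / 96% hit dies if its query also matches 200 bp / 92% off-target
  hs <- data.frame(query_id = c("q2", "q2"),
                   subject_id = c("chrC1", "chrC2"),
                   s_start = c(0, 0), s_end = c(600, 200),
                   length_bp = c(600, 200), identity_pct = c(96, 92))
  expect_equal(nrow(filter_hsps(hs, region)), 0)
  hs$identity_pct[2] <- 89                               # below off_id
  expect_equal(nrow(filter_hsps(hs, region)), 1)
  expect_equal(nrow(filter_hsps(hs[0, ], region)), 0)    # empty in, empty out
})

test_that("HSP filtering equals a brute-force scan and is monotone in its thresholds", {
  region <- list(subject_id = "chrC1", start = 200000, end = 800000)
  hs <- make_hsps(300)
  got <- filter_hsps(hs, region)
  # brute force re-derivation
  keep <- logical(nrow(hs))
  for (i in seq_len(nrow(hs))) {
    in_t <- hs$subject_id[i] == "chrC1" & hs$s_start[i] >= 200000 &
      hs$s_end[i] <= 800000
    sib <- hs[hs$query_id == hs$query_id[i], ]
    sib_off <- any(!(sib$subject_id == "chrC1" & sib$s_start >= 200000 &
                       sib$s_end <= 800000) &
                     sib$length_bp >= 150 & sib$identity_pct >= 90)
    keep[i] <- in_t && hs$length_bp[i] >= 500 && hs$identity_pct[i] >= 95 &&
      !sib_off
  }
  expect_setequal(paste(got$query_id, got$s_start),
                  paste(hs$query_id[keep], hs$s_start[keep]))
  # tightening never adds
  tighter <- filter_hsps(hs, region, min_len = 700, min_id = 97)
  expect_true(all(paste(tighter$query_id, tighter$s_start) %in%
                    paste(got$query_id, got$s_start)))
})

test_that("GSS contigs merge overlap components and mask disagreements", {
  reads <- data.frame(read_id = c("r1", "r2"),
                      sequence = c("ACGTACGT", "GTACGTAA"))
  ov <- data.frame(read_a = "r1", read_b = "r2", offset = 2)
  ct <- assemble_gss_contigs(reads, ov)
  expect_length(ct, 1)
  expect_equal(ct[[1]]$consensus, "ACGTACGTAA")
  expect_length(ct[[1]]$masked, 0)

  reads2 <- data.frame(read_id = c("r1", "r2"),
                       sequence = c("ACGTACGT", "GTACCTAA"))
  ct2 <- assemble_gss_contigs(reads2, ov)
  expect_equal(ct2[[1]]$consensus, "ACGTACNTAA")
  expect_equal(ct2[[1]]$masked, 6L)

  # unrelated reads stay in separate contigs
  reads3 <- rbind(reads, data.frame(read_id = "r3", sequence = "TTTT"))
  ct3 <- assemble_gss_contigs(reads3, ov)
  expect_length(ct3, 2)

  expect_error(assemble_gss_contigs(
    reads, data.frame(read_a = "r1", read_b = "r2", offset = 50)),
    "do not overlap")
})

test_that("planted disagreements in a random tiling are exactly the masked columns", {
  set.seed(4)
  truth <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
  starts <- c(0, 40, 90, 130, 180, 220)
  len <- 90
  seqs <- substring(truth, starts + 1, pmin(starts + len, 300))
  planted <- c(55, 200)   # 0-based columns, covered by >= 2 reads
  for (p in planted) {
    k <- max(which(starts <= p & p < starts + len))
    local_i <- p - starts[k] + 1
    old <- substring(seqs[k], local_i, local_i)
    new <- setdiff(c("A", "C", "G", "T"), old)[1]
    substring(seqs[k], local_i, local_i) <- new
  }
  reads <- data.frame(read_id = sprintf("r%d", seq_along(starts)),
                      sequence = seqs)
  ov <- data.frame(read_a = sprintf("r%d", seq_len(length(starts) - 1)),
                   read_b = sprintf("r%d", 2:length(starts)),
                   offset = diff(starts))
  ct <- assemble_gss_contigs(reads, ov)
  expect_length(ct, 1)
  expect_equal(ct[[1]]$masked, planted)
})

test_that("assay-site finding honours the flank constraints", {
  flank <- function(n) strrep("ACGTG", n / 5)
  # clean site: 30 identical bases each side within a long identical context
  ctx <- strrep("ACGTG", 30)
  a <- paste0(ctx, "A", ctx)
  c_ <- paste0(ctx, "G", ctx)
  got <- find_assay_sites(a, c_)
  expect_equal(nrow(got), 1)
  expect_equal(got$site_a, nchar(ctx))
  expect_equal(c(got$nt1, got$nt2), c("A", "G"))

  # extra mismatch 10 bases away violates the clearance rule
  c_bad <- c_
  substring(c_bad, nchar(ctx) + 1 - 10, nchar(ctx) + 1 - 10) <- "T"
  expect_equal(nrow(find_assay_sites(a, c_bad)), 0)
  # ... but beyond the perfect-flank length (20) it is tolerated
  c_ok <- c_
  substring(c_ok, nchar(ctx) + 1 - 22, nchar(ctx) + 1 - 22) <- "T"
  expect_equal(nrow(find_assay_sites(a, c_ok)), 1)

  # an indel inside the flank window disqualifies
  a_gap <- paste0(ctx, "A", substr(ctx, 1, 9), "-", substr(ctx, 10, nchar(ctx)))
  c_gap <- paste0(ctx, "G", substr(ctx, 1, 9), "C", substr(ctx, 10, nchar(ctx)))
  expect_equal(nrow(find_assay_sites(a_gap, c_gap)), 0)

  # ambiguity at the site is skipped
  a_n <- a; substring(a_n, nchar(ctx) + 1, nchar(ctx) + 1) <- "N"
  expect_equal(nrow(find_assay_sites(a_n, c_)), 0)
})

test_that("assay-site finding equals an independent per-column evaluation on simulated alignments", {
  cfg <- small_config(region_length_bp = 8000, divergence_rate = 0.02,
                      indel_rate = 0.002, seed = 31)
  pair <- simulate_progenitor_pair(cfg)
  s <- alignment_strings(pair)
  got <- find_assay_sites(s[["A"]], s[["C"]])

  # independent oracle: direct string comparison over ungapped windows
  va <- strsplit(s[["A"]], "")[[1]]
  vc <- strsplit(s[["C"]], "")[[1]]
  ua <- va[va != "-"]; uc <- vc[vc != "-"]
  pos_a <- cumsum(va != "-"); pos_c <- cumsum(vc != "-")
  expected <- integer(0)
  for (i in which(va != "-" & vc != "-" & va != vc)) {
    lcols <- (i - 25):(i - 1); rcols <- (i + 1):(i + 25)
    if (min(lcols) < 1 || max(rcols) > length(va)) next
    win <- c(lcols, rcols)
    if (any(va[win] == "-" | vc[win] == "-")) next
    mm <- win[va[win] != vc[win]]
    if (length(mm) > 1) next
    if (length(mm) == 1 && abs(mm - i) <= 20) next # clearance (15) plus
                                                   # perfect-flank rule (20)
    if (pos_a[i] <= 60 || pos_a[i] + 60 > length(ua)) next
    if (pos_c[i] <= 60 || pos_c[i] + 60 > length(uc)) next
    w <- paste(ua[(pos_a[i] - 60):(pos_a[i] + 60)], collapse = "")
    if (designability_surrogate(w) <= 0.6) next
    expected <- c(expected, pos_a[i] - 1L)
  }
  expect_setequal(got$site_a, expected)
  expect_gt(nrow(got), 0)
})

test_that("zero-divergence alignments yield no assay sites", {
  cfg <- small_config(divergence_rate = 0, indel_rate = 0,
                      region_length_bp = 2000)
  pair <- simulate_progenitor_pair(cfg)
  s <- alignment_strings(pair)
  expect_equal(nrow(find_assay_sites(s[["A"]], s[["C"]])), 0)
})

test_that("the designability surrogate penalises homopolymers and GC extremes", {
  expect_lt(designability_surrogate(strrep("A", 60)), 0.1)
  expect_lt(designability_surrogate(strrep("GC", 30)), 0.1)
  expect_gt(designability_surrogate(strrep("ACGTG", 24)), 0.6)
})

test_that("amphidiploid verification distinguishes the four candidate fates", {
  w <- small_world()
  df <- w$panel$assays
  cand_of <- function(row) data.frame(site_a = row$a_pos - 1L,
                                      site_c = row$c_pos - 1L,
                                      nt1 = BASES[row$base_a],
                                      nt2 = BASES[row$base_c])
  clean <- df[df$category_true == 1, ][1, ]
  expect_equal(verify_in_amphidiploid(cand_of(clean), w$pair, w$amph),
               "conserved")
  mono <- df[df$category_true == 5, ][1, ]
  expect_equal(verify_in_amphidiploid(cand_of(mono), w$pair, w$amph),
               "monomorphic")
  inter <- df[df$category_true == 4, ][1, ]
  expect_equal(verify_in_amphidiploid(cand_of(inter), w$pair, w$amph),
               "interfering")
  # a mutated (still polymorphic, different allele) site reads as changed
  st <- w$amph$snp_truth
  ch <- st[st$mutated & !st$monomorphic, ]
  novel <- (ch$amph_a != ch$base_a & ch$amph_a != ch$base_c) |
    (ch$amph_c != ch$base_a & ch$amph_c != ch$base_c)
  ch <- ch[novel, ][1, ]
  cand <- data.frame(site_a = ch$a_pos - 1L, site_c = ch$c_pos - 1L,
                     nt1 = BASES[ch$base_a], nt2 = BASES[ch$base_c])
  status <- verify_in_amphidiploid(cand, w$pair, w$amph)
  expect_true(status %in% c("changed", "interfering"))
  expect_equal(verify_in_amphidiploid(
    data.frame(site_a = 5, site_c = NA, nt1 = "A", nt2 = "C"),
    w$pair, w$amph), "unmappable")
})
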