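test_that("mature miRNA construction validates and extracts the seed", {
  mir <- mature_mirna("miR-155-5p", "UUAAUGCUAAUUGUGAUAGGGGU")
  expect_equal(mir$seed, "UAAUGCU")
  expect_equal(mature_mirna("x", "ttaatgctaa")$sequence, "UUAAUGCUAA")
  expect_error(mature_mirna("x", "UUAAUGC"), "at least 8")
  expect_error(mature_mirna("x", "UUAAUGCXAA"), "position 8")
})

test_that("canonical seed sites are found and typed, case/alphabet invariant", {
  hits <- scan_seed_sites(c(u1 = "GGAGCAUUAAGG"), MIR155)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$site_type, "8mer")
  expect_equal(hits$match, "AGCAUUAA")
  expect_equal(c(hits$start, hits$end), c(2, 10))

  # lowercase DNA input gives the identical call
  dna <- scan_seed_sites(c(u1 = "ggagcattaagg"), MIR155)
  expect_equal(dna[c("start", "end", "site_type")],
               hits[c("start", "end", "site_type")])

  expect_equal(nrow(scan_seed_sites(c(u1 = "CCCCCCCC"), MIR155)), 0)
  expect_error(scan_seed_sites(c(u1 = "GGAGNAUU"), MIR155), "position 5")

  # the four types at hand-placed loci
  types <- scan_seed_sites(c(
    a = "CCAGCAUUAAC",   # m8 + core + A  -> 8mer
    b = "CCAGCAUUACC",   # m8 + core      -> 7mer-m8
    c = "CCGGCAUUAAC",   # core + A       -> 7mer-A1
    d = "CCGGCAUUACC"),  # bare core      -> 6mer
    MIR155)
  expect_equal(types$site_type[match(c("a", "b", "c", "d"), types$utr_id)],
               c("8mer", "7mer-m8", "7mer-A1", "6mer"))
})

test_that("scanner agrees with the brute-force substring oracle", {
  set.seed(31)
  for (i in 1:200) {
    utr <- random_utr(sample(20:500, 1))
    got <- scan_seed_sites(c(u = utr), MIR155)
    want <- oracle_seed_scan(utr, MIR155$sequence)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      ord <- order(want$start)
      expect_equal(got$start, want$start[ord])
      expect_equal(got$end, want$end[ord])
      expect_equal(got$site_type, want$site_type[ord])
    }
  }
})

test_that("site types are hierarchical and specificity-resolved", {
  # every 8mer site contains the 7mer-m8 and 7mer-A1 patterns
  pats <- list(m8 = "AGCAUUA", a1 = "GCAUUAA", core = "GCAUUA")
  set.seed(32)
  n8 <- 0
  for (i in 1:300) {
    # embed a seed-match core with random flanks so every type is sampled
    utr <- paste0(random_utr(50), "GCAUUA", random_utr(50))
    hits <- scan_seed_sites(c(u = utr), MIR155)
    e8 <- hits[hits$site_type == "8mer", ]
    if (nrow(e8)) {
      n8 <- n8 + nrow(e8)
      expect_true(all(grepl(pats$m8, e8$match, fixed = TRUE)))
      expect_true(all(grepl(pats$a1, e8$match, fixed = TRUE)))
    }
    # one typed site per core locus: relaxing specificity to "any core
    # occurrence" can only add counts
    n_core <- length(gregexpr("(?=GCAUUA)", utr, perl = TRUE)[[1]])
    n_core <- if (attr(regexpr("GCAUUA", utr), "match.length") == -1) 0 else n_core
    expect_equal(nrow(hits), n_core)
  }
  expect_gt(n8, 0)
})

test_that("repression filter keeps down-regulated universe members", {
  fc_wt <- fake_contrast(c("Mafb", "Up1", "Mid"), fc = c(0.37, 1.5, 0.8))
  uni <- gene_set(c("Mafb", "Up1", "Mid"))
  kept <- candidate_targets(fc_wt, uni)
  expect_setequal(kept$members, c("Mafb", "Mid"))
  strict <- candidate_targets(fc_wt, uni, max_fc = 0.5)
  expect_identical(strict$members, "Mafb")
  expect_warning(out <- candidate_targets(fc_wt, gene_set("Ghost")),
                 "empty set")
  expect_length(out$members, 0)

  # planted 3-fold-repressed targets survive the filter at n = 3 vs 3
  gp <- generator_params(n_probes = 2000, seed = 8)
  gen <- generate_expression(gp)
  wt <- contrast(gen$matrix, "WT_M1", "WT_M0")
  targets <- gen$truth$gene_symbols[gen$truth$classes == "target"]
  kept2 <- candidate_targets(wt, gene_set(targets), max_fc = 0.5)
  expect_gte(length(kept2$members), 28)
})

test_that("re-induction filter splits candidates at FC 1 and the top cut", {
  fc_cx <- fake_contrast(c("Bat5", "mild", "flat"), fc = c(2.07, 1.01, 0.9))
  cand <- gene_set(c("Bat5", "mild", "flat"), match = "probe")
  out <- reinduction_filter(cand, fc_cx)
  expect_setequal(out$reinduced$members, c("Bat5", "mild"))
  expect_identical(out$top$members, "Bat5")
  expect_equal(out$fraction_reinduced, 2 / 3)
})

test_that("miRNA correlation matches the textbook formula and cor.test", {
  m <- matrix(rnorm(33, 8), 3, 11,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:11)))
  em <- expression_matrix(m)
  mir <- rnorm(11)
  m[1, ] <- -mir + 10                     # perfect anticorrelation
  em <- expression_matrix(m)
  res <- correlate_with_mir(em, mir)
  expect_equal(res$r[1], -1)
  expect_equal(res$p[1], 0)

  # 6-point hand vectors against the independent oracle
  g <- c(1.2, 3.4, 2.2, 5.0, 4.1, 0.7)
  v <- c(2.0, 1.1, 1.9, 0.2, 0.4, 2.6)
  em6 <- expression_matrix(matrix(g, 1, 6,
                                  dimnames = list("g", paste0("s", 1:6))))
  res6 <- correlate_with_mir(em6, v)
  ct <- cor.test(g, v)
  expect_equal(res6$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res6$p, ct$p.value, tolerance = 1e-12)

  # affine rescaling of either vector leaves R untouched
  res_scaled <- correlate_with_mir(em6, 3 * v - 7)
  expect_equal(res_scaled$r, res6$r, tolerance = 1e-12)

  # zero-variance gene flagged, not dropped
  emz <- expression_matrix(matrix(c(1, 1, 1, 1, 2, 1), 2, 3, byrow = TRUE,
                                  dimnames = list(c("flat", "var"),
                                                  paste0("s", 1:3))))
  resz <- correlate_with_mir(emz, c(1, 2, 3))
  expect_true(resz$zero_variance[1])
  expect_true(is.na(resz$r[1]))
})

test_that("independent genes exceed the 5% critical value at the null rate", {
  set.seed(77)
  n <- 11
  E <- matrix(rnorm(1000 * n), 1000, n,
              dimnames = list(sprintf("g%04d", 1:1000), paste0("s", 1:n)))
  res <- correlate_with_mir(expression_matrix(E), rnorm(n))
  crit <- abs(qt(0.025, n - 2)) / sqrt(n - 2 + qt(0.025, n - 2)^2)
  expect_equal(mean(abs(res$r) > crit), mean(res$p < 0.05), tolerance = 1e-12)
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.02)
})

test_that("target report sorts by R and counts significant rows", {
  tab <- published_target_screen()
  rep_ <- build_target_report(tab)
  expect_equal(nrow(rep_), 18)
  expect_equal(attr(rep_, "n_significant"), 16)
  expect_identical(rep_$gene[1], "Bat5")
  expect_identical(rep_$gene[18], "Olfml3")
  expect_true(!is.unsorted(rep_$r))
  expect_true(all(rep_$fc_cross >= 2))

  empty <- build_target_report(tab[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_significant"), 0)
})

test_that("the screen is a pure filter chain with negative-R planted targets", {
  gp <- generator_params(n_probes = 1500, n_targets = 20, seed = 13)
  gen <- generate_expression(gp)
  wt <- contrast(gen$matrix, "WT_M1", "WT_M0")
  ko <- contrast(gen$matrix, "KO_M1", "KO_M0")
  cx <- contrast(gen$matrix, "KO_M1", "WT_M1")
  targets <- gen$truth$gene_symbols[gen$truth$classes == "target"]
  uni <- gene_set(c(targets, gen$truth$gene_symbols[1:50]))
  scr <- screen_targets(gen$matrix, gen$truth$mir_vector, uni, wt, ko, cx)
  expect_true(all(scr$report$r < 0))
  expect_gte(nrow(scr$report), 18)

  # permuting the universe's gene order changes nothing
  uni2 <- gene_set(rev(uni$members))
  scr2 <- screen_targets(gen$matrix, gen$truth$mir_vector, uni2, wt, ko, cx)
  expect_equal(as.data.frame(scr2$report), as.data.frame(scr$report))
})
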