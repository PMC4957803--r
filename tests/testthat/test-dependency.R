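sig_from <- function(up = character(), down = character()) {
  structure(list(up = gene_set(up, direction = "up", match = "probe"),
                 down = gene_set(down, direction = "down", match = "probe"),
                 up_fc = 2, down_fc = 0.5, alpha = 0.05,
                 p_value = "adjusted", inclusive = TRUE,
                 n_up = length(up), n_down = length(down)),
            class = "signature")
}

test_that("dependency labels follow the fold-change band rules", {
  probes <- c("dep_up", "att_up", "ind_up", "dep_dn", "att_dn")
  fc_wt <- fake_contrast(probes, fc = c(4, 260, 2.5, 0.2, 0.1))
  fc_ko <- fake_contrast(probes, fc = c(1.2, 4, 3.0, 0.9, 0.25))
  part <- classify_dependency(sig_from(up = probes[1:3], down = probes[4:5]),
                              fc_wt, fc_ko)
  expect_equal(part$label[match(probes, part$probe_id)],
               c("dependent", "attenuated", "independent",
                 "dependent", "attenuated"))
  s <- attr(part, "summary")
  expect_equal(s$pct_up_dependent, 100 / 3, tolerance = 1e-12)
  expect_equal(s$pct_down_dependent, 50)
  expect_equal(s$pct_overall_dependent, 40)

  # labels always partition the signature
  expect_equal(sum(s$counts), nrow(part))

  expect_error(
    classify_dependency(sig_from(up = c(probes[1], "ghost")), fc_wt, fc_ko),
    "ghost")
})

test_that("planted 50% dependency is recovered from a full synthetic run", {
  gp <- generator_params(n_probes = 10000, fraction_induced = 0.1,
                         fraction_repressed = 0.1, n_targets = 0, seed = 42)
  gen <- generate_expression(gp)
  wt <- contrast(gen$matrix, "WT_M1", "WT_M0")
  ko <- contrast(gen$matrix, "KO_M1", "KO_M0")
  part <- classify_dependency(call_signature(wt), wt, ko)
  s <- attr(part, "summary")
  expect_gt(s$n_up + s$n_down, 1800)   # ~2000 signature genes planted
  expect_lt(abs(s$pct_up_dependent - 50), 5)
  expect_lt(abs(s$pct_overall_dependent - 50), 5)
})

test_that("the affected-gene list applies both compilation criteria", {
  probes <- c("c1", "c2", "none", "dn1")
  fc_wt <- fake_contrast(probes, fc = c(3, 1.5, 3, 0.3))
  fc_ko <- fake_contrast(probes, fc = c(1.1, 1.4, 3, 0.9))
  fc_cx <- fake_contrast(probes, fc = c(1.5, 2.5, 1.0, 1.2))
  gs <- compile_affected_list(fc_wt, fc_ko, fc_cx)
  prov <- attr(gs, "provenance")
  expect_setequal(gs$members, c("c1", "c2", "dn1"))
  expect_equal(prov$criterion[match(c("c1", "c2", "dn1"), prov$probe_id)],
               c("wt_not_ko", "cross", "wt_not_ko"))

  # identical WT/KO contrasts and unit cross contrast select nothing
  empty <- compile_affected_list(fc_wt, fc_wt,
                                 fake_contrast(probes, fc = rep(1, 4)))
  expect_length(empty$members, 0)

  expect_error(
    compile_affected_list(fc_wt, fc_ko, fake_contrast("other", fc = 1)),
    "probe universe")
})

test_that("power-law trend fitting recovers known parameters", {
  # exact identity line
  fc <- c(0.25, 0.5, 1, 2, 4, 8)
  fit <- fit_fcfc_trend(fc, fc)
  expect_equal(fit$a, 1, tolerance = 1e-12)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # generated pairs: a = 1, b = 0.6, log2-scale noise sd 0.5, n = 5000
  set.seed(9)
  x <- rnorm(5000, 0, 2)
  y <- 0.6 * x + rnorm(5000, 0, 0.5)
  fit2 <- fit_fcfc_trend(2^x, 2^y)
  expect_lt(abs(fit2$b - 0.6), 0.03)
  expect_lt(abs(fit2$a - 1), 0.05)

  # flat knockout response: exponent 0
  fit3 <- fit_fcfc_trend(c(1, 2, 4, 8), rep(1, 4))
  expect_equal(fit3$b, 0, tolerance = 1e-12)

  expect_error(fit_fcfc_trend(c(1, 2), c(1, 2)), "3 points")
  expect_error(fit_fcfc_trend(c(1, -2, 3), c(1, 2, 3)), "positive")
})

test_that("trend fit is equivariant under rescaling of the WT axis", {
  set.seed(21)
  x <- 2^rnorm(200); y <- x^0.7 * 2^rnorm(200, 0, 0.2)
  f0 <- fit_fcfc_trend(x, y)
  f1 <- fit_fcfc_trend(3.7 * x, y)
  expect_equal(f1$b, f0$b, tolerance = 1e-10)
  expect_equal(f1$a, f0$a * 3.7^(-f0$b), tolerance = 1e-10)
  expect_equal(f1$r_squared, f0$r_squared, tolerance = 1e-10)
})

test_that("marker panels are flagged by their position against y = x", {
  fc_wt <- fake_contrast(c("Mrc1", "Egr2"), fc = c(0.2, 1.5))
  fc_ko <- fake_contrast(c("Mrc1", "Egr2"), fc = c(0.7, 1.5))
  rep_ <- marker_panel_report(gene_set(c("Mrc1", "Egr2")), fc_wt, fc_ko)
  expect_identical(rep_$above_line, c(TRUE, FALSE))

  # planted less-suppressed genes in the synthetic set are all above-line
  gp <- generator_params(n_probes = 2000, seed = 5)
  gen <- generate_expression(gp)
  wt <- contrast(gen$matrix, "WT_M1", "WT_M0")
  ko <- contrast(gen$matrix, "KO_M1", "KO_M0")
  strong <- which(gen$truth$classes == "repressed-attenuated" &
                    gen$truth$effect_wt <= -2.5)
  panel <- gene_set(gen$truth$gene_symbols[strong[1:10]], direction = "down")
  out <- marker_panel_report(panel, wt, ko)
  expect_equal(nrow(out), 10)
  expect_true(all(out$above_line))

  expect_error(marker_panel_report(gene_set("Nosuch"), fc_wt, fc_ko),
               "no panel gene")
})
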