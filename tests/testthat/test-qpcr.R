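make_ct <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1]], gene = r[[2]], ct = as.numeric(r[[3]]),
               group = if (length(r) > 3) r[[4]] else NA_character_)))
  if (all(is.na(df$group))) df$group <- NULL
  ct_table(df, "Hprt")
}

test_that("comparative-Ct quantification follows 2^-ddCt", {
  ct <- make_ct(list("cal", "Hprt", 20), list("cal", "Nos2", 25),
                list("s1", "Hprt", 20), list("s1", "Nos2", 25),
                list("s2", "Hprt", 21), list("s2", "Nos2", 27))
  rq <- ddct_quantify(ct, "Nos2", "cal")
  expect_equal(rq$rq[rq$sample_id == "cal"], 1)
  expect_equal(rq$rq[rq$sample_id == "s1"], 1)     # identical to calibrator
  expect_equal(rq$rq[rq$sample_id == "s2"], 0.5)   # one extra target cycle

  # adding a constant to every Ct of one sample changes nothing
  ct2 <- make_ct(list("cal", "Hprt", 20), list("cal", "Nos2", 25),
                 list("s1", "Hprt", 23.7), list("s1", "Nos2", 28.7),
                 list("s2", "Hprt", 21), list("s2", "Nos2", 27))
  expect_equal(ddct_quantify(ct2, "Nos2", "cal")$rq, rq$rq)

  expect_error(
    ct_table(data.frame(sample_id = c("a", "a", "b"),
                        gene = c("Hprt", "Nos2", "Nos2"),
                        ct = c(20, 25, 24)), "Hprt"),
    "b")
})

test_that("group-mean calibration equals the averaged-dCt hand computation", {
  ct <- make_ct(list("m0_1", "Hprt", 20), list("m0_1", "Il1b", 24),
                list("m0_2", "Hprt", 20), list("m0_2", "Il1b", 25),
                list("m0_3", "Hprt", 20), list("m0_3", "Il1b", 26),
                list("m1_1", "Hprt", 20), list("m1_1", "Il1b", 22))
  ct$group <- rep(c("M0", "M1"), c(6, 2))
  ct <- ct_table(as.data.frame(ct), "Hprt")
  rq <- ddct_quantify(ct, "Il1b", "M0")
  # dCt = 4,5,6,2; mean calibrator dCt = 5
  expect_equal(rq$rq, 2^-(c(4, 5, 6, 2) - 5))
  expect_equal(gmean(rq$rq[1:3]), 1, tolerance = 1e-12)
})

test_that("standard-curve method matches ddCt at 100% efficiency", {
  slope <- -1 / log10(2)                     # exactly 100% efficiency
  curve_pts <- function(intercept) {
    q <- c(0, -1, -2, -3)
    standard_curve(q, intercept + slope * q)
  }
  curves <- list(Hprt = curve_pts(20), Nos2 = curve_pts(24))
  expect_equal(curves$Hprt$efficiency, 1, tolerance = 1e-12)

  ct <- make_ct(list("cal", "Hprt", 21.5), list("cal", "Nos2", 26),
                list("s1", "Hprt", 22.3), list("s1", "Nos2", 25.1),
                list("s2", "Hprt", 20.9), list("s2", "Nos2", 27.8))
  sc <- standard_curve_quantify(ct, curves, "Nos2", calibrator = "cal")
  dd <- ddct_quantify(ct, "Nos2", "cal")
  expect_equal(sc$rq, dd$rq, tolerance = 1e-9)
})

test_that("different gene efficiencies give the hand-computed ratio", {
  curves <- list(Hprt = standard_curve(c(0, -1, -2), c(20, 23.5, 27)),
                 Il6 = standard_curve(c(0, -1, -2), c(24, 27.2, 30.4)))
  expect_false(efficiencies_comparable(curves$Hprt, curves$Il6))
  ct <- make_ct(list("s1", "Hprt", 22), list("s1", "Il6", 26))
  out <- standard_curve_quantify(ct, curves, "Il6")
  q_t <- 10^((26 - 24) / curves$Il6$slope)
  q_r <- 10^((22 - 20) / curves$Hprt$slope)
  expect_equal(out$rq, q_t / q_r, tolerance = 1e-12)

  # a Ct at a curve point returns that point's quantity
  at_point <- standard_curve_quantify(
    make_ct(list("s1", "Hprt", 20), list("s1", "Il6", 27.2)), curves, "Il6")
  expect_equal(at_point$quantity_target, 0.1, tolerance = 1e-9)

  expect_warning(
    standard_curve_quantify(make_ct(list("s1", "Hprt", 22),
                                    list("s1", "Il6", 35)), curves, "Il6"),
    "outside")
  expect_error(standard_curve(c(0, -1, -2), c(22.5, 21, 20)), "negative")
})

test_that("percent-of-condition scaling fixes the reference at 100", {
  rq <- c(2, 2.2, 1.8, 1.0, 1.1, 0.9, 0.2, 0.3)
  grp <- rep(c("WT_M1", "KO_M1", "M0"), c(3, 3, 2))
  out <- percent_of_condition(rq, grp, "WT_M1")
  expect_equal(out$percent[out$group == "WT_M1"], 100)
  expect_equal(out$percent[out$group == "KO_M1"], 50)
  expect_equal(out$percent[out$group == "M0"], 100 * 0.25 / 2)
  expect_equal(out$sem[out$group == "WT_M1"],
               100 * sd(rq[1:3]) / sqrt(3) / 2)
  expect_error(percent_of_condition(rq, grp, "M2"), "not present")
  expect_error(percent_of_condition(c(0, 0), c("a", "a", "b")), "aligned")
})

test_that("generated Ct tables recover planted relative quantities", {
  # a planted ~72% knockdown, exactly recovered at zero noise
  rq_truth <- c(WT_M1 = 1, KO_M1 = 0.28)
  ct <- generate_ct_table(rq_truth, target = "Inos", noise_sd = 0, seed = 2)
  rq <- ddct_quantify(ct, "Inos", "WT_M1")
  expect_equal(rq$rq[rq$group == "KO_M1"], rep(0.28, 3), tolerance = 1e-12)

  # flat truth: all Ct differences come from the reference gene
  ct1 <- generate_ct_table(c(A = 1, B = 1), noise_sd = 0, seed = 2)
  dct <- ddct_quantify(ct1, "Target", "A")
  expect_equal(unique(round(dct$dct, 9)), 5)

  # Monte-Carlo: mean recovered RQ within 2% of planted at 0.1-cycle noise
  set.seed(60)
  recovered <- replicate(1000, {
    ct_i <- generate_ct_table(rq_truth, noise_sd = 0.1,
                              seed = sample.int(1e6, 1))
    out <- ddct_quantify(ct_i, "Target", "WT_M1")
    mean(out$rq[out$group == "KO_M1"])
  })
  expect_lt(abs(mean(recovered) - 0.28) / 0.28, 0.02)
})
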