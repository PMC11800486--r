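test_that("majority vote consolidates an odd reader panel", {
  m <- rbind(c("rim+", "rim+", "rim-"),
             c("rim-", "rim-", "rim-"),
             c("rim-", "rim+", "rim+"))
  expect_equal(majority_vote(m), c("rim+", "rim-", "rim+"))
  expect_error(majority_vote(m[, 1:2]), "odd")
  m32 <- matrix("rim-", 32, 3)
  expect_length(majority_vote(m32), 32L)
})

test_that("contingency tables tally calls against iron truth", {
  # the study's QSM reading: 10 rim+ all iron+; of 22 rim-, 1 iron+
  calls_q <- c(rep("rim+", 10), rep("rim-", 22))
  truth_q <- c(rep("iron+", 10), "iron+", rep("iron-", 21))
  tq <- build_contingency(calls_q, truth_q)
  expect_equal(unclass(tq)[c("tp", "fp", "fn", "tn")],
               list(tp = 10, fp = 0, fn = 1, tn = 21))
  # the phase reading: 16 rim+ of which 10 iron+; of 16 rim-, 1 iron+
  calls_p <- c(rep("rim+", 16), rep("rim-", 16))
  truth_p <- c(rep("iron+", 10), rep("iron-", 6), "iron+", rep("iron-", 15))
  tp <- build_contingency(calls_p, truth_p)
  expect_equal(tp$total, 32)
  expect_equal(c(tp$tp, tp$fp, tp$fn, tp$tn), c(10, 6, 1, 15))
  # empty and mismatched inputs
  t0 <- build_contingency(character(0), character(0))
  expect_equal(t0$total, 0)
  expect_error(build_contingency("rim+", character(0)), "different lesion sets")
})

test_that("diagnostic metrics round half-up to the printed percentages", {
  mq <- diagnostic_metrics(contingency_table(10, 0, 1, 21))
  expect_equal(unname(mq$percent[c("sensitivity", "specificity", "ppv", "npv", "accuracy")]),
               c(91, 100, 100, 95, 97))
  mp <- diagnostic_metrics(contingency_table(10, 6, 1, 15))
  expect_equal(unname(mp$percent[c("sensitivity", "specificity", "ppv", "npv", "accuracy")]),
               c(91, 71, 63, 94, 78))
  # 10/16 = 62.5% prints as 63%: half-up, not banker's rounding
  expect_equal(unname(mp$percent["ppv"]), 63)
})

test_that("zero denominators flag as undefined instead of erroring", {
  m <- diagnostic_metrics(contingency_table(0, 0, 0, 5))
  expect_equal(unname(m$percent["specificity"]), 100)
  expect_equal(unname(m$percent["accuracy"]), 100)
  expect_true(m$undefined[["sensitivity"]])
  expect_true(m$undefined[["ppv"]])
  expect_true(is.na(m$fraction[["sensitivity"]]))
})

test_that("accuracy decomposes into prevalence-weighted sensitivity and specificity", {
  set.seed(8)
  for (i in 1:20) {
    tab <- contingency_table(sample(0:20, 1) + 1, sample(0:20, 1),
                             sample(0:20, 1), sample(0:20, 1) + 1)
    m <- diagnostic_metrics(tab)
    prev <- (tab$tp + tab$fn) / tab$total
    expect_equal(m$fraction[["accuracy"]],
                 m$fraction[["sensitivity"]] * prev +
                   m$fraction[["specificity"]] * (1 - prev),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to lesion ordering", {
  set.seed(12)
  calls <- sample(c("rim+", "rim-"), 40, TRUE)
  truth <- sample(c("iron+", "iron-"), 40, TRUE)
  o <- sample(40)
  expect_identical(unclass(build_contingency(calls, truth)),
                   unclass(build_contingency(calls[o], truth[o])))
})

test_that("Cohen's kappa matches hand-computed values and edge cases", {
  s <- c(rep("a", 10), rep("b", 10))
  expect_equal(cohen_kappa(s, s), 1)
  expect_equal(cohen_kappa(s, rev(s)), -1)   # complement on a balanced set
  s1 <- c(rep("a", 20), rep("a", 5), rep("b", 5), rep("b", 20))
  s2 <- c(rep("a", 20), rep("b", 5), rep("a", 5), rep("b", 20))
  expect_equal(cohen_kappa(s1, s2), 0.6, tolerance = 1e-12)
  # constant identical sessions: p_e = 1 with perfect agreement
  expect_equal(cohen_kappa(rep("a", 5), rep("a", 5)), 1)
  expect_error(cohen_kappa("a", c("a", "b")), "length")
})

test_that("Fleiss' kappa matches hand-computed fixtures and the independence null", {
  perfect <- rbind(c("+", "+", "+"), c("-", "-", "-"), c("+", "+", "+"))
  expect_equal(fleiss_kappa(perfect), 1)
  two_items <- rbind(c("+", "+", "-"), c("-", "-", "+"))
  expect_equal(fleiss_kappa(two_items), -1 / 3, tolerance = 1e-12)
  set.seed(11)
  null_m <- matrix(sample(c("x", "y"), 2000 * 3, TRUE), ncol = 3)
  expect_lt(abs(fleiss_kappa(null_m)), 0.05)
})

test_that("Fleiss with two raters equals Cohen exactly when marginals coincide", {
  # both raters use each category equally often: pooled and per-rater chance
  # agreement coincide, so the two statistics agree; with unequal marginals
  # Fleiss' pooled-chance formulation differs from Cohen's product form
  r1 <- c("a", "a", "b", "b", "a", "b")
  r2 <- c("a", "b", "b", "a", "a", "b")
  expect_equal(fleiss_kappa(cbind(r1, r2)), cohen_kappa(r1, r2), tolerance = 1e-12)
  q1 <- c("a", "a", "a", "b")
  q2 <- c("a", "a", "b", "b")
  expect_false(isTRUE(all.equal(fleiss_kappa(cbind(q1, q2)), cohen_kappa(q1, q2))))
})

test_that("Landis-Koch bands label kappa with right-closed edges", {
  expect_equal(landis_koch_label(0.57), "moderate")
  expect_equal(landis_koch_label(0.85), "almost perfect")
  expect_equal(landis_koch_label(1.0), "almost perfect")
  expect_equal(landis_koch_label(c(0.20, 0.40, 0.60, 0.80)),
               c("slight", "fair", "moderate", "substantial"))
  expect_equal(landis_koch_label(-0.2), "poor")
  expect_error(landis_koch_label(1.2), "exceed")
})

test_that("panel agreement wrapper combines Fleiss and per-rater Cohen", {
  truth <- data.frame(lesion_id = 1:32,
                      iron_rim_status = rep(c("iron+", "iron-"), 16))
  s1 <- generate_rating_matrix(truth, c(0.95, 0.85, 0.9), c(0.95, 0.9, 0.85), seed = 2)
  s2 <- generate_rating_matrix(truth, c(0.95, 0.85, 0.9), c(0.95, 0.9, 0.85), seed = 3)
  ag <- agreement_stats(s1, s2)
  expect_length(ag$cohen_kappa, 3L)
  expect_true(all(ag$cohen_kappa <= 1))
  expect_true(ag$fleiss_label %in% c("poor", "slight", "fair", "moderate",
                                     "substantial", "almost perfect"))
})
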