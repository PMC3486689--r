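# Empirical choice tables, NLL scoring, five-way comparison and the exact
# significance tests (checked against brute-force enumeration oracles).

make_probe_rows <- function(subject, part, width, choices) {
  data.frame(subject_id = subject, part = as.integer(part), index = 1L,
             trial_type = "probe", true_model = NA_character_,
             shift_cm = NA_real_, array_width_cm = width, choice = choices,
             correct = NA)
}

test_that("empirical probe probabilities count choices per cell", {
  tr <- rbind(make_probe_rows("a", 1, 3, rep(c("M1", "M2"), c(24, 6))),
              make_probe_rows("a", 1, 5, rep(c("M1", "M2"), c(5, 5))),
              make_probe_rows("b", 1, 3, rep("M1", 4)))
  tab <- empirical_probe_probs(tr)
  expect_equal(tab$p_hat[tab$subject_id == "a" & tab$width == 3], 0.8)
  expect_equal(tab$p_hat[tab$subject_id == "b" & tab$width == 3], 1)
  # absent cells are absent; totals partition the probe count
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$n[tab$subject_id == "a"]), 40)
  expect_error(empirical_probe_probs(tr[tr$trial_type == "standard", ]),
               "no probe trials")
})

test_that("probe NLL has its closed-form fixed points and clips safely", {
  tr <- make_probe_rows("a", 1, 3, rep(c("M1", "M2"), c(24, 6)))
  cells <- data.frame(subject_id = "a", part = 1L, width = 3)
  expect_equal(probe_nll(cbind(cells, p = 0.5), tr), 30 * log(2))
  # predicting every realized choice with certainty gives NLL ~ 0
  tr_all <- make_probe_rows("a", 1, 3, rep("M1", 10))
  expect_warning(v <- probe_nll(cbind(cells, p = 1), tr_all), "clipped")
  expect_equal(v, -10 * log(1 - 1e-6), tolerance = 1e-9)
  expect_warning(v0 <- probe_nll(cbind(cells, p = 0), tr_all), "clipped")
  expect_true(is.finite(v0))
  expect_error(probe_nll(cbind(cells, p = 0.5),
                         make_probe_rows("a", 1, 5, "M1")),
               "missing prediction")
})

test_that("probe NLL is additive over disjoint trial subsets", {
  tr1 <- make_probe_rows("a", 1, 3, rep(c("M1", "M2"), c(7, 3)))
  tr2 <- make_probe_rows("a", 1, 5, rep(c("M1", "M2"), c(2, 8)))
  preds <- data.frame(subject_id = "a", part = 1L, width = c(3, 5),
                      p = c(0.7, 0.3))
  expect_equal(probe_nll(preds, rbind(tr1, tr2)),
               probe_nll(preds, tr1) + probe_nll(preds, tr2))
})

test_that("five-way comparison scores every explanation and ignores row order", {
  log1 <- simulate_cohort(cond1, cond2, 2, "bayes_factor", seed = 60)
  res <- suppressWarnings(compare_explanations(log1, cond1, cond2))
  expect_setequal(names(res$total_nll),
                  c("bayes_factor", "policy_inference", "average",
                    "biggest", "halfway"))
  expect_true(all(is.finite(res$total_nll)) && all(res$total_nll >= 0))
  expect_equal(unname(res$total_nll),
               unname(sort(rowSums(res$per_subject_nll))))
  shuffled <- log1[sample(nrow(log1)), ]
  res2 <- suppressWarnings(compare_explanations(shuffled, cond1, cond2))
  expect_equal(res2$total_nll, res$total_nll, tolerance = 1e-12)
  expect_equal(res2$ranking, res$ranking)
})

test_that("generating strategies win the comparison on their own data", {
  # single-replicate smoke check of model recovery (the full replicated
  # study runs with the acceptance suite)
  log_b <- simulate_cohort(cond1, cond2, 7, "bayes_factor", seed = 61)
  res_b <- suppressWarnings(compare_explanations(log_b, cond1, cond2))
  expect_true(res_b$ranking[1] %in% c("bayes_factor", "policy_inference"))
  log_a <- simulate_cohort(cond1, cond2, 7, "average", seed = 62,
                           generating_curves = gen_curves)
  res_a <- suppressWarnings(compare_explanations(log_a, cond1, cond2))
  expect_equal(res_a$ranking[1], "average")
})

# Freeman-Halton exact probability by exhaustive enumeration over 2 x 3
# tables with both margins fixed
enumerate_fisher_p <- function(tab) {
  r <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  logp <- function(m) {
    sum(lgamma(r + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
      sum(lgamma(m + 1))
  }
  p_obs <- logp(tab)
  total <- 0
  for (a in 0:min(r[1], cs[1])) for (b in 0:min(r[1] - a, cs[2])) {
    cc <- r[1] - a - b
    if (cc > cs[3]) next
    m <- rbind(c(a, b, cc), cs - c(a, b, cc))
    if (any(m < 0)) next
    if (logp(m) <= p_obs + 1e-7) total <- total + exp(logp(m))
  }
  total
}

test_that("width-choice association matches exhaustive Fisher enumeration", {
  choices <- c(rep("M1", 10), rep(c("M2", "M1"), c(10, 0)), rep("M1", 10))
  tr <- rbind(make_probe_rows("a", 1, 3, rep(c("M1", "M2"), c(10, 2))),
              make_probe_rows("a", 1, 5, rep(c("M1", "M2"), c(3, 9))),
              make_probe_rows("a", 1, 8, rep(c("M1", "M2"), c(1, 11))))
  tab <- matrix(c(10, 2, 3, 9, 1, 11), nrow = 2)
  expect_equal(as.numeric(width_choice_association(tr, "a", 1)),
               enumerate_fisher_p(tab), tolerance = 1e-9)
  # identical proportions across widths: no association
  tr_same <- rbind(make_probe_rows("a", 1, 3, rep(c("M1", "M2"), c(5, 5))),
                   make_probe_rows("a", 1, 5, rep(c("M1", "M2"), c(5, 5))))
  expect_equal(as.numeric(width_choice_association(tr_same, "a", 1)), 1)
  # all-M1 choices: degenerate margin, flagged p = 1
  tr_m1 <- rbind(make_probe_rows("a", 1, 3, rep("M1", 6)),
                 make_probe_rows("a", 1, 5, rep("M1", 6)))
  p <- width_choice_association(tr_m1, "a", 1)
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
  expect_error(width_choice_association(tr_m1, "a", 2), "two widths")
})

test_that("part comparison matches the exact rank-sum permutation null", {
  tab <- data.frame(subject_id = rep(sprintf("s%d", 1:7), 2),
                    part = rep(1:2, each = 7), width = 8,
                    n_m1 = 0, n = 10,
                    p_hat = c(seq(0.8, 0.95, length.out = 7),
                              seq(0.1, 0.3, length.out = 7)))
  p <- part_comparison_test(tab, 8)
  # completely separated samples: enumerate all C(14,7) splits
  w_obs <- sum(rank(tab$p_hat)[1:7])
  splits <- utils::combn(14, 7)
  w_all <- colSums(matrix(rank(tab$p_hat)[splits], nrow = 7))
  p_exact <- mean(w_all >= w_obs | w_all <= sum(1:14) - w_obs)
  expect_equal(p, p_exact, tolerance = 1e-12)
  # symmetry under swapping the parts
  tab_sw <- tab; tab_sw$part <- rep(2:1, each = 7)
  expect_equal(part_comparison_test(tab_sw, 8), p)
  # identical samples: maximal p
  tab_id <- tab; tab_id$p_hat <- rep(seq(0.1, 0.7, length.out = 7), 2)
  expect_gt(part_comparison_test(tab_id, 8), 0.99)
  expect_error(part_comparison_test(tab[1:8, ], 8), "2 subjects")
})
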