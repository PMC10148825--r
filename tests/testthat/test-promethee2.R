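test_that("min-max normalization reproduces the worked 3-dp table exactly", {
  dm <- rtki_case_study()
  norm <- normalize_matrix(dm, rounding = 3)
  expect_equal(norm$values, expected_normalized)
  expect_length(norm$degenerate, 0)
  # GF2 spans [0, 1] so rounding leaves the raw values untouched
  expect_equal(unname(norm$values[, "GF2"]), unname(dm$scores[, "GF2"]))
})

test_that("normalization handles cost and degenerate criteria", {
  scores <- matrix(c(1, 2, 4, 5, 5, 5), ncol = 2,
                   dimnames = list(c("a", "b", "c"), c("price", "flat")))
  dm <- decision_matrix(scores, criteria = list(
    criterion("price", direction = "cost", weight = 0.5),
    criterion("flat", weight = 0.5)))
  norm <- normalize_matrix(dm)
  expect_equal(unname(norm$values[, "price"]), c(1, 2/3, 0)) # lower price better
  expect_equal(unname(norm$values[, "flat"]), c(0, 0, 0))
  expect_identical(norm$degenerate, "flat")
  # non-degenerate beneficial criteria attain both 0 and 1
  set.seed(7)
  for (i in 1:10) {
    nv <- normalize_matrix(random_dm(sample(2:8, 1), sample(1:4, 1)))$values
    expect_true(all(nv >= 0 & nv <= 1))
    expect_true(all(apply(nv, 2, min) == 0) && all(apply(nv, 2, max) == 1))
  }
})

test_that("deviations are lookups into the normalized matrix, antisymmetric", {
  norm <- normalize_matrix(rtki_case_study(), rounding = 3)
  expect_equal(deviation(norm, "GF2", "In9", "In4"), 0.334)
  expect_equal(deviation(norm, "GF1", "In7", "In1"), 0.499)
  expect_equal(deviation(norm, "GF1", "In3", "In3"), 0)
  # antisymmetry over all pairs and criteria
  for (j in colnames(norm$values))
    for (z in 1:9) for (y in 1:9)
      expect_identical(deviation(norm, j, z, y), -deviation(norm, j, y, z))
  expect_error(deviation(norm, "GF1", "In10", "In1"), "unknown alternative")
  expect_error(deviation(norm, "GF9", "In1", "In2"), "unknown criterion")
})

test_that("preference functions match their closed forms", {
  lin <- pf_spec("paper-linear")
  expect_equal(preference_value(0.334, lin), 0.334)
  expect_equal(preference_value(-0.334, lin), 0)
  # w = 0 returns 0 for every kind
  kinds <- list(lin, pf_spec("usual"), pf_spec("u-shape", q = 0.1),
                pf_spec("v-shape", p = 0.5), pf_spec("level", q = 0.1, p = 0.5),
                pf_spec("v-shape-indifference", q = 0.1, p = 0.5),
                pf_spec("gaussian", s = 0.5))
  for (spec in kinds) expect_equal(preference_value(0, spec), 0)
  # gaussian closed form
  expect_equal(preference_value(0.5, pf_spec("gaussian", s = 0.5)),
               1 - exp(-0.5), tolerance = 1e-12)
  # usual: indicator of a strictly positive deviation
  expect_equal(preference_value(c(-1, 1e-9, 2), pf_spec("usual")), c(0, 1, 1))
  # u-shape: indicator of exceeding q
  expect_equal(preference_value(c(0.1, 0.11), pf_spec("u-shape", q = 0.1)),
               c(0, 1))
  # v-shape: linear up to p then capped
  expect_equal(preference_value(c(0.25, 0.5, 0.9), pf_spec("v-shape", p = 0.5)),
               c(0.5, 1, 1))
  # level: 0 / 0.5 / 1 by thresholds
  expect_equal(preference_value(c(0.05, 0.3, 0.7),
                                pf_spec("level", q = 0.1, p = 0.5)),
               c(0, 0.5, 1))
  # v-shape with indifference: ramp between q and p
  expect_equal(preference_value(c(0.05, 0.3, 0.7),
                                pf_spec("v-shape-indifference", q = 0.1, p = 0.5)),
               c(0, 0.5, 1))
  # preference values lie in [0, 1] on the deviation range the pipeline
  # produces (paper-linear presumes normalized deviations, i.e. [-1, 1])
  w <- seq(-1, 1, by = 0.01)
  for (spec in kinds) {
    pv <- preference_value(w, spec)
    expect_true(all(pv >= 0 & pv <= 1))
    expect_true(all(pv[w <= 0] == 0))
  }
})

test_that("aggregation reproduces the worked 3-dp preference indices", {
  dm <- rtki_case_study()
  norm <- normalize_matrix(dm, rounding = 3)
  pref <- promethee2:::pairwise_preferences(norm, dm$criteria)
  pi_mat <- aggregate_preferences(pref, c(0.45, 0.35, 0.20), rounding = 3)
  expect_equal(pi_mat, expected_pi)
  # spot checks straight from the weighted sum
  expect_equal(pi_mat["In4", "In5"], 0.883) # 0.45*1 + 0.35*0.666 + 0.20*1
  expect_equal(pi_mat["In6", "In9"], 0.200) # only GF3 prefers In6 over In9
  # all-zero preferences aggregate to zero
  zero <- pref; zero[] <- 0
  pz <- aggregate_preferences(zero, c(0.45, 0.35, 0.20))
  expect_true(all(pz[!is.na(pz)] == 0))
  expect_error(aggregate_preferences(pref, c(0.5, 0.5)), "weights")
})

test_that("flows match the worked table at 6 decimals; ranks are competition", {
  res <- run_promethee2(rtki_case_study(), mode = "paper")
  fl <- res$flows
  phi_plus <- setNames(fl$phi_plus, fl$alternative)
  phi_minus <- setNames(fl$phi_minus, fl$alternative)
  phi_net <- setNames(fl$phi_net, fl$alternative)
  expect_equal(phi_plus, expected_phi_plus, tolerance = 1e-12)
  expect_equal(phi_minus, expected_phi_minus, tolerance = 1e-12)
  expect_equal(phi_net, expected_phi_net, tolerance = 1e-12)
  expect_identical(setNames(fl$rank, fl$alternative), expected_rank)
  # identical alternatives (In1, In2) share a rank
  expect_identical(fl$rank[fl$alternative == "In1"],
                   fl$rank[fl$alternative == "In2"])
  # flow errors on degenerate sizes
  expect_error(positive_flow(matrix(NA_real_, 1, 1)), "at least 2")
  expect_error(negative_flow(matrix(NA_real_, 1, 1)), "at least 2")
  expect_error(net_flow(1:3, 1:2), "equal length")
})

test_that("two-alternative problems rank by pairwise preference", {
  scores <- matrix(c(0.8, 0.2), ncol = 1, dimnames = list(c("a", "b"), "c1"))
  fl <- run_promethee2(decision_matrix(scores))$flows
  expect_identical(fl$rank[fl$alternative == "a"], 1L)
  expect_identical(fl$rank[fl$alternative == "b"], 2L)
})

test_that("one-shot pipeline equals the stage-by-stage composition", {
  set.seed(11)
  for (mode in c("paper", "full-precision")) {
    dm <- random_dm(6, 3)
    res <- run_promethee2(dm, mode = mode)
    rounding <- if (mode == "paper") 3 else NULL
    norm <- normalize_matrix(dm, rounding = rounding)
    pref <- promethee2:::pairwise_preferences(norm, dm$criteria)
    pi_mat <- aggregate_preferences(
      pref, vapply(dm$criteria, `[[`, numeric(1), "weight"), rounding = rounding)
    expect_identical(res$normalized$values, norm$values)
    expect_identical(res$preferences$aggregated, pi_mat)
    expect_identical(res$flows$phi_net,
                     unname(net_flow(positive_flow(pi_mat),
                                     negative_flow(pi_mat))))
  }
})

test_that("full-precision flows differ from paper mode only via rounding", {
  full <- run_promethee2(rtki_case_study(), mode = "full-precision")
  fl <- full$flows
  phi4 <- fl$phi_net[fl$alternative == "In4"]
  # unrounded recomputation oracle
  oracle <- oracle_promethee(rtki_case_study()$scores, c(0.45, 0.35, 0.20))
  expect_equal(fl$phi_net, oracle$phi, tolerance = 1e-12)
  expect_equal(phi4, 0.5139, tolerance = 1e-4)
  # same leader either way, but third decimals move
  expect_identical(fl$alternative[fl$rank == 1], "In4")
  paper <- run_promethee2(rtki_case_study(), mode = "paper")
  expect_false(isTRUE(all.equal(fl$phi_net, paper$flows$phi_net,
                                tolerance = 1e-6)))
})

test_that("flow conservation, range and mutual exclusion hold on random data", {
  set.seed(23)
  for (i in 1:25) {
    dm <- random_dm(sample(2:9, 1), sample(1:4, 1))
    res <- run_promethee2(dm)
    fl <- res$flows
    expect_lt(abs(sum(fl$phi_net)), 1e-9)
    expect_equal(sum(fl$phi_plus), sum(fl$phi_minus), tolerance = 1e-9)
    expect_true(all(fl$phi_plus >= 0 & fl$phi_plus <= 1))
    expect_true(all(fl$phi_minus >= 0 & fl$phi_minus <= 1))
    # linear preference: strict preference in one direction zeroes the other
    pref <- res$preferences$per_criterion
    for (j in seq_len(dim(pref)[3])) {
      pj <- pref[, , j]
      prod <- pj * t(pj)
      expect_true(all(prod[!is.na(prod)] == 0))
    }
  }
})

test_that("pipeline equals the naive double-loop oracle within 1e-12", {
  set.seed(31)
  for (i in 1:30) {
    m <- sample(2:5, 1); k <- sample(1:3, 1)
    dm <- random_dm(m, k)
    fl <- run_promethee2(dm)$flows
    oracle <- oracle_promethee(dm$scores,
                               vapply(dm$criteria, `[[`, numeric(1), "weight"))
    expect_equal(fl$phi_plus, oracle$phi_plus, tolerance = 1e-12)
    expect_equal(fl$phi_minus, oracle$phi_minus, tolerance = 1e-12)
    expect_equal(fl$phi_net, oracle$phi, tolerance = 1e-12)
    expect_identical(fl$rank, as.integer(oracle$rank))
  }
})

test_that("rankings are invariant to positive affine rescaling of raw columns", {
  set.seed(47)
  for (i in 1:10) {
    dm <- random_dm(sample(3:7, 1), 3)
    base <- run_promethee2(dm)
    scaled <- dm
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    j <- sample(3, 1)
    scaled$scores[, j] <- a * dm$scores[, j] + b
    res <- run_promethee2(scaled)
    expect_equal(res$normalized$values, base$normalized$values,
                 tolerance = 1e-9)
    expect_identical(res$flows$rank, base$flows$rank)
  }
})

test_that("a dominating alternative attains rank 1", {
  set.seed(59)
  for (i in 1:10) {
    m <- sample(3:7, 1); k <- sample(2:4, 1)
    scores <- matrix(runif(m * k), m, k,
                     dimnames = list(paste0("A", 1:m), paste0("C", 1:k)))
    scores[1, ] <- apply(scores, 2, max)        # weak dominance everywhere
    scores[1, 1] <- max(scores[, 1]) + 0.5      # strict somewhere
    fl <- run_promethee2(decision_matrix(scores))$flows
    expect_identical(fl$rank[fl$alternative == "A1"], 1L)
  }
})

test_that("the outranking graph exports arcs above the threshold", {
  res <- run_promethee2(rtki_case_study(), mode = "paper")
  pi_mat <- res$preferences$aggregated
  all_arcs <- export_outranking_graph(pi_mat, threshold = 0)
  expect_identical(nrow(all_arcs), 9L * 8L) # both arcs for each of 36 pairs
  strong <- export_outranking_graph(pi_mat, threshold = 0.5)
  hit <- strong[strong$from == "In4" & strong$to == "In5", ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$weight, 0.883)
  expect_true(all(strong$weight >= 0.5))
  expect_identical(nrow(export_outranking_graph(pi_mat, threshold = 1.1)), 0L)
  expect_error(export_outranking_graph(pi_mat, threshold = -0.1),
               "non-negative")
})
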