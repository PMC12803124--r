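# Unloaded-volume heuristic and score-space volume matching.

test_that("the linear unloaded-volume heuristic evaluates exactly", {
  expect_equal(estimate_unloaded_volume(120), 0.5025 * 120 + 5.7574)
  expect_equal(estimate_unloaded_volume(120), 66.0574)
  expect_error(estimate_unloaded_volume(0), "> 0")
  expect_error(estimate_unloaded_volume(-5), "> 0")
  expect_gt(estimate_unloaded_volume(150), estimate_unloaded_volume(100))
})

test_that("a target equal to the current volume converges in zero iterations", {
  fx <- fixture_small()
  s <- fx$cohort_scores[[1]]
  v <- chamber_volume(reconstruct_pair(fx$atlas, s)$ed, "LV")
  res <- unload_scores(fx$atlas, s, v)
  expect_true(res$converged)
  expect_equal(res$iterations, 0L)
  expect_identical(res$unloaded_scores, as.numeric(s))
})

test_that("single-mode volume matching agrees with a 1-D root-finding oracle", {
  fx <- fixture_small()
  atl <- fx$atlas
  s0 <- rep(0, 3)
  v_of_s1 <- function(s1) chamber_volume(reconstruct_pair(atl, c(s1, 0, 0))$ed, "LV")
  v_start <- v_of_s1(0)
  target <- 0.75 * v_start
  s_star <- uniroot(function(s1) v_of_s1(s1) - target, c(-6, 6),
                    extendInt = "yes", tol = 1e-8)$root
  res <- unload_scores(atl, s0, target, free_modes = 1, lambda = 0,
                       max_iters = 300)
  expect_true(res$converged)
  expect_lt(abs(res$v0_achieved - target), 0.1)
  expect_lt(abs(res$unloaded_scores[1] - s_star), 0.05)
  expect_lt(max(abs(res$unloaded_scores[-1])), 1e-12)
})

test_that("converged results respect the 0.1 mL tolerance and decrease the objective", {
  fx <- fixture_small()
  atl <- fx$atlas
  for (i in 1:3) {
    s <- fx$cohort_scores[[i]]
    lvedv <- chamber_volume(reconstruct_pair(atl, s)$ed, "LV")
    v0 <- estimate_unloaded_volume(lvedv)
    res <- unload_scores(atl, s, v0, max_iters = 120)
    if (res$converged) {
      expect_lte(abs(res$v0_achieved - res$v0_target), 0.1)
    }
    if (length(res$objective_trace) > 1) {
      expect_true(all(diff(res$objective_trace) <= 1e-9))
    }
    # deterministic: same inputs, same outputs
    res2 <- unload_scores(atl, s, v0, max_iters = 120)
    expect_identical(res$unloaded_scores, res2$unloaded_scores)
  }
})

test_that("the unloaded cloud is the ED half re-tagged as UNLOADED", {
  fx <- fixture_small()
  s <- fx$cohort_scores[[2]]
  res <- unload_scores(fx$atlas, s,
                       estimate_unloaded_volume(
                         chamber_volume(reconstruct_pair(fx$atlas, s)$ed, "LV")),
                       max_iters = 60)
  ucl <- unloaded_cloud(fx$atlas, res)
  expect_equal(ucl$frame, "UNLOADED")
  pr <- reconstruct_pair(fx$atlas, res$unloaded_scores)
  expect_equal(ucl$points, pr$ed$points)
})
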