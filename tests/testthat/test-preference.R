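test_that("2AFC scores follow the distance-to-shoal definition", {
  fc <- c(0, 0); nc <- c(10, 0)
  at <- function(x) data.table::data.table(
    trial_id = 1, age = 1, t_step = 1:5, fish_id = 1, color = "orange",
    x = x, y = 0, heading_deg = 0)
  expect_equal(two_afc_score(at(rep(0, 5)), fc, nc), 1)      # parked familiar
  expect_equal(two_afc_score(at(rep(10, 5)), fc, nc), 0)     # parked novel
  expect_equal(two_afc_score(at(rep(5, 5)), fc, nc), 0.5)    # bisector tie
  expect_equal(two_afc_score(at(c(0, 0, 0, 10, 5)), fc, nc), 0.7)
  # a symmetric random walker scores one half on average
  set.seed(8)
  scores <- replicate(60, {
    w <- simulate_independent_walkers(1, 150, arena = arena_square(20))
    two_afc_score(w, c(5, 10), c(15, 10))
  })
  expect_lt(abs(mean(scores) - 0.5), 3 * sd(scores) / sqrt(60))
})

test_that("self-segregation separates colored clusters and respects nulls", {
  # two tight same-color clusters far apart
  mk <- function(id, col, cx) data.table::data.table(
    trial_id = 1, age = 1, t_step = 1:3, fish_id = id, color = col,
    x = cx + 0.1 * id, y = 0, heading_deg = 0)
  tr <- rbind(mk(1, "orange", 0), mk(2, "orange", 0),
              mk(3, "blue", 20), mk(4, "blue", 20))
  sc <- self_segregation_scores(tr)
  expect_true(all(sc$in_group < sc$out_group))
  # symmetric under color-label swap
  tr_sw <- data.table::copy(tr)
  tr_sw[, color := ifelse(color == "orange", "blue", "orange")]
  sc_sw <- self_segregation_scores(tr_sw)
  expect_equal(sc$in_group, sc_sw$in_group)
  expect_equal(sc$out_group, sc_sw$out_group)
  # colors assigned at random to independent walkers show no separation
  set.seed(9)
  w <- simulate_independent_walkers(6, 2500, seed = 10)
  w[, color := rep(c("orange", "blue"), 3)[fish_id]]
  scn <- self_segregation_scores(w)
  expect_lt(abs(mean(scn$in_group - scn$out_group)),
            0.2 * mean(scn$out_group))
  # single-member color yields NA in-group distance
  solo <- rbind(mk(1, "orange", 0), mk(2, "blue", 5), mk(3, "blue", 6))
  sc2 <- self_segregation_scores(solo)
  expect_true(is.na(sc2$in_group[sc2$fish_id == 1]))
  expect_error(self_segregation_scores(mk(1, "orange", 0)), "2 colors")
})

test_that("preference tests match their t-test definitions and edge cases", {
  # all scores exactly at chance
  sc <- data.table::data.table(fish_id = 1, score = rep(0.5, 10))
  out <- preference_tests(sc, "2afc")
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  # degenerate variance away from the null is reported as the limit case
  sc1 <- data.table::data.table(fish_id = 1, score = rep(1, 10))
  out1 <- preference_tests(sc1, "2afc")
  expect_equal(out1$p_value, 0)
  # power sanity check on strong preferences
  set.seed(11)
  sc2 <- data.table::data.table(fish_id = 1,
                                score = rnorm(1000, 0.6, 0.05))
  out2 <- preference_tests(sc2, "2afc")
  expect_lt(out2$p_value, 1e-3)
  # paired segregation test agrees with t.test directly
  set.seed(12)
  seg <- data.table::data.table(fish_id = 1, in_group = rnorm(20, 3, 0.5),
                                out_group = rnorm(20, 5, 0.5))
  out3 <- preference_tests(seg, "segregation")
  ref <- t.test(seg$out_group, seg$in_group, paired = TRUE)
  expect_equal(out3$statistic, unname(ref$statistic))
  expect_equal(out3$p_value, ref$p.value)
  expect_error(preference_tests(
    data.table::data.table(fish_id = 1, score = 0.7), "2afc"), "2 samples")
})
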