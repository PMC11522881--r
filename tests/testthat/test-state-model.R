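test_that("state enumeration is a 24-element bijection", {
  ss <- state_space()
  expect_equal(nrow(ss), 24L)
  expect_equal(ss$state_id, 0:23)
  expect_equal(nrow(dplyr::distinct(ss[-1])), 24L)
  # first element of the canonical order
  expect_equal(state_index("mobile", "none", "none", "single"), 0L)
  # round trip through labels and back
  expect_equal(
    state_index(ss$house, ss$savings, ss$tenure, ss$family),
    ss$state_id
  )
  expect_equal(state_config(ss$state_id), ss)
  expect_error(state_index("yurt", "none", "none", "single"), "unknown state")
  expect_error(state_config(24), "0..23")
})

test_that("pay-off tables are scaled to [0, 1] and honour stated orderings", {
  for (sc in payoff_scenarios()) {
    pt <- payoff_table(sc)
    expect_equal(nrow(pt), 24L)
    expect_equal(min(pt$payoff), 0)
    expect_equal(max(pt$payoff), 1)
  }
  # family priority rewards the family state only
  fp <- payoff_table("family_priority")
  per_level <- dplyr::summarise(
    dplyr::group_by(fp, family), d = diff(range(payoff)), .groups = "drop"
  )
  expect_true(all(per_level$d == 0))
  # house priority: house+tenure+savings > house+tenure > house alone
  hp <- payoff_table("house_priority")
  v <- function(s, l) hp$payoff[hp$house == "fixed" & hp$savings == s &
                                  hp$tenure == l & hp$family == "single"]
  expect_gt(v("has", "has"), v("none", "has"))
  expect_gt(v("none", "has"), v("none", "none"))
  # material baseline: worst configuration pays nothing
  mb <- payoff_table("material_baseline")
  expect_equal(mb$payoff[mb$state_id == 0], 0)
})

test_that("pay-off weights are overridable and validated", {
  pt <- payoff_table("house_priority",
                     weights = list(house = 0.5, tenure = 0.3, savings = 0.2))
  expect_equal(max(pt$payoff), 1)
  expect_equal(
    pt$payoff[pt$state_id == state_index("fixed", "none", "none", "single")],
    0.5
  )
  expect_error(payoff_table("additive", weights = list(apartment = 1)),
               "unknown pay-off weight")
  expect_error(payoff_table("penthouse_priority"))
})

test_that("transition distributions are proper for random parameter draws", {
  set.seed(101)
  for (i in 1:100) {
    k <- dwellsim:::kernel_array(random_params())
    sums <- apply(k, c(1, 3), sum)
    expect_true(max(abs(sums - 1)) < 1e-12)
    expect_true(min(k) >= 0)
  }
})

test_that("kernel matches the event-tree oracle on every cell", {
  set.seed(202)
  for (i in 1:10) {
    p <- random_params()
    k <- dwellsim:::kernel_array(p)
    for (sid in 0:23) {
      for (b in behaviours()) {
        oracle <- step_outcomes(sid, b, p)
        got <- k[sid + 1L, , match(b, behaviours())]
        expect_equal(got[oracle$next_state_id + 1L], oracle$prob,
                     tolerance = 1e-12)
        expect_equal(sum(got[-(oracle$next_state_id + 1L)]), 0)
      }
    }
  }
})

test_that("degenerate kernels are point masses", {
  # certain move: tenure gained, fixed house abandoned, family frozen
  p <- model_params(0, 0, 1, 0, 0,
                    family_growth = family_growth_spec(base_prob = 0))
  from <- state_index("fixed", "has", "has", "couple")
  k <- transition_kernel(p, state = from, behaviour = "move")
  expect_equal(nrow(k), 1L)
  expect_equal(k$next_state_id, state_index("mobile", "has", "has", "couple"))
  expect_equal(k$prob, 1)
  # all probabilities zero: every behaviour leaves every state unchanged
  pz <- frozen_params()
  kz <- dwellsim:::kernel_array(pz)
  for (b in 1:3) expect_equal(kz[, , b], diag(24), ignore_attr = TRUE)
})

test_that("structural invariants: family monotone, build gated by savings", {
  set.seed(303)
  fam_level <- dwellsim:::decode_state(0:23)$f
  for (i in 1:20) {
    p <- random_params(build_condition = 1L)
    k <- dwellsim:::kernel_array(p)
    for (sid in 0:23) {
      d <- dwellsim:::decode_state(sid)
      for (b in 1:3) {
        support <- which(k[sid + 1L, , b] > 0) - 1L
        # family level never decreases
        expect_true(all(fam_level[support + 1L] >= d$f))
        # under build condition 1, no fixed house can appear without savings
        if (d$h == 0L && d$s == 0L) {
          expect_true(all(dwellsim:::decode_state(support)$h == 0L))
        }
      }
    }
  }
})
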