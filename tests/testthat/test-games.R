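# Payoff engine against the printed game rules, and the decision-variable
# schema.

test_that("payoffs of the simultaneous binary games follow the printed matrices", {
  # chicken game
  expect_equal(compute_payoff("CG", list(player1 = "proceed", player2 = "proceed")),
               c(player1 = 0, player2 = 0))
  expect_equal(compute_payoff("CG", list(player1 = "turn back", player2 = "turn back")),
               c(player1 = 300, player2 = 300))
  expect_equal(compute_payoff("CG", list(player1 = "proceed", player2 = "turn back")),
               c(player1 = 1200, player2 = 300))
  expect_equal(compute_payoff("CG", list(player1 = "turn back", player2 = "proceed")),
               c(player1 = 300, player2 = 1200))
  # stag hunt
  expect_equal(compute_payoff("SH", list(player1 = "invest", player2 = "invest")),
               c(player1 = 1000, player2 = 1000))
  expect_equal(compute_payoff("SH", list(player1 = "keep", player2 = "keep")),
               c(player1 = 500, player2 = 500))
  expect_equal(compute_payoff("SH", list(player1 = "invest", player2 = "keep")),
               c(player1 = 0, player2 = 500))
})

test_that("preemptive strike payoffs follow the printed conditions", {
  none <- list(player1 = FALSE, player2 = FALSE)
  p1 <- list(player1 = TRUE, player2 = FALSE)
  p2 <- list(player1 = FALSE, player2 = TRUE)
  for (cond in c("55", "1010", "510", "105"))
    expect_equal(compute_payoff("PSG", none, cond),
                 c(player1 = 1500, player2 = 1500))
  expect_equal(compute_payoff("PSG", p2, "55"), c(player1 = 500, player2 = 1300))
  expect_equal(compute_payoff("PSG", p1, "55"), c(player1 = 1300, player2 = 500))
  expect_equal(compute_payoff("PSG", p2, "1010"), c(player1 = 1000, player2 = 1300))
  expect_equal(compute_payoff("PSG", p1, "1010"), c(player1 = 1300, player2 = 100))
  expect_equal(compute_payoff("PSG", p2, "510"), c(player1 = 500, player2 = 1300))
  expect_equal(compute_payoff("PSG", p1, "510"), c(player1 = 1300, player2 = 1000))
  expect_equal(compute_payoff("PSG", p2, "105"), c(player1 = 1000, player2 = 1300))
  expect_equal(compute_payoff("PSG", p1, "105"), c(player1 = 1300, player2 = 500))
  expect_error(compute_payoff("PSG", list(player1 = TRUE, player2 = TRUE), "55"),
               "one player")
  expect_error(compute_payoff("PSG", none), "condition")
})

test_that("transfer multipliers follow the printed rules", {
  # PDG-II: the gift is doubled
  expect_equal(compute_payoff("PDG-II", list(player1 = 1000, player2 = 0)),
               c(player1 = 0, player2 = 3000))
  # PDG-I with the three endowment conditions
  for (e in c(300, 800, 1500)) {
    both <- compute_payoff("PDG-I", list(player1 = TRUE, player2 = TRUE), e)
    expect_equal(unname(both), c(2 * e, 2 * e))
    one <- compute_payoff("PDG-I", list(player1 = TRUE, player2 = FALSE), e)
    expect_equal(unname(one), c(0, 3 * e))
  }
  # trust game: tripled transfer, strategy-method return
  expect_equal(compute_payoff("TG", list(transfer = 1000, return_fraction = 0.5)),
               c(trustor = 1500, trustee = 1500))
  expect_equal(compute_payoff("TG", list(transfer = 0, return_fraction = 0.5)),
               c(trustor = 1000, trustee = 0))
  # faith game: the distribution is tripled
  expect_equal(compute_payoff("Faith", list(entrusted = 600, distributed = 300)),
               c(recipient = 400 + 900, distributor = 300))
  # public goods: pot tripled and split equally
  expect_equal(unname(compute_payoff("PGG-I", list(contributions = rep(1000, 4)))),
               rep(3000, 4))
  expect_equal(unname(compute_payoff("PGG-II", list(contributions = c(0, 0, 0, 1000)))),
               c(1750, 1750, 1750, 750))
})

test_that("punishment multipliers follow the printed rules", {
  # SPPG: the amount spent is doubled and deducted from the opponent
  base <- compute_payoff("SPPG", list(given = c(0, 0), punishment = c(0, 0)))
  pun <- compute_payoff("SPPG", list(given = c(0, 0), punishment = c(500, 0)))
  expect_equal(base[["player2"]] - pun[["player2"]], 1000)
  expect_equal(base[["player1"]] - pun[["player1"]], 500)
  # TPPG: three times the amount spent is deducted from the distributor
  t1 <- compute_payoff("TPPG-I", list(allocation = 0, punishment = 500))
  expect_equal(t1[["distributor"]], 1500 - 1500)
  expect_equal(t1[["third_party"]], -500)
  t2 <- compute_payoff("TPPG-II", list(allocation = 500, punishment = 300))
  expect_equal(t2[["distributor"]], 1500 - 500 - 900)
  expect_equal(t2[["third_party"]], 500 - 300)
  # PGG with punishment: double the fund, deducted from the lowest contributor
  pp <- compute_payoff("PGG-P", list(contributions = c(0, 500, 500, 1000),
                                     punishment_fund = c(100, 100, 0, 100)))
  no_pun <- compute_payoff("PGG-I", list(contributions = c(0, 500, 500, 1000)))
  expect_equal(pp[["player1"]], no_pun[["player1"]] - 100 - 2 * 300)
  expect_equal(pp[["player3"]], no_pun[["player3"]])
})

test_that("split games conserve the (multiplied) pie", {
  for (e in c(1000, 300, 400, 600, 700, 1200, 1300))
    expect_equal(sum(compute_payoff("DG", list(allocation = 100), e)), e)
  expect_equal(sum(compute_payoff("UG", list(offer = 600, accept = TRUE))), 1500)
  expect_equal(sum(compute_payoff("UG", list(offer = 600, accept = FALSE))), 0)
  for (t in seq(0, 1000, by = 200)) for (r in c(0, 0.3, 1)) {
    pay <- compute_payoff("TG", list(transfer = t, return_fraction = r))
    expect_equal(sum(pay), 1000 + 2 * t)
  }
})

test_that("invalid games, actions and conditions are rejected", {
  expect_error(compute_payoff("poker", list()), "unknown game")
  expect_error(compute_payoff("DG", list(allocation = 1100)), "out of range")
  expect_error(compute_payoff("DG", list(allocation = 150)), "increments")
  expect_error(compute_payoff("PDG-I", list(player1 = TRUE, player2 = TRUE), 500),
               "condition")
  expect_error(compute_payoff("TPPG-I", list(allocation = 0, punishment = 600)),
               "out of range")
  expect_error(compute_payoff("PGG-I", list(contributions = c(100, 100))),
               "at least 4")
  expect_error(compute_payoff("Faith", list(entrusted = 300, distributed = 400)),
               "out of range")
})

test_that("the default schema enumerates 108 tagged variables over all 15 games", {
  sch <- default_variable_schema()
  expect_equal(nrow(sch), 108)
  expect_setequal(unique(sch$game), game_names())
  expect_true(all(table(sch$game) >= 1))
  expect_true(all(sch$direction %in% c("prosocial", "punishment", "other")))
  # ultimatum responder strategy method: one accept/reject cell per offer
  expect_equal(sum(sch$game == "UG" & sch$role == "responder"), 16)
  expect_true(all(sch$increment > 0))
  expect_true(all(sch$hi > sch$lo))
})

test_that("the schema is configurable by game subset", {
  sch <- default_variable_schema(games = c("DG", "UG"))
  expect_setequal(unique(sch$game), c("DG", "UG"))
  expect_equal(nrow(sch), 7 + 17)
  expect_error(default_variable_schema(games = "whist"), "unknown game")
})
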