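# Payoff engine for the fifteen economic games and the default enumeration of
# the decision variables they produce. Amounts are Japanese yen (JPY).

#' Names of the fifteen economic games
#'
#' @return Character vector of game identifiers: prisoner's dilemma games I/II
#'   (`PDG-I`, `PDG-II`), dictator game (`DG`), faith game (`Faith`), public
#'   goods games (`PGG-I`, `PGG-II`, `PGG-P` with punishment), second- and
#'   third-party punishment games (`SPPG`, `TPPG-I`, `TPPG-II`), trust game
#'   (`TG`), ultimatum game (`UG`), preemptive strike game (`PSG`), chicken
#'   game (`CG`) and stag hunt (`SH`).
#' @export
game_names <- function() {
  c("PDG-I", "DG", "Faith", "PGG-I", "PDG-II", "SPPG", "TG", "UG",
    "TPPG-I", "TPPG-II", "PSG", "CG", "PGG-II", "PGG-P", "SH")
}

check_amount <- function(x, lo, hi, inc, name, game) {
  if (is.null(x) || length(x) == 0 || anyNA(x) || !is.numeric(x))
    stopf("%s: missing or non-numeric '%s'", game, name)
  if (any(x < lo - 1e-9) || any(x > hi + 1e-9))
    stopf("%s: '%s' out of range [%s, %s]", game, name, lo, hi)
  if (any(abs(x / inc - round(x / inc)) > 1e-9))
    stopf("%s: '%s' must be in increments of %s", game, name, inc)
  x
}

check_flag <- function(x, name, game) {
  if (is.null(x) || length(x) != 1 || is.na(x) || !is.logical(x))
    stopf("%s: '%s' must be a single TRUE/FALSE", game, name)
  x
}

check_choice <- function(x, allowed, name, game) {
  if (is.null(x) || length(x) != 1 || !(x %in% allowed))
    stopf("%s: '%s' must be one of %s", game, name,
          paste(allowed, collapse = ", "))
  x
}

#' Compute game payoffs from the printed rules
#'
#' Applies the exact payoff rule of one of the fifteen economic games to a set
#' of decisions. Transfers are multiplied as each game prescribes (doubled
#' gifts in the prisoner's dilemma variants and second-party punishment,
#' tripled transfers in the trust and faith games and public goods pots,
#' tripled deductions in third-party punishment).
#'
#' @param game Game identifier, one of [game_names()].
#' @param actions Named list of decisions. The expected fields depend on the
#'   game: symmetric binary games (`PDG-I`, `CG`, `SH`, `PSG`) take `player1`
#'   and `player2`; `DG` takes `allocation`; `Faith` takes `entrusted` and
#'   `distributed`; public goods games take `contributions` (and
#'   `punishment_fund` for `PGG-P`); `PDG-II` takes `player1`/`player2`
#'   amounts; `SPPG` takes `given` and `punishment` (length-2 each); `TG`
#'   takes `transfer` and `return_fraction`; `UG` takes `offer` and `accept`;
#'   `TPPG-I`/`TPPG-II` take `allocation` and `punishment`.
#' @param condition Condition label where the game has one: the `PDG-I`
#'   endowment (300, 800 or 1500), the `DG` endowment, or the preemptive
#'   strike condition ("55", "1010", "510", "105").
#' @return Named numeric vector of payoffs in JPY, one entry per role.
#' @examples
#' compute_payoff("CG", list(player1 = "proceed", player2 = "turn back"))
#' compute_payoff("TG", list(transfer = 1000, return_fraction = 0.5))
#' @export
compute_payoff <- function(game, actions, condition = NULL) {
  if (!is.character(game) || length(game) != 1 || !(game %in% game_names()))
    stopf("unknown game '%s'", paste(game, collapse = ","))
  switch(game,
    "PDG-I" = {
      e <- check_choice(condition, c(300, 800, 1500), "condition", game)
      g1 <- check_flag(actions$player1, "player1", game)
      g2 <- check_flag(actions$player2, "player2", game)
      c(player1 = (!g1) * e + g2 * 2 * e,
        player2 = (!g2) * e + g1 * 2 * e)
    },
    "DG" = {
      e <- check_choice(condition %||% 1000,
                        c(1000, 300, 400, 600, 700, 1200, 1300),
                        "condition", game)
      a <- check_amount(actions$allocation, 0, e, 100, "allocation", game)
      c(dictator = e - a, recipient = a)
    },
    "Faith" = {
      k <- check_amount(actions$entrusted, 0, 1000, 100, "entrusted", game)
      d <- check_amount(actions$distributed, 0, k, 100, "distributed", game)
      c(recipient = (1000 - k) + 3 * d, distributor = k - d)
    },
    "PGG-I" = ,
    "PGG-II" = {
      cc <- actions$contributions
      if (length(cc) < 4) stopf("%s: needs at least 4 players", game)
      cc <- check_amount(cc, 0, 1000, 100, "contributions", game)
      p <- 1000 - cc + 3 * sum(cc) / length(cc)
      stats::setNames(p, paste0("player", seq_along(p)))
    },
    "PDG-II" = {
      g1 <- check_amount(actions$player1, 0, 1000, 100, "player1", game)
      g2 <- check_amount(actions$player2, 0, 1000, 100, "player2", game)
      c(player1 = 1000 - g1 + 2 * g2, player2 = 1000 - g2 + 2 * g1)
    },
    "SPPG" = {
      g <- check_amount(actions$given, 0, 1000, 100, "given", game)
      s <- check_amount(actions$punishment, 0, 1500, 100, "punishment", game)
      if (length(g) != 2 || length(s) != 2)
        stopf("%s: 'given' and 'punishment' must each have length 2", game)
      c(player1 = 1000 - g[1] + 2 * g[2] - s[1] - 2 * s[2],
        player2 = 1000 - g[2] + 2 * g[1] - s[2] - 2 * s[1])
    },
    "TG" = {
      t <- check_amount(actions$transfer, 0, 1000, 100, "transfer", game)
      r <- check_amount(actions$return_fraction, 0, 1, 0.1,
                        "return_fraction", game)
      c(trustor = 1000 - t + r * 3 * t, trustee = (1 - r) * 3 * t)
    },
    "UG" = {
      o <- check_amount(actions$offer, 0, 1500, 100, "offer", game)
      a <- check_flag(actions$accept, "accept", game)
      if (a) c(proposer = 1500 - o, responder = o)
      else   c(proposer = 0, responder = 0)
    },
    "TPPG-I" = ,
    "TPPG-II" = {
      a <- check_amount(actions$allocation, 0, 1500, 100, "allocation", game)
      s <- check_amount(actions$punishment, 0, 500, 100, "punishment", game)
      tp <- if (game == "TPPG-I") -s else 500 - s
      c(distributor = 1500 - a - 3 * s, recipient = a, third_party = tp)
    },
    "PSG" = {
      cond <- check_choice(as.character(condition %||% ""),
                           c("55", "1010", "510", "105"), "condition", game)
      p1 <- check_flag(actions$player1, "player1", game)
      p2 <- check_flag(actions$player2, "player2", game)
      if (p1 && p2)
        stopf("%s: only one player can press the button", game)
      if (!p1 && !p2) return(c(player1 = 1500, player2 = 1500))
      # payoff of the player who did not press, by condition and presser
      loser_if_p1 <- c("55" = 500, "1010" = 100, "510" = 1000, "105" = 500)
      loser_if_p2 <- c("55" = 500, "1010" = 1000, "510" = 500, "105" = 1000)
      if (p1) c(player1 = 1300, player2 = unname(loser_if_p1[cond]))
      else    c(player1 = unname(loser_if_p2[cond]), player2 = 1300)
    },
    "CG" = {
      ch <- c("proceed", "turn back")
      a1 <- check_choice(actions$player1, ch, "player1", game)
      a2 <- check_choice(actions$player2, ch, "player2", game)
      pay <- function(me, other) {
        if (me == "proceed" && other == "proceed") 0
        else if (me == "proceed") 1200
        else 300
      }
      c(player1 = pay(a1, a2), player2 = pay(a2, a1))
    },
    "PGG-P" = {
      cc <- actions$contributions
      if (length(cc) < 4) stopf("%s: needs at least 4 players", game)
      cc <- check_amount(cc, 0, 1000, 100, "contributions", game)
      f <- check_amount(actions$punishment_fund, 0, 300, 10,
                        "punishment_fund", game)
      if (length(f) != length(cc))
        stopf("%s: one punishment-fund entry per player", game)
      base <- 1000 - cc + 3 * sum(cc) / length(cc)
      pen <- 2 * sum(f)
      # the lowest contributor is punished; ties are all punished (declared)
      lose <- cc == min(cc)
      p <- base - f - lose * pen
      stats::setNames(p, paste0("player", seq_along(p)))
    },
    "SH" = {
      ch <- c("invest", "keep")
      a1 <- check_choice(actions$player1, ch, "player1", game)
      a2 <- check_choice(actions$player2, ch, "player2", game)
      pay <- function(me, other) {
        if (me == "invest") { if (other == "invest") 1000 else 0 }
        else 500
      }
      c(player1 = pay(a1, a2), player2 = pay(a2, a1))
    }
  )
}

schema_row <- function(variable, game, role, type, lo, hi, inc, direction,
                       description) {
  data.frame(variable = variable, game = game, role = role, type = type,
             lo = lo, hi = hi, increment = inc, direction = direction,
             description = description, stringsAsFactors = FALSE)
}

#' Default decision-variable schema for the fifteen games
#'
#' Enumerates the behavioral decision variables produced by the games,
#' including one variable per strategy-method grid cell (trustee returns for
#' each transfer level, ultimatum accept/reject for each offer, punishment
#' expenditure for each opponent cooperation level or distributor allocation).
#' The default enumeration has 108 variables; the set is configurable by
#' restricting `games`.
#'
#' Each variable carries a direction tag: `prosocial` (giving, contributing,
#' trusting, investing), `punishment` (second/third-party punishment
#' expenditure, punishment-fund contributions, preemptive strikes, proceeding
#' in chicken) or `other` (decisions with no declared prosocial/aggressive
#' direction, e.g. ultimatum responder acceptance).
#'
#' @param games Subset of [game_names()] to include.
#' @return data.frame with columns `variable`, `game`, `role`, `type`
#'   (binary/amount/fraction), `lo`, `hi`, `increment`, `direction`,
#'   `description`.
#' @export
default_variable_schema <- function(games = game_names()) {
  unknown <- setdiff(games, game_names())
  if (length(unknown)) stopf("unknown game(s): %s", paste(unknown, collapse = ", "))
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  if ("PDG-I" %in% games) {
    for (e in c(300, 800, 1500)) {
      add(schema_row(sprintf("pdg1_sim_%d", e), "PDG-I", "player", "binary",
                     0, 1, 1, "prosocial",
                     sprintf("simultaneous PD, give endowment JPY %d", e)))
      add(schema_row(sprintf("pdg1_first_%d", e), "PDG-I", "player", "binary",
                     0, 1, 1, "prosocial",
                     sprintf("sequential PD moving first, endowment JPY %d", e)))
      add(schema_row(sprintf("pdg1_second_given_%d", e), "PDG-I", "player",
                     "binary", 0, 1, 1, "prosocial",
                     sprintf("sequential PD second, opponent gave, JPY %d", e)))
      add(schema_row(sprintf("pdg1_second_notgiven_%d", e), "PDG-I", "player",
                     "binary", 0, 1, 1, "prosocial",
                     sprintf("sequential PD second, opponent kept, JPY %d", e)))
    }
  }
  if ("DG" %in% games) {
    for (e in c(1000, 300, 400, 600, 700, 1200, 1300))
      add(schema_row(sprintf("dg_%d", e), "DG", "dictator", "amount",
                     0, e, 100, "prosocial",
                     sprintf("dictator allocation from JPY %d", e)))
  }
  if ("Faith" %in% games) {
    add(schema_row("faith_entrusted", "Faith", "recipient", "amount",
                   0, 1000, 100, "prosocial",
                   "amount of JPY 1000 left to the distributor"))
    add(schema_row("faith_distributed", "Faith", "distributor", "amount",
                   0, 1000, 100, "prosocial",
                   "amount distributed (tripled to the recipient)"))
  }
  if ("PGG-I" %in% games)
    add(schema_row("pgg1_contribution", "PGG-I", "player", "amount",
                   0, 1000, 100, "prosocial", "public goods contribution"))
  if ("PDG-II" %in% games)
    add(schema_row("pdg2_given", "PDG-II", "player", "amount",
                   0, 1000, 100, "prosocial", "amount given (doubled)"))
  if ("SPPG" %in% games) {
    add(schema_row("sppg_given", "SPPG", "player", "amount",
                   0, 1000, 100, "prosocial", "PD-phase amount given"))
    for (c_opp in seq(0, 1000, by = 100))
      add(schema_row(sprintf("sppg_punish_c%d", c_opp), "SPPG", "player",
                     "amount", 0, 1500, 100, "punishment",
                     sprintf("punishment spend if opponent gave JPY %d", c_opp)))
  }
  if ("TG" %in% games) {
    add(schema_row("tg_transfer", "TG", "trustor", "amount",
                   0, 1000, 100, "prosocial", "amount transferred (tripled)"))
    for (t in seq(0, 1000, by = 100))
      add(schema_row(sprintf("tg_return_t%d", t), "TG", "trustee",
                     "fraction", 0, 1, 0.1, "prosocial",
                     sprintf("fraction returned if transfer was JPY %d", t)))
  }
  if ("UG" %in% games) {
    add(schema_row("ug_offer", "UG", "proposer", "amount",
                   0, 1500, 100, "prosocial", "proposer offer from JPY 1500"))
    for (o in seq(0, 1500, by = 100))
      add(schema_row(sprintf("ug_accept_o%d", o), "UG", "responder",
                     "binary", 0, 1, 1, "other",
                     sprintf("accept an offer of JPY %d", o)))
  }
  if ("TPPG-I" %in% games) {
    add(schema_row("tppg1_allocation", "TPPG-I", "distributor", "amount",
                   0, 1500, 100, "prosocial", "allocation to the recipient"))
    for (a in seq(0, 1500, by = 100))
      add(schema_row(sprintf("tppg1_punish_a%d", a), "TPPG-I", "third_party",
                     "amount", 0, 500, 100, "punishment",
                     sprintf("third-party spend if distributor gave JPY %d", a)))
  }
  if ("TPPG-II" %in% games) {
    for (a in seq(0, 1500, by = 100))
      add(schema_row(sprintf("tppg2_punish_a%d", a), "TPPG-II", "third_party",
                     "amount", 0, 500, 100, "punishment",
                     sprintf("endowed third-party spend if distributor gave JPY %d", a)))
  }
  if ("PSG" %in% games) {
    for (cond in c("55", "1010", "510", "105"))
      add(schema_row(sprintf("psg_press_%s", cond), "PSG", "player",
                     "binary", 0, 1, 1, "punishment",
                     sprintf("pressed the button, condition %s", cond)))
  }
  if ("CG" %in% games) {
    for (m in 1:3)
      add(schema_row(sprintf("cg_proceed_m%d", m), "CG", "player",
                     "binary", 0, 1, 1, "punishment",
                     sprintf("chose proceed, payoff matrix %d", m)))
    add(schema_row("cg_proceed_first", "CG", "player", "binary",
                   0, 1, 1, "punishment",
                   "chose proceed, participant-first condition"))
  }
  if ("PGG-II" %in% games)
    add(schema_row("pgg2_contribution", "PGG-II", "player", "amount",
                   0, 1000, 100, "prosocial", "public goods contribution"))
  if ("PGG-P" %in% games)
    add(schema_row("pggp_punishment_fund", "PGG-P", "player", "amount",
                   0, 300, 10, "punishment",
                   "contribution to the punishment fund"))
  if ("SH" %in% games)
    add(schema_row("sh_invest", "SH", "player", "binary",
                   0, 1, 1, "prosocial", "chose to invest"))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
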