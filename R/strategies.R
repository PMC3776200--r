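#' @importFrom rlang .data
NULL

strategy_trait_levels <- list(
  proposes    = c("never", "full_cost", "shared_cost"),
  committed   = c("C", "D"),
  uncommitted = c("C", "D", "no_play")
)

new_strategy_row <- function(name, proposes, accepts_full, accepts_shared,
                             committed, uncommitted) {
  tibble::tibble(
    name = name, proposes = proposes,
    accepts_full = accepts_full, accepts_shared = accepts_shared,
    committed = committed, uncommitted = uncommitted
  )
}

#' Strategy catalogs of the commitment game
#'
#' Each strategy is a behavioural rule with five traits: whether it
#' proposes a commitment (and whether it asks the partner to share the
#' arrangement cost), whether it accepts a full-cost or a shared-cost
#' proposal from others, its move inside an accepted deal, and its move
#' when no deal is active (`"no_play"` means it refuses to play at all).
#'
#' The `"basic"` catalog holds the five strategies of the core model:
#' * `COMP` — proposes a commitment at full cost, cooperates inside deals,
#'   refuses to play without one;
#' * `C` — unconditional cooperator, accepts any full-cost proposal;
#' * `D` — unconditional defector, rejects all proposals;
#' * `FAKE` — accepts a proposal but defects inside the deal (and pays the
#'   compensation);
#' * `FREE` — cooperates only when a deal is proposed to it, defects
#'   otherwise, and will not pay any part of the arrangement cost.
#'
#' The `"sharing"` catalog adds the cost-sharing proposer `COMS` (who asks
#' the partner to pay half of the arrangement cost) together with `CS`,
#' `FAKS` and `FRES`, the variants of `C`, `FAKE` and `FREE` that agree to
#' share the cost when asked. `C`, `FAKE` and `FREE` themselves reject
#' shared-cost proposals, so against `COMS` those encounters never happen.
#'
#' @param model `"basic"` (5 strategies) or `"sharing"` (9 strategies).
#'
#' @return A tibble with one row per strategy and columns `name`,
#'   `proposes`, `accepts_full`, `accepts_shared`, `committed`,
#'   `uncommitted`, in a fixed order (the order shown above).
#' @export
#' @examples
#' strategy_catalog("basic")
strategy_catalog <- function(model = c("basic", "sharing")) {
  model <- match.arg(model)
  basic <- dplyr::bind_rows(
    new_strategy_row("COMP", "full_cost", TRUE,  TRUE,  "C", "no_play"),
    new_strategy_row("C",    "never",     TRUE,  FALSE, "C", "C"),
    new_strategy_row("D",    "never",     FALSE, FALSE, "D", "D"),
    new_strategy_row("FAKE", "never",     TRUE,  FALSE, "D", "D"),
    new_strategy_row("FREE", "never",     TRUE,  FALSE, "C", "D")
  )
  if (model == "basic") return(basic)
  dplyr::bind_rows(
    basic,
    new_strategy_row("COMS", "shared_cost", TRUE, TRUE, "C", "no_play"),
    new_strategy_row("CS",   "never",       TRUE, TRUE, "C", "C"),
    new_strategy_row("FAKS", "never",       TRUE, TRUE, "D", "D"),
    new_strategy_row("FRES", "never",       TRUE, TRUE, "C", "D")
  )
}

validate_strategies <- function(strategies) {
  needed <- c("name", "proposes", "accepts_full", "accepts_shared",
              "committed", "uncommitted")
  if (!is.data.frame(strategies) || !all(needed %in% names(strategies))) {
    stop("strategies must be a data frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(strategies$name)) {
    stop("strategy names must be unique", call. = FALSE)
  }
  stopifnot(
    all(strategies$proposes %in% strategy_trait_levels$proposes),
    all(strategies$committed %in% strategy_trait_levels$committed),
    all(strategies$uncommitted %in% strategy_trait_levels$uncommitted),
    is.logical(strategies$accepts_full),
    is.logical(strategies$accepts_shared)
  )
  invisible(strategies)
}

strategy_as_list <- function(strategies, name) {
  i <- match(name, strategies$name)
  if (is.na(i)) stop("strategy '", name, "' not in catalog", call. = FALSE)
  as.list(strategies[i, ])
}

#' Enumerate the full behavioural strategy space
#'
#' Crosses every trait value (3 proposal modes, 2 x 2 acceptance rules,
#' 2 committed moves, 3 uncommitted moves: 72 raw combinations) and
#' collapses combinations that are behaviourally identical — i.e. whose
#' payoff rows and columns against the whole raw set coincide for every
#' point of a parameter grid spanning arrangement cost, compensation and
#' enforcement probability. Unreachable traits (a proposer's uncommitted
#' move, since a rejected proposal voids the game; the committed move of a
#' strategy that can never be party to a deal) are what the collapse
#' removes. Combinations matching a named catalog strategy keep its name;
#' the rest get systematic names `P<f|s|n>.A<b|f|s|n>.K<C|D>.U<C|D|O>`
#' (proposal mode, acceptance set, committed move, uncommitted move).
#'
#' @param game A `game_matrix` used for the deduplication grid (payoff
#'   identity is checked at this game across the (epsilon, delta, p) grid).
#'
#' @return A tibble of distinct strategies in the same format as
#'   [strategy_catalog()], catalog members first.
#' @export
enumerate_strategies <- function(game = donation_game(2, 1)) {
  grid <- expand.grid(
    proposes = strategy_trait_levels$proposes,
    accepts_full = c(TRUE, FALSE), accepts_shared = c(TRUE, FALSE),
    committed = strategy_trait_levels$committed,
    uncommitted = strategy_trait_levels$uncommitted,
    stringsAsFactors = FALSE
  )
  acc_code <- ifelse(grid$accepts_full,
                     ifelse(grid$accepts_shared, "b", "f"),
                     ifelse(grid$accepts_shared, "s", "n"))
  grid$name <- sprintf("P%s.A%s.K%s.U%s",
                       substr(grid$proposes, 1, 1), acc_code,
                       grid$committed,
                       ifelse(grid$uncommitted == "no_play", "O",
                              grid$uncommitted))
  raw <- tibble::as_tibble(grid[, c("name", "proposes", "accepts_full",
                                    "accepts_shared", "committed",
                                    "uncommitted")])

  # payoff signature over a parameter grid: rows and columns vs the raw set
  param_grid <- expand.grid(epsilon = c(0, 0.3, 1.1),
                            delta = c(0, 0.7, 3.1),
                            p = c(0.4, 1))
  sig <- vapply(seq_len(nrow(raw)), function(i) "", character(1))
  parts <- vector("list", nrow(param_grid))
  for (g in seq_len(nrow(param_grid))) {
    terms <- commitment_terms(param_grid$epsilon[g], param_grid$delta[g],
                              param_grid$p[g])
    M <- payoff_matrix_internal(raw, game, terms)
    parts[[g]] <- cbind(M, t(M))
  }
  all_sig <- do.call(cbind, parts)
  keys <- apply(round(all_sig, 9), 1, paste, collapse = ",")

  # prefer a catalog representative within each behavioural class
  catalog <- strategy_catalog("sharing")
  cat_idx <- vapply(seq_len(nrow(catalog)), function(i) {
    s <- catalog[i, ]
    which(raw$proposes == s$proposes &
            raw$accepts_full == s$accepts_full &
            raw$accepts_shared == s$accepts_shared &
            raw$committed == s$committed &
            raw$uncommitted == s$uncommitted)
  }, integer(1))
  raw$name[cat_idx] <- catalog$name

  pref <- rep(1L, nrow(raw))
  pref[cat_idx] <- 0L
  ord <- order(pref, seq_len(nrow(raw)))
  keep <- ord[!duplicated(keys[ord])]
  out <- raw[sort(keep), ]
  # catalog members first, in catalog order
  out <- dplyr::bind_rows(
    out[match(catalog$name, out$name), ],
    out[!(out$name %in% catalog$name), ]
  )
  out
}

#' Is a strategy (weakly) dominated within a payoff table?
#'
#' Strategy `s` is weakly dominated by another strategy `o` when `o`'s
#' payoff is at least `s`'s against every opponent in the table, and
#' strictly larger against at least one. With `strict = TRUE` the
#' inequality must be strict against every opponent.
#'
#' @param s Name of the focal strategy (must be in the table).
#' @param table A [payoff_table()].
#' @param by Names of candidate dominating strategies; defaults to all
#'   other strategies in the table.
#' @param strict Use strict dominance instead of weak dominance.
#' @param tol Numerical tolerance for payoff comparisons.
#'
#' @return `TRUE` if some strategy in `by` dominates `s`. The dominating
#'   strategies are attached as attribute `"by"`.
#' @export
is_dominated <- function(s, table, by = NULL, strict = FALSE, tol = 1e-9) {
  stopifnot(inherits(table, "payoff_table"))
  M <- table$payoff
  if (!(s %in% rownames(M))) {
    stop("strategy '", s, "' not in table", call. = FALSE)
  }
  if (is.null(by)) by <- setdiff(rownames(M), s)
  missing <- setdiff(by, rownames(M))
  if (length(missing) > 0) {
    stop("strategies not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  row_s <- M[s, ]
  dominates <- vapply(by, function(o) {
    d <- M[o, ] - row_s
    if (strict) all(d > tol) else all(d >= -tol) && any(d > tol)
  }, logical(1))
  structure(any(dominates), by = names(dominates)[dominates])
}
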