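#' Elo tournament configuration
#'
#' The rating update is zero-sum: after each forced-choice matchup the
#' winner gains `k_factor * (1 - E_winner)` points and the loser loses the
#' same amount, where `E_winner` is the winner's expected score given the
#' pre-matchup ratings. An upset (low-rated image beating a high-rated one)
#' therefore exchanges more points than the expected outcome would.
#'
#' @param initial_score starting rating of every image (0 by convention
#'   here; only rating differences enter the update).
#' @param k_factor maximum points exchanged per matchup.
#' @param logistic_scale rating-difference scale of the expected-score
#'   logistic (chess-standard 400).
#' @param max_rounds cap on sweeps for [run_tournament()].
#' @param stability_window consecutive sweeps with an unchanged
#'   genotype-mean rank order required to declare convergence.
#' @return a list of class `"elo_config"`.
#' @export
elo_config <- function(initial_score = 0, k_factor = 32,
                       logistic_scale = 400, max_rounds = 200,
                       stability_window = 5) {
  stopifnot(k_factor > 0, logistic_scale > 0, max_rounds >= 1,
            stability_window >= 1)
  structure(list(initial_score = initial_score, k_factor = k_factor,
                 logistic_scale = logistic_scale, max_rounds = max_rounds,
                 stability_window = stability_window),
            class = "elo_config")
}

#' Expected score of a matchup
#'
#' Standard Elo logistic: `E_a = 1 / (1 + 10^((r_b - r_a) / scale))`.
#' `E_a + E_b = 1` by construction.
#'
#' @param r_a,r_b pre-matchup ratings.
#' @param scale logistic scale in rating points.
#' @return probability that the first image wins.
#' @export
expected_score <- function(r_a, r_b, scale = 400) {
  stopifnot(scale > 0)
  1 / (1 + 10^((r_b - r_a) / scale))
}

#' Initialize an Elo rating state
#'
#' @param image_ids character vector of image identifiers.
#' @param config an [elo_config()].
#' @return a list of class `"elo_state"` with `ratings` (named numeric),
#'   `history` (data.frame of applied matchups), `converged`, `rounds_run`.
#' @export
elo_init <- function(image_ids, config = elo_config()) {
  if (anyDuplicated(image_ids)) stop("duplicate image ids")
  ratings <- stats::setNames(rep(config$initial_score, length(image_ids)),
                             image_ids)
  structure(list(ratings = ratings, history = list(),
                 converged = FALSE, rounds_run = 0L),
            class = "elo_state")
}

#' Apply one forced-choice matchup to an Elo state
#'
#' @param state an `elo_state`.
#' @param record one comparison: list/row with `image_a`, `image_b`,
#'   `winner`, `rater`.
#' @param config an [elo_config()].
#' @return the updated `elo_state`; total rating is conserved.
#' @export
apply_matchup <- function(state, record, config = elo_config()) {
  a <- as.character(record$image_a); b <- as.character(record$image_b)
  win <- as.character(record$winner)
  if (!a %in% names(state$ratings) || !b %in% names(state$ratings))
    stop("unknown image id in matchup: ", paste(setdiff(c(a, b),
         names(state$ratings)), collapse = ", "))
  if (a == b) stop("self-comparison")
  if (!win %in% c(a, b)) stop("winner must be one of the two images")
  loser <- if (win == a) b else a
  e_win <- expected_score(state$ratings[[win]], state$ratings[[loser]],
                          config$logistic_scale)
  delta <- config$k_factor * (1 - e_win)
  r_win_pre <- state$ratings[[win]]
  r_lose_pre <- state$ratings[[loser]]
  state$ratings[[win]] <- r_win_pre + delta
  state$ratings[[loser]] <- r_lose_pre - delta
  state$history[[length(state$history) + 1L]] <-
    list(image_a = a, image_b = b, winner = win,
         rater = as.character(record$rater %||% NA),
         r_winner_pre = r_win_pre, r_loser_pre = r_lose_pre, delta = delta)
  state
}

#' Matchup history of an Elo state as a data.frame
#'
#' One row per applied matchup, in order, with pre-matchup ratings and the
#' points exchanged — sufficient to replay or audit the tournament.
#'
#' @param state an `elo_state`.
#' @return data.frame with columns `image_a`, `image_b`, `winner`, `rater`,
#'   `r_winner_pre`, `r_loser_pre`, `delta`.
#' @export
elo_history <- function(state) {
  if (length(state$history) == 0)
    return(data.frame(image_a = character(0), image_b = character(0),
                      winner = character(0), rater = character(0),
                      r_winner_pre = numeric(0), r_loser_pre = numeric(0),
                      delta = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(state$history, function(h)
    data.frame(h, stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replay a recorded comparison log through the Elo updates
#'
#' Deterministic: the same log always yields the same ratings.
#'
#' @param state an `elo_state` (or character vector of image ids).
#' @param records data.frame of comparisons in presentation order.
#' @param config an [elo_config()].
#' @return the final `elo_state`.
#' @export
replay_comparisons <- function(state, records, config = elo_config()) {
  if (is.character(state)) state <- elo_init(state, config)
  validate_comparisons(records)
  for (k in seq_len(nrow(records)))
    state <- apply_matchup(state, records[k, ], config)
  state
}

#' Run a randomized Elo tournament with convergence detection
#'
#' Repeated sweeps of uniformly random distinct image pairs are presented
#' to a chooser (a human-log surrogate). One sweep holds
#' `ceiling(n_images / 2)` matchups, i.e. one matchup per image on average.
#' After each sweep the rank order of genotype mean ratings is computed;
#' the tournament is converged when that order has been identical for
#' `stability_window` consecutive sweeps (the endpoint criterion: further
#' matchups do not change the relative genotype ranking). Stops at
#' `max_rounds` sweeps otherwise, with `converged = FALSE`.
#'
#' @param images data.frame with columns `image_id`, `retina_id`,
#'   `genotype`.
#' @param chooser function `(image_a, image_b) -> winner id`; see
#'   [bt_chooser()] for the latent-quality simulator.
#' @param config an [elo_config()].
#' @param seed integer seed for the pair schedule.
#' @return the final `elo_state`, with `rounds_run` and `converged` set and
#'   the genotype rank order per sweep in `$rank_history`.
#' @export
run_tournament <- function(images, chooser, config = elo_config(),
                           seed = 1) {
  stopifnot(all(c("image_id", "retina_id", "genotype") %in% names(images)))
  ids <- as.character(images$image_id)
  if (length(ids) < 2) stop("need at least 2 images")
  geno <- stats::setNames(as.character(images$genotype), ids)
  state <- elo_init(ids, config)
  set.seed(seed)
  per_sweep <- ceiling(length(ids) / 2)
  rank_history <- character(0)
  stable <- 0L
  for (round in seq_len(config$max_rounds)) {
    for (m in seq_len(per_sweep)) {
      pair <- sample(ids, 2)
      win <- chooser(pair[1], pair[2])
      state <- apply_matchup(state,
                             list(image_a = pair[1], image_b = pair[2],
                                  winner = win, rater = "sim"),
                             config)
    }
    gmeans <- tapply(state$ratings, geno[names(state$ratings)], mean)
    order_sig <- paste(names(sort(gmeans)), collapse = "<")
    rank_history <- c(rank_history, order_sig)
    stable <- if (round > 1 &&
                  order_sig == rank_history[round - 1]) stable + 1L else 1L
    state$rounds_run <- round
    if (stable >= config$stability_window) {
      state$converged <- TRUE
      break
    }
  }
  state$rank_history <- rank_history
  state
}

#' Bradley-Terry chooser over latent qualities
#'
#' Returns a chooser function for [run_tournament()] that picks winners
#' with probability `1 / (1 + exp(-(q_a - q_b) / noise_scale))`; with
#' `noise_scale = 0` the higher-latent image always wins.
#'
#' @param latent_scores named numeric vector of latent qualities.
#' @param noise_scale logistic noise scale.
#' @return function `(a, b) -> winner id`.
#' @export
bt_chooser <- function(latent_scores, noise_scale = 1) {
  function(a, b) {
    qa <- latent_scores[[a]]; qb <- latent_scores[[b]]
    p_a <- if (noise_scale == 0) {
      if (qa == qb) 0.5 else as.numeric(qa > qb)
    } else 1 / (1 + exp(-(qa - qb) / noise_scale))
    if (stats::runif(1) < p_a) a else b
  }
}

#' Per-retina mean Elo scores
#'
#' Averages final image ratings within each retina, the unit used for all
#' group statistics (1-4 images per retina).
#'
#' @param state an `elo_state`.
#' @param images data.frame with `image_id`, `retina_id`, `genotype`.
#' @return a group table: data.frame `(retina_id, genotype, metric, value)`.
#' @export
retina_scores <- function(state, images) {
  ids <- names(state$ratings)
  m <- match(ids, as.character(images$image_id))
  if (anyNA(m))
    stop("unmapped image id: ", paste(ids[is.na(m)], collapse = ", "))
  df <- data.frame(retina_id = as.character(images$retina_id)[m],
                   genotype = as.character(images$genotype)[m],
                   value = unname(state$ratings),
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(value ~ retina_id + genotype, df, mean)
  data.frame(retina_id = agg$retina_id, genotype = agg$genotype,
             metric = "elo_score", value = agg$value,
             stringsAsFactors = FALSE)
}

#' Pairwise genotype comparison of retinal mean scores
#'
#' All genotype pairs are compared by a Wilcoxon rank-sum test on the
#' per-retina values (exact distribution where sample sizes allow), and the
#' raw p-values are Benjamini-Hochberg adjusted across the pairs.
#' Genotypes with fewer than 2 retinas are excluded with a warning.
#'
#' @param table group table `(retina_id, genotype, metric, value)`.
#' @return data.frame with one row per genotype pair: `group1`, `group2`,
#'   `n1`, `n2`, `statistic` (rank-sum W), `p_raw`, `p_adjusted`.
#' @export
compare_genotypes <- function(table) {
  counts <- table(table$genotype)
  drop <- names(counts)[counts < 2]
  if (length(drop) > 0) {
    warning("excluding genotypes with < 2 retinas: ",
            paste(drop, collapse = ", "))
    table <- table[!table$genotype %in% drop, ]
  }
  groups <- sort(unique(table$genotype))
  if (length(groups) < 2) stop("need at least 2 genotypes with >= 2 retinas")
  pairs <- utils::combn(groups, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    v1 <- table$value[table$genotype == g1]
    v2 <- table$value[table$genotype == g2]
    wt <- stats::wilcox.test(v1, v2,
                             exact = (length(v1) + length(v2) <= 20) &&
                               !any(duplicated(c(v1, v2))))
    data.frame(group1 = g1, group2 = g2, n1 = length(v1), n2 = length(v2),
               statistic = unname(wt$statistic), p_raw = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out
}
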