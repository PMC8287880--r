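#' Survival fraction after a lethal stress, from a lineage forest
#'
#' Scores survival of a lethal stress in mother-machine channel lineage
#' forests, with two counting methods that guard against the two artefacts of
#' channel geometry:
#'
#' * `"top3_longest"` — only the three cells closest to the dead end of each
#'   channel at `assay_start` are scored (deep cells are not washed out). A
#'   scored cell survives when at least one lineage descending from it is
#'   still alive at `assay_end`; only that single (longest) lineage counts, so
#'   divisions cannot inflate the survivor count. The fraction is
#'   survivors / (3 x number of scored channels); channels with fewer than
#'   three cells are skipped with a warning.
#' * `"channel_end_exclusion"` — every cell present at `assay_start` is
#'   scored, but cells whose last recorded position lies within `k_sd`
#'   standard deviations of the estimated channel end are excluded as washed
#'   out. The channel end is estimated per channel from the last positions of
#'   cells that left the channel before the stress.
#'
#' @param forest A lineage forest table (see
#'   [generate_priming_lineages()]): columns `cell_id`, `channel`,
#'   `parent_id`, `birth_min`, `end_min`, `end_cause` (one of `"division"`,
#'   `"death"`, `"left_channel"`, `"movie_end"`), `rank_at_assay` (1 =
#'   closest to the dead end, `NA` if absent at `assay_start`), `last_pos`
#'   (um from the dead end).
#' @param method Counting method (see above).
#' @param assay_start Time of lethal-stress addition (min).
#' @param assay_end End of the observation window (min).
#' @param k_sd Wash-out exclusion stringency for
#'   `"channel_end_exclusion"` (default 6).
#' @return A list: `fraction`, `sd` (standard deviation of per-channel
#'   fractions), `n_scored`, `n_channels`, `per_channel` tibble.
#' @export
survival_fraction <- function(forest,
                              method = c("top3_longest",
                                         "channel_end_exclusion"),
                              assay_start, assay_end, k_sd = 6) {
  method <- match.arg(method)
  needed <- c("cell_id", "channel", "parent_id", "birth_min", "end_min",
              "end_cause", "rank_at_assay", "last_pos")
  stopifnot(is.data.frame(forest), all(needed %in% names(forest)))

  kids <- split(forest$cell_id, factor(forest$parent_id,
                                       levels = forest$cell_id))
  alive_at_end <- setNames(forest$end_min >= assay_end &
                             forest$end_cause == "movie_end",
                           forest$cell_id)
  survives <- function(id) {
    # depth-first: the cell or any descendant alive at assay_end
    stack <- as.character(id)
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (isTRUE(alive_at_end[[cur]])) return(TRUE)
      stack <- c(stack, as.character(kids[[cur]]))
    }
    FALSE
  }

  present <- forest[forest$birth_min <= assay_start &
                      forest$end_min > assay_start, ]

  if (method == "top3_longest") {
    per_channel <- present %>%
      filter(!is.na(.data$rank_at_assay)) %>%
      group_by(.data$channel) %>%
      summarise(n_cells = dplyr::n(),
                survivors = sum(vapply(
                  .data$cell_id[order(.data$rank_at_assay)][seq_len(min(3, dplyr::n()))],
                  survives, logical(1))),
                .groups = "drop")
    short <- per_channel$channel[per_channel$n_cells < 3]
    if (length(short) > 0) {
      warning(sprintf("skipping %d channel(s) with fewer than 3 cells at assay start",
                      length(short)))
      per_channel <- filter(per_channel, .data$n_cells >= 3)
    }
    if (nrow(per_channel) == 0) abort("no channel has 3 cells at assay start")
    per_channel <- mutate(per_channel, fraction = .data$survivors / 3)
    n_scored <- 3L * nrow(per_channel)
    frac <- sum(per_channel$survivors) / n_scored
  } else {
    ends <- forest %>%
      filter(.data$end_cause == "left_channel", .data$end_min < assay_start) %>%
      group_by(.data$channel) %>%
      summarise(end_mean = mean(.data$last_pos),
                end_sd = sd(.data$last_pos), .groups = "drop")
    if (nrow(ends) == 0)
      abort("no pre-stress channel exits to estimate the channel ends")
    pooled_sd <- sd(forest$last_pos[forest$end_cause == "left_channel" &
                                      forest$end_min < assay_start])
    ends$end_sd[is.na(ends$end_sd)] <- pooled_sd
    scored <- present %>%
      left_join(ends, by = "channel") %>%
      filter(!is.na(.data$end_mean),
             .data$last_pos < .data$end_mean - k_sd * .data$end_sd)
    if (nrow(scored) == 0) abort("all cells excluded as washed out")
    scored$survived <- vapply(scored$cell_id, survives, logical(1))
    per_channel <- scored %>%
      group_by(.data$channel) %>%
      summarise(n_cells = dplyr::n(), survivors = sum(.data$survived),
                fraction = mean(.data$survived), .groups = "drop")
    n_scored <- nrow(scored)
    frac <- mean(scored$survived)
  }

  list(fraction = frac,
       sd = if (nrow(per_channel) > 1) sd(per_channel$fraction) else NA_real_,
       n_scored = n_scored, n_channels = nrow(per_channel),
       per_channel = per_channel, method = method)
}
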