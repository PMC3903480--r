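# Local-global session label sequences.
#
# Blocks alternate between two types. In block type 1 the frequent (global
# standard) trials are local standards (LSGS) and the rare (global deviant)
# trials are local deviants (LDGD); block type 2 swaps the mapping (LDGS
# frequent, LSGD rare). Global deviants are placed pseudo-randomly with the
# run of global standards before the first deviant and between consecutive
# deviants constrained to [min_gap, max_gap]; the trailing run is free.

# Sample `n_dev` gap lengths in [min_gap, max_gap] whose total fits in
# `budget` standards; when `exact` the gaps must consume the budget entirely
# (the block then ends on a deviant). Random draws are nudged up/down one step
# at a time to satisfy the sum constraint, preserving pseudo-randomness while
# guaranteeing termination.
sample_gaps <- function(n_dev, budget, min_gap, max_gap, exact = FALSE) {
  if (n_dev == 0L) return(integer(0))
  lo <- n_dev * min_gap
  hi <- n_dev * max_gap
  if (lo > budget || (exact && hi < budget))
    stop("global-deviant spacing constraints are unsatisfiable for the requested counts")
  pick <- function(idx) idx[sample.int(length(idx), 1L)]
  g <- min_gap + sample.int(max_gap - min_gap + 1L, n_dev, replace = TRUE) - 1L
  while (sum(g) > budget) {
    i <- pick(which(g > min_gap))
    g[i] <- g[i] - 1L
  }
  if (exact) while (sum(g) < budget) {
    i <- pick(which(g < max_gap))
    g[i] <- g[i] + 1L
  }
  g
}

# One block's global-class sequence ("GS"/"GD"), excluding habituation.
block_global_sequence <- function(n, n_dev, min_gap, max_gap,
                                  end_with_deviant = FALSE) {
  if (n_dev > 0 && n_dev * (min_gap + 1L) > n)
    stop("global-deviant spacing constraints are unsatisfiable for the requested counts")
  if (n_dev == 0L) return(rep("GS", n))
  # unless a block is deliberately ended on a deviant, keep at least one
  # trailing standard so block endings do not drift with the random draw
  budget <- n - n_dev - if (end_with_deviant) 0L else 1L
  gaps <- sample_gaps(n_dev, budget, min_gap, max_gap,
                      exact = end_with_deviant)
  out <- character(0)
  for (g in gaps) out <- c(out, rep("GS", g), "GD")
  c(out, rep("GS", n - length(out)))
}

block_labels <- function(gseq, block_id, block_type, habituation_trials) {
  gl <- c(rep("GS", habituation_trials), gseq)
  analyzed <- c(rep(FALSE, habituation_trials), rep(TRUE, length(gseq)))
  after_dev <- c(FALSE, gl[-length(gl)] == "GD")
  analyzed[after_dev] <- FALSE
  global_class <- ifelse(gl == "GD", "deviant", "standard")
  local_class <- if (block_type == 1L)
    ifelse(gl == "GD", "deviant", "standard")
  else
    ifelse(gl == "GD", "standard", "deviant")
  trial_labels(local_class, global_class, block_id = block_id,
               block_type = block_type, analyzed = analyzed)
}

#' Generate a local-global session label sequence
#'
#' Produces per-trial labels for a session of alternating block types. Each
#' block starts with `habituation_trials` global standards flagged
#' `analyzed = FALSE`; among the remaining `trials_per_block` trials,
#' `round(p_global_deviant * trials_per_block)` are global deviants whose
#' leading and inter-deviant runs of global standards have lengths in
#' `[min_gap, max_gap]`. Every trial immediately following a global deviant is
#' flagged `analyzed = FALSE`.
#'
#' @param n_blocks number of blocks (alternating types 1, 2, 1, ...).
#' @param trials_per_block trials per block, excluding habituation.
#' @param p_global_deviant fraction of global deviants per block (0 < p < 0.5).
#' @param min_gap,max_gap minimum / maximum run of global standards before the
#'   first and between consecutive global deviants.
#' @param habituation_trials global standards opening each block,
#'   never analyzed.
#' @param seed RNG seed.
#' @return A [trial_labels()] data frame covering the whole session.
#' @export
localglobal_sequence <- function(n_blocks = 14L, trials_per_block = 68L,
                                 p_global_deviant = 0.2, min_gap = 1L,
                                 max_gap = 6L, habituation_trials = 20L,
                                 seed = 1L) {
  if (p_global_deviant <= 0 || p_global_deviant >= 0.5)
    stop("p_global_deviant must lie in (0, 0.5)")
  if (min_gap < 1L || max_gap < min_gap)
    stop("need min_gap >= 1 and max_gap >= min_gap")
  n_dev <- as.integer(round(p_global_deviant * trials_per_block))
  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      gseq <- block_global_sequence(trials_per_block, n_dev, min_gap, max_gap)
      block_labels(gseq, b, if (b %% 2L == 1L) 1L else 2L, habituation_trials)
    })
  })
  do.call(rbind, blocks)
}

#' Generate a full canonical local-global session
#'
#' A complete 14-block session whose analyzed-trial bookkeeping reproduces the
#' canonical design counts exactly: 780 analyzed trials, a local contrast of
#' 390 standards versus 390 deviants and a global contrast of 600 standards
#' versus 180 deviants. Each block holds 68 trials after a 20-trial
#' habituation run-in; per block type the seven blocks carry 13, 13, 13, 13,
#' 13, 13 and 12 global deviants (90 per type) and exactly four blocks per
#' type end on a global deviant, so that precisely 86 post-deviant trials per
#' type are excluded.
#'
#' @param seed RNG seed controlling deviant placement.
#' @param habituation_trials habituation trials per block.
#' @return A [trial_labels()] data frame for the session.
#' @export
localglobal_session <- function(seed = 1L, habituation_trials = 20L) {
  trials_per_block <- 68L
  dev_counts <- c(13L, 13L, 13L, 13L, 13L, 13L, 12L)
  with_seed(seed, {
    plan <- lapply(1:2, function(type) {
      enders <- sample.int(7L, 4L)
      list(dev = sample(dev_counts), end = seq_len(7L) %in% enders)
    })
    blocks <- vector("list", 14L)
    for (b in seq_len(14L)) {
      type <- if (b %% 2L == 1L) 1L else 2L
      within <- ceiling(b / 2L)
      gseq <- block_global_sequence(trials_per_block,
                                    plan[[type]]$dev[within], 1L, 6L,
                                    end_with_deviant = plan[[type]]$end[within])
      blocks[[b]] <- block_labels(gseq, b, type, habituation_trials)
    }
  })
  do.call(rbind, blocks)
}
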