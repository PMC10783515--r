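# Ranked-list evaluation against crosstalk truth labels.

# AUROC of a strict ranking (rank 1 = most likely positive): the fraction of
# (positive, negative) pairs ranked concordantly — the Mann-Whitney U
# normalization.
auroc_from_ranks <- function(rank, label) {
  ord <- order(rank)
  lab <- label[ord]
  n_pos <- sum(lab == 1)
  n_neg <- sum(lab == 0)
  concordant <- sum(cumsum(lab == 1)[lab == 0])
  concordant / (n_pos * n_neg)
}

# Average precision: mean of precision at each positive's rank.
auprc_from_ranks <- function(rank, label) {
  ord <- order(rank)
  lab <- label[ord]
  hits <- which(lab == 1)
  mean(cumsum(lab)[hits] / hits)
}

#' Evaluate a ranked pair list against crosstalk labels
#'
#' Deterministic mode scores only the detected labeled pairs by their given
#' ranks. Stochastic mode scores the full labeled universe: detected pairs
#' keep their ranks and undetected pairs receive random distinct ranks
#' strictly below the last detected rank, re-drawn `n_shuffles` times; the
#' ROC and PR areas are then reported as mean and standard deviation over
#' the shuffles. With no undetected pairs the stochastic areas equal the
#' deterministic ones with zero standard deviation.
#'
#' @param ranked Tibble with columns `pathway_a`, `pathway_b`, `detected`,
#'   `rank` (as produced by [infer_crosstalk()], [tidy()] of it, or the
#'   baseline rankers).
#' @param labels Tibble with columns `pathway_a`, `pathway_b`, `label`
#'   (1 = crosstalk, 0 = no crosstalk), e.g. from [gen_labels()] or
#'   [read_labels_tsv()].
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param n_shuffles Shuffles of undetected ranks in stochastic mode.
#' @param seed Seed for the shuffles.
#' @return A `mux_eval` list: `auroc`, `auprc` (single values, or means),
#'   `auroc_sd`, `auprc_sd` (stochastic mode), `mode`, `n_detected`,
#'   `n_pairs`, `n_shuffles`.
#' @export
evaluate_ranking <- function(ranked, labels,
                             mode = c("deterministic", "stochastic"),
                             n_shuffles = 1000, seed = 7L) {
  mode <- match.arg(mode)
  dat <- dplyr::inner_join(
    tibble::as_tibble(ranked)[, c("pathway_a", "pathway_b", "detected", "rank")],
    tibble::as_tibble(labels)[, c("pathway_a", "pathway_b", "label")],
    by = c("pathway_a", "pathway_b")
  )
  if (!nrow(dat)) stop("no labeled pairs in the ranking", call. = FALSE)

  if (mode == "deterministic") {
    use <- dplyr::filter(dat, .data$detected)
    if (!sum(use$label == 1) || !sum(use$label == 0)) {
      stop("need at least one positive and one negative among detected ",
           "labeled pairs", call. = FALSE)
    }
    out <- list(auroc = auroc_from_ranks(use$rank, use$label),
                auprc = auprc_from_ranks(use$rank, use$label),
                auroc_sd = 0, auprc_sd = 0, mode = mode,
                n_detected = nrow(use), n_pairs = nrow(dat), n_shuffles = 0L)
  } else {
    if (!sum(dat$label == 1) || !sum(dat$label == 0)) {
      stop("need at least one positive and one negative labeled pair",
           call. = FALSE)
    }
    n_det <- sum(dat$detected)
    base_rank <- ifelse(dat$detected, dat$rank, NA_real_)
    n_und <- sum(!dat$detected)
    draws <- withr::with_seed(seed, {
      vapply(seq_len(n_shuffles), function(s) {
        r <- base_rank
        if (n_und) r[!dat$detected] <- n_det + sample.int(n_und)
        c(auroc_from_ranks(r, dat$label), auprc_from_ranks(r, dat$label))
      }, numeric(2))
    })
    out <- list(auroc = mean(draws[1, ]), auprc = mean(draws[2, ]),
                auroc_sd = stats::sd(draws[1, ]),
                auprc_sd = stats::sd(draws[2, ]),
                mode = mode, n_detected = n_det, n_pairs = nrow(dat),
                n_shuffles = as.integer(n_shuffles))
  }
  structure(out, class = "mux_eval")
}

#' @export
print.mux_eval <- function(x, ...) {
  cat("<mux_eval> mode = ", x$mode, ", ", x$n_detected, "/", x$n_pairs,
      " pairs detected\n", sep = "")
  cat(sprintf("  AUROC = %.4f (sd %.4f)\n  AUPRC = %.4f (sd %.4f)\n",
              x$auroc, x$auroc_sd, x$auprc, x$auprc_sd))
  invisible(x)
}

#' @rdname evaluate_ranking
#' @param x A `mux_eval`.
#' @param ... Unused.
#' @export
glance.mux_eval <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, auroc_sd = x$auroc_sd, auprc = x$auprc,
                 auprc_sd = x$auprc_sd, mode = x$mode,
                 n_detected = x$n_detected, n_pairs = x$n_pairs,
                 n_shuffles = x$n_shuffles)
}

#' Precision among the top-ranked pairs
#'
#' @param ranked Ranked tibble (columns `rank`, `pathway_a`, `pathway_b`).
#' @param positives Tibble of positive pairs (`pathway_a`, `pathway_b`).
#' @param top_k Depth of the precision-rank curve; at most the number of
#'   ranked (detected) pairs.
#' @return Tibble with columns `k` and `precision` (precision among the top
#'   `k` pairs, for `k = 1..top_k`).
#' @export
precision_at_rank <- function(ranked, positives, top_k) {
  det <- dplyr::arrange(dplyr::filter(tibble::as_tibble(ranked),
                                      !is.na(.data$rank)), .data$rank)
  if (top_k > nrow(det)) {
    stop("top_k exceeds the number of ranked pairs", call. = FALSE)
  }
  pos_id <- paste(positives$pathway_a, positives$pathway_b, sep = "\r")
  hit <- paste(det$pathway_a, det$pathway_b, sep = "\r") %in% pos_id
  tibble::tibble(k = seq_len(top_k),
                 precision = cumsum(hit[seq_len(top_k)]) / seq_len(top_k))
}

#' Read / write benchmark labels as TSV
#'
#' Columns: `pathway_a`, `pathway_b`, `label` (1 = crosstalk, 0 = none).
#'
#' @param path TSV path.
#' @export
read_labels_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    pathway_a = readr::col_character(), pathway_b = readr::col_character(),
    label = readr::col_integer()
  ))
}

#' @rdname read_labels_tsv
#' @param labels Labels tibble.
#' @export
write_labels_tsv <- function(labels, path) {
  readr::write_tsv(labels, path)
  invisible(path)
}
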