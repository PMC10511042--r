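# Benchmark utilities: score detections, links and pair correlations
# against the generator's ground truth.

#' Detection precision and recall against ground truth
#'
#' Detections and true positions are matched greedily by ascending
#' distance, one-to-one, within `radius`.
#'
#' @param detections data frame `frame, z, y, x`.
#' @param truth_positions data frame `frame, id, z, y, x`.
#' @param radius matching radius in px.
#' @return list `precision`, `recall`, `n_tp`, `n_fp`, `n_fn`.
#' @export
detection_scores <- function(detections, truth_positions, radius = 2.5) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (f in sort(unique(c(detections$frame, truth_positions$frame)))) {
    D <- as.matrix(detections[detections$frame == f, c("z", "y", "x")])
    Tr <- as.matrix(truth_positions[truth_positions$frame == f,
                                    c("z", "y", "x")])
    if (nrow(Tr) == 0) { fp <- fp + nrow(D); next }
    if (nrow(D) == 0) { fn <- fn + nrow(Tr); next }
    m <- greedy_match(Tr, D, radius)
    tp <- tp + sum(!is.na(m))
    fn <- fn + sum(is.na(m))
    fp <- fp + nrow(D) - sum(!is.na(m))
  }
  list(precision = tp / (tp + fp), recall = tp / (tp + fn),
       n_tp = tp, n_fp = fp, n_fn = fn)
}

# Nearest ground-truth identity for each trajectory point.
truth_id_map <- function(trajectories, truth_positions) {
  out <- rep(NA_integer_, nrow(trajectories))
  for (f in unique(trajectories$frame)) {
    sel <- trajectories$frame == f
    Tr <- truth_positions[truth_positions$frame == f, , drop = FALSE]
    if (nrow(Tr) == 0) next
    A <- as.matrix(trajectories[sel, c("z", "y", "x")])
    B <- as.matrix(Tr[, c("z", "y", "x")])
    D2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
    out[sel] <- Tr$id[apply(D2, 1, which.min)]
  }
  out
}

#' Link identity accuracy against ground truth
#'
#' Fraction of consecutive-frame links in the measured trajectories whose
#' two endpoints map (by proximity) to the same ground-truth identity.
#'
#' @param trajectories data frame `track_id, frame, z, y, x`.
#' @inheritParams detection_scores
#' @return fraction in \[0, 1\].
#' @export
link_accuracy <- function(trajectories, truth_positions) {
  trajectories$true_id <- truth_id_map(trajectories, truth_positions)
  good <- 0L; total <- 0L
  for (tr in split(trajectories, trajectories$track_id)) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) next
    consec <- diff(tr$frame) == 1
    total <- total + sum(consec)
    good <- good + sum(consec & diff(tr$true_id) == 0)
  }
  if (total == 0) return(NA_real_)
  good / total
}

#' Pair-correlation recovery error of the full pipeline
#'
#' For every row of a measured pair-correlation table, recomputes the
#' ground-truth r of the corresponding true cell pair (mapping measured
#' track ids to true identities by proximity) and returns the mean
#' absolute error.
#'
#' @param table measured pair correlation table from
#'   [pair_correlations()].
#' @param trajectories measured trajectories behind `table`.
#' @inheritParams detection_scores
#' @return list `mae`, `n` (rows compared).
#' @export
pair_r_recovery <- function(table, trajectories, truth_positions) {
  trajectories$true_id <- truth_id_map(trajectories, truth_positions)
  errs <- numeric(0)
  for (f in unique(table$frame)) {
    rows <- table[table$frame == f, , drop = FALSE]
    cur <- truth_positions[truth_positions$frame == f, , drop = FALSE]
    prev <- truth_positions[truth_positions$frame == f - 1, , drop = FALSE]
    tsel <- trajectories[trajectories$frame == f, , drop = FALSE]
    idmap <- tsel$true_id[match(c(rows$id_a, rows$id_b), tsel$track_id)]
    ta <- idmap[seq_len(nrow(rows))]
    tb <- idmap[nrow(rows) + seq_len(nrow(rows))]
    for (i in seq_len(nrow(rows))) {
      if (is.na(ta[i]) || is.na(tb[i]) || ta[i] == tb[i]) next
      va <- as.numeric(cur[cur$id == ta[i], c("z", "y", "x")]) -
        as.numeric(prev[prev$id == ta[i], c("z", "y", "x")])
      vb <- as.numeric(cur[cur$id == tb[i], c("z", "y", "x")]) -
        as.numeric(prev[prev$id == tb[i], c("z", "y", "x")])
      if (length(va) != 3 || length(vb) != 3) next
      rt <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
      errs <- c(errs, abs(rows$r[i] - rt))
    }
  }
  list(mae = mean(errs), n = length(errs))
}
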