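# Shared fixture builders: all synthetic, generated at test time.

disc_mask <- function(r, size = 2L * ceiling(r) + 21L,
                      cy = (size + 1) / 2, cx = (size + 1) / 2) {
  Y <- outer(seq_len(size), rep(1, size))
  X <- outer(rep(1, size), seq_len(size))
  (Y - cy)^2 + (X - cx)^2 <= r^2
}

# Independent brute-force max Feret: all pairs of pixel corners.
feret_bruteforce <- function(mask) {
  coords <- which(mask > 0, arr.ind = TRUE)
  corners <- rbind(
    cbind(coords[, 1] - 0.5, coords[, 2] - 0.5),
    cbind(coords[, 1] - 0.5, coords[, 2] + 0.5),
    cbind(coords[, 1] + 0.5, coords[, 2] - 0.5),
    cbind(coords[, 1] + 0.5, coords[, 2] + 0.5)
  )
  max(stats::dist(corners))
}

# Match each detection to the nearest ground-truth position; returns
# per-frame precision/recall at the given radius and the id map.
match_detections <- function(det, truth_pos, radius) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (f in unique(det$frame)) {
    D <- det[det$frame == f, c("z", "y", "x")]
    Tr <- truth_pos[truth_pos$frame == f, c("z", "y", "x")]
    if (nrow(Tr) == 0) { fp <- fp + nrow(D); next }
    if (nrow(D) == 0) { fn <- fn + nrow(Tr); next }
    M <- as.matrix(stats::dist(rbind(as.matrix(Tr), as.matrix(D))))
    M <- M[seq_len(nrow(Tr)), nrow(Tr) + seq_len(nrow(D)), drop = FALSE]
    used_d <- logical(nrow(D)); matched_t <- logical(nrow(Tr))
    ord <- order(M)
    for (k in ord) {
      if (M[k] > radius) break
      i <- ((k - 1) %% nrow(Tr)) + 1
      j <- ((k - 1) %/% nrow(Tr)) + 1
      if (!matched_t[i] && !used_d[j]) {
        matched_t[i] <- TRUE; used_d[j] <- TRUE; tp <- tp + 1L
      }
    }
    fp <- fp + sum(!used_d); fn <- fn + sum(!matched_t)
  }
  list(precision = tp / (tp + fp), recall = tp / (tp + fn))
}

# Fraction of frame-to-frame links in measured trajectories that join
# detections belonging to the same ground-truth identity (nearest truth
# position per detection defines its identity).
link_identity_accuracy <- function(traj, truth_pos) {
  ids <- integer(nrow(traj))
  for (f in unique(traj$frame)) {
    sel <- traj$frame == f
    Tr <- truth_pos[truth_pos$frame == f, ]
    M <- as.matrix(stats::dist(rbind(as.matrix(Tr[, c("z", "y", "x")]),
                                     as.matrix(traj[sel, c("z", "y", "x")]))))
    M <- M[seq_len(nrow(Tr)), nrow(Tr) + seq_len(sum(sel)), drop = FALSE]
    ids[sel] <- Tr$id[apply(M, 2, which.min)]
  }
  traj$true_id <- ids
  good <- 0L; total <- 0L
  for (tr in split(traj, traj$track_id)) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) next
    consec <- diff(tr$frame) == 1
    total <- total + sum(consec)
    good <- good + sum(consec & diff(tr$true_id) == 0)
  }
  if (total == 0) return(NA_real_)
  good / total
}
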