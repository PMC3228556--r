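# Independent oracle for the local pair-HMM alignment: enumerates every
# legal local path and returns the best total score. Under the
# five-state model, gap runs are homogeneous (a gap state can only be
# entered from MM and left into MM), so every legal path is a chain of
# MM cells where consecutive cells differ by (1,1) (direct diagonal),
# (di, 1) with di >= 2 (a run of MI or DG advancing only the first
# profile) or (1, dj) with dj >= 2 (a run of IM or GD). The oracle
# enumerates all such chains from every start cell and scores each
# transition in closed form from the recurrence definitions.

oracle_logs <- function(profile) {
  lg <- function(x) ifelse(x > 0, pmax(log2(x), -50), -50)
  apply(profile$trans, 2, lg)
}

oracle_best_score <- function(P, Q, params) {
  n <- P$length; m <- Q$length
  M <- column_score_matrix(P, Q, params)
  lp <- oracle_logs(P); lq <- oracle_logs(Q)
  Wg <- params$Wg
  best <- 0

  extend <- function(i, j, s) {
    if (s > best) best <<- s
    if (i < n && j < m) {
      # direct diagonal MM -> MM
      extend(i + 1, j + 1,
             s + Wg * (lp[i, "MM"] + lq[j, "MM"]) + M[i + 1, j + 1])
      # runs advancing only P: land at (i2, j+1), i2 >= i+2
      if (i + 2 <= n) for (i2 in (i + 2):n) {
        mid <- if (i2 > i + 2) (i + 1):(i2 - 2) else integer(0)
        mi <- Wg * (lp[i, "MM"] + lq[j, "MI"]) +
          Wg * sum(lp[mid, "MM"] + lq[j, "II"]) +
          Wg * (lp[i2 - 1, "MM"] + lq[j, "IM"])
        dg <- Wg * lp[i, "MD"] +
          Wg * sum(lp[mid, "DD"]) +
          Wg * (lp[i2 - 1, "DM"] + lq[j, "MM"])
        extend(i2, j + 1, s + mi + M[i2, j + 1])
        extend(i2, j + 1, s + dg + M[i2, j + 1])
      }
      # runs advancing only Q: land at (i+1, j2), j2 >= j+2
      if (j + 2 <= m) for (j2 in (j + 2):m) {
        mid <- if (j2 > j + 2) (j + 1):(j2 - 2) else integer(0)
        im <- Wg * (lq[j, "MM"] + lp[i, "MI"]) +
          Wg * sum(lq[mid, "MM"] + lp[i, "II"]) +
          Wg * (lp[i, "IM"] + lq[j2 - 1, "MM"])
        gd <- Wg * lq[j, "MD"] +
          Wg * sum(lq[mid, "DD"]) +
          Wg * (lp[i, "MM"] + lq[j2 - 1, "DM"])
        extend(i + 1, j2, s + im + M[i + 1, j2])
        extend(i + 1, j2, s + gd + M[i + 1, j2])
      }
    }
  }

  for (i in 1:n) for (j in 1:m) extend(i, j, M[i, j])
  max(best, 0)
}
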