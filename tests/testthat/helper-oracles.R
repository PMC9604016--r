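# Independent brute-force oracles. These recompute every mean and standard
# deviation from scratch with explicit loops, sharing no code with the
# package's vectorized implementations.

oracle_pop_sd <- function(x) {
  x <- x[!is.na(x)]
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

# quotient normalization + 3-sigma selection, cell by cell
oracle_method1 <- function(S) {
  nr <- nrow(S); nc <- ncol(S)
  V <- matrix(NA_real_, nr, nc, dimnames = dimnames(S))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(S[i, j])) next
      ML <- mean(S[i, ][!is.na(S[i, ])])
      MT <- mean(S[, j][!is.na(S[, j])])
      V[i, j] <- S[i, j] / ((ML + MT) / 2)
    }
  }
  M <- mean(V[!is.na(V)])
  sigma <- oracle_pop_sd(V)
  sel <- which(!is.na(V) & V >= M + 3 * sigma, arr.ind = TRUE)
  list(V = V, M = M, sigma = sigma,
       pairs = sort(paste(colnames(S)[sel[, 2]], rownames(S)[sel[, 1]])))
}

# two-directional Z-transformation, cell by cell
oracle_zcomb <- function(S, wT = 0.7, wL = 0.3) {
  nr <- nrow(S); nc <- ncol(S)
  ZT <- ZL <- matrix(NA_real_, nr, nc, dimnames = dimnames(S))
  for (i in seq_len(nr)) {
    row <- S[i, ][!is.na(S[i, ])]
    mu <- mean(row); sdev <- oracle_pop_sd(row)
    for (j in seq_len(nc)) {
      if (is.na(S[i, j])) next
      ZT[i, j] <- if (sdev == 0) 0 else (S[i, j] - mu) / sdev
    }
  }
  for (j in seq_len(nc)) {
    col <- S[, j][!is.na(S[, j])]
    mu <- mean(col); sdev <- oracle_pop_sd(col)
    for (i in seq_len(nr)) {
      if (is.na(S[i, j])) next
      ZL[i, j] <- if (sdev == 0) 0 else (S[i, j] - mu) / sdev
    }
  }
  list(ZT = ZT, ZL = ZL, Zcomb = wT * ZT + wL * ZL)
}

# shared-ligand counts between all target pairs, by set enumeration
oracle_projection <- function(assoc) {
  targets <- sort(unique(assoc$target_id))
  out <- data.frame(a = character(), b = character(), w = integer(),
                    stringsAsFactors = FALSE)
  for (i in seq_along(targets)) {
    for (j in seq_along(targets)) {
      if (j <= i) next
      shared <- length(intersect(
        assoc$ligand_id[assoc$target_id == targets[i]],
        assoc$ligand_id[assoc$target_id == targets[j]]))
      if (shared > 0)
        out <- rbind(out, data.frame(a = targets[i], b = targets[j],
                                     w = shared, stringsAsFactors = FALSE))
    }
  }
  out
}

# random negative matrix with unique dimnames
random_score_matrix <- function(nr, nc, seed, missing = 0) {
  set.seed(seed)
  s <- matrix(rnorm(nr * nc, -8, 1.5), nr, nc,
              dimnames = list(sprintf("L%02d", seq_len(nr)),
                              sprintf("T%02d", seq_len(nc))))
  s[s >= 0] <- -0.1
  if (missing > 0) s[sample(length(s), missing)] <- NA_real_
  s
}

pair_keys <- function(p) sort(paste(p$target_id, p$ligand_id))
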