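# Independent oracles used by the unit and acceptance suites. These stay
# deliberately separate from the package's own code paths.

## quaternion (Horn) closed-form superposition RMSD
horn_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- crossprod(Pc, Qc)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],       S[3,1]-S[1,3],       S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],       S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

## brute-force GDT oracle: superpositions seeded from every size-3 subset
## (plus the global fit), each refined by iterative extension
gdt_oracle <- function(P, Q, cutoffs = c(0.5, 1, 2, 4)) {
  n <- nrow(P)
  subsets <- combn(n, 3, simplify = FALSE)
  per_cutoff <- vapply(cutoffs, function(cc) {
    best <- 0
    for (sub in c(subsets, list(seq_len(n)))) {
      s <- sub
      for (it in 1:6) {
        fit <- hddr:::kabsch(P[s, , drop = FALSE], Q[s, , drop = FALSE])
        if (is.null(fit)) break
        Pf <- sweep(P %*% fit$R, 2, fit$t, `+`)
        hit <- which(sqrt(rowSums((Pf - Q)^2)) <= cc)
        best <- max(best, length(hit) / n)
        if (identical(hit, s) || length(hit) < 3) break
        s <- hit
      }
    }
    best
  }, numeric(1))
  mean(per_cutoff)
}

## direct-enumeration lDDT oracle
lddt_oracle <- function(model, native, thresholds = c(0.5, 1, 2, 4),
                        radius = 15) {
  P <- coords(model); Q <- coords(native)
  res <- native$atoms$res_index
  acc <- numeric(0)
  for (th in thresholds) {
    num <- 0; den <- 0
    for (i in 1:(nrow(Q) - 1)) for (j in (i + 1):nrow(Q)) {
      if (res[i] == res[j]) next
      dn <- sqrt(sum((Q[i, ] - Q[j, ])^2))
      if (dn >= radius) next
      dm <- sqrt(sum((P[i, ] - P[j, ])^2))
      den <- den + 1
      if (abs(dm - dn) < th) num <- num + 1
    }
    acc <- c(acc, num / den)
  }
  mean(acc)
}
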