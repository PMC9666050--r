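# independent brute-force KNN oracle: plain per-query loop with the same
# stated rules (Euclidean distance, majority vote, ties by smallest summed
# distance then class order)
oracle_knn <- function(Xtr, ytr, Q, k, classes) {
  apply(Q, 1, function(q) {
    d <- sqrt(colSums((t(Xtr) - q)^2))
    ord <- order(d, seq_along(d))[seq_len(k)]
    votes <- table(factor(ytr[ord], levels = classes))
    best <- names(votes)[votes == max(votes)]
    if (length(best) > 1) {
      sums <- sapply(best, function(cl) sum(d[ord][ytr[ord] == cl]))
      best <- best[sums == min(sums)]
    }
    best[1]
  })
}
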