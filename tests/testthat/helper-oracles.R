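## brute-force O(n^2) silhouette, the independent oracle for avgSilhouette
bruteSilhouette <- function(E, labels) {
  labels <- factor(labels)
  n <- nrow(E)
  s <- numeric(n)
  for (i in 1:n) {
    di <- sqrt(colSums((t(E) - E[i, ])^2))
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(di[own & seq_len(n) != i])
    b <- min(vapply(setdiff(levels(labels), as.character(labels[i])),
                    function(g) mean(di[labels == g]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}
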