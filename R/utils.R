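utils::globalVariables(c("LD1", "LD2", "group", "specimen", "q", "cluster"))

# Dirichlet draw (one vector)
.rdirichlet <- function(alpha) {
  x <- rgamma(length(alpha), alpha)
  s <- sum(x)
  if (s == 0) { x[which.max(alpha)] <- 1; s <- 1 }
  x / s
}

# largest-remainder rounding of n*p to integers summing to n,
# with optional minimum count per class
.quota_round <- function(p, n, min_count = 0L) {
  k <- length(p)
  tgt <- p / sum(p) * n
  cnt <- floor(tgt)
  cnt <- pmax(cnt, min_count)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(tgt - floor(tgt), decreasing = TRUE)
    i <- 0L
    while (rem > 0) {
      cnt[ord[i %% k + 1L]] <- cnt[ord[i %% k + 1L]] + 1L
      rem <- rem - 1L; i <- i + 1L
    }
  } else if (rem < 0) {
    while (rem < 0) {
      j <- which(cnt > min_count)
      j <- j[which.max(cnt[j] - tgt[j])]
      cnt[j] <- cnt[j] - 1L
      rem <- rem + 1L
    }
  }
  as.integer(cnt)
}
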