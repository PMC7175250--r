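# Brute-force oracles, deliberately written as explicit loops with no code
# shared with the package implementation.

oracle_moments <- function(mask) {
  n <- 0; sr <- 0; sc_ <- 0
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    if (mask[r, c]) { n <- n + 1; sr <- sr + r; sc_ <- sc_ + c }
  mr <- sr / n; mc <- sc_ / n
  m20 <- 0; m02 <- 0; m11 <- 0
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    if (mask[r, c]) {
      m20 <- m20 + (r - mr)^2
      m02 <- m02 + (c - mc)^2
      m11 <- m11 + (r - mr) * (c - mc)
    }
  m20 <- m20 / n; m02 <- m02 / n; m11 <- m11 / n
  tr <- m20 + m02
  det <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (tr + det) / 2
  l2 <- max((tr - det) / 2, 0)
  list(major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
       ecc = if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0)
}

# per-class precision/recall/F1 by counting pairs one at a time
oracle_metrics <- function(pred, truth, classes = 0:3) {
  out <- list()
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(pred)) {
      if (pred[i] == cl && truth[i] == cl) tp <- tp + 1
      if (pred[i] == cl && truth[i] != cl) fp <- fp + 1
      if (pred[i] != cl && truth[i] == cl) fn <- fn + 1
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    out[[as.character(cl)]] <- c(precision = p, recall = r, f1 = f)
  }
  acc <- 0
  for (i in seq_along(pred)) if (pred[i] == truth[i]) acc <- acc + 1
  list(per_class = out, accuracy = acc / length(pred))
}
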