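# Shared fixture builders. Everything is generated in code at test time.

# Single-regulator toy: a target driven by one sinusoidal factor through
# known parameters (alpha, beta, w), noise free.
toy_single_reg <- function(T = 40, alpha = 1.5, beta = 0.2, w = 0.8) {
  reg <- sin_factor(T, 1, 17, 0.4)
  tgt <- numeric(T)
  tgt[1] <- 0.2
  for (t in seq_len(T - 1))
    tgt[t + 1] <- tgt[t] + alpha * tanh(w * reg[t] - beta)
  expr_ts(rbind(tg = tgt, rg = reg), factors = "rg")
}

# Three-gene noise-free toy with known structure: g1 <- F, g2 <- g1,
# g3 <- g1 + g2 (self-links off). Used for GA-vs-exhaustive checks.
toy_three_gene <- function(T = 40) {
  Fs <- sin_factor(T, 1, 11, 0.3)
  g <- matrix(0, 3, T, dimnames = list(c("g1", "g2", "g3"), NULL))
  g[, 1] <- c(0.2, -0.1, 0.1)
  al <- c(0.9, 0.8, 0.9)
  for (t in seq_len(T - 1)) {
    g[1, t + 1] <- g[1, t] + al[1] * tanh(1.4 * Fs[t] - 0.6 * g[1, t])
    g[2, t + 1] <- g[2, t] + al[2] * tanh(1.3 * g[1, t] - 0.6 * g[2, t])
    g[3, t + 1] <- g[3, t] + al[3] * tanh(1.2 * g[1, t] - 1.1 * g[2, t] -
                                            0.6 * g[3, t])
  }
  expr_ts(rbind(g, F1 = Fs), factors = "F1")
}

# Tiny random truth + prediction pair for metric property tests.
random_truth_and_pred <- function(n = 5, K = 1, seed = 1) {
  set.seed(seed)
  net <- random_grn(n, K, n_links = sample(3:(2 * n), 1), l_max = 3)
  nodes <- c(net$genes, net$factors)
  cand <- expand.grid(regulator = nodes, target = net$genes,
                      stringsAsFactors = FALSE)
  pick <- sample(nrow(cand), sample(0:(2 * n), 1))
  pred <- cand[pick, , drop = FALSE]
  pred$weight <- rnorm(nrow(pred))
  list(net = net, pred = pred)
}
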