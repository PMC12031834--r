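# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately share no code with
# the package: naive loops and direct formula transcriptions only.

# --- transfer entropy: explicit triple-histogram counting ----------------
oracle_pte <- function(phase_x, phase_y, delay, n_bins) {
  brk <- seq(-pi, pi, length.out = n_bins + 1)
  to_bin <- function(p) {
    b <- integer(length(p))
    for (i in seq_along(p)) {
      for (k in seq_len(n_bins)) {
        if (p[i] <= brk[k + 1] + 1e-12) { b[i] <- k; break }
      }
      if (b[i] == 0) b[i] <- n_bins
    }
    b
  }
  n <- length(phase_x)
  xs <- to_bin(phase_x); ys <- to_bin(phase_y)
  m <- n - delay
  counts3 <- array(0, c(n_bins, n_bins, n_bins))  # [yd, y, x]
  for (t in seq_len(m))
    counts3[ys[t + delay], ys[t], xs[t]] <-
      counts3[ys[t + delay], ys[t], xs[t]] + 1
  p3 <- counts3 / m
  te <- 0
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins))
    for (k in seq_len(n_bins)) {
      pj <- p3[i, j, k]
      if (pj > 0) {
        p_y <- sum(p3[, j, ])
        p_yx <- sum(p3[, j, k])
        p_ydy <- sum(p3[i, j, ])
        te <- te + pj * log(pj * p_y / (p_yx * p_ydy))
      }
    }
  te
}

# --- weighted digraph metrics by exhaustive path enumeration -------------
# all simple paths between two nodes of a small digraph
oracle_all_paths <- function(W, from, to) {
  n <- nrow(W)
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to && length(path) > 1) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (nxt in seq_len(n)) {
      if (W[last, nxt] > 0 && !(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(from)
  paths
}

oracle_graph_metrics <- function(W) {
  n <- nrow(W)
  len <- function(path) {
    s <- 0
    for (k in seq_len(length(path) - 1)) s <- s + 1 / W[path[k], path[k + 1]]
    s
  }
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  shortest <- vector("list", n * n)
  betw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) if (s != t) {
    paths <- oracle_all_paths(W, s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, len, numeric(1))
    d <- min(lens)
    dist[s, t] <- d
    sp <- paths[abs(lens - d) < 1e-9]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      on_sp <- vapply(sp, function(p) v %in% p, logical(1))
      betw[v] <- betw[v] + sum(on_sp) / length(sp)
    }
  }
  ecc <- apply(dist, 1, max)
  # eigenvector centrality by plain power iteration on t(W)
  v <- rep(1, n)
  for (it in 1:2000) {
    v2 <- as.numeric(t(W) %*% v)
    if (max(abs(v2)) == 0) { v <- v2; break }
    v2 <- v2 / max(abs(v2))
    if (max(abs(v2 - v)) < 1e-13) { v <- v2; break }
    v <- v2
  }
  ev <- abs(v)
  if (max(ev) > 0) ev <- ev / max(ev)
  list(in_degree = colSums(W), out_degree = rowSums(W),
       betweenness = betw, eigenvector = ev,
       eccentricity = ecc, diameter = max(dist))
}

# --- Cox partial likelihood (Breslow; for tie-free event times) ----------
oracle_cox_loglik <- function(beta, start, stop, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- start < stop[i] & stop >= stop[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

oracle_cox_coef <- function(start, stop, event, x) {
  stats::optimize(function(b) -oracle_cox_loglik(b, start, stop, event, x),
                  interval = c(-5, 5))$minimum
}

# --- Higuchi curve-length sums, transcribed independently ----------------
oracle_higuchi <- function(x, kmax) {
  n <- length(x)
  logL <- numeric(kmax)
  for (k in 1:kmax) {
    Ls <- c()
    for (m in 1:k) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) next
      ng <- length(idx) - 1
      L <- sum(abs(diff(x[idx]))) * (n - 1) / (ng * k) / k
      Ls <- c(Ls, L)
    }
    logL[k] <- log(mean(Ls))
  }
  fit <- stats::lm(logL ~ log(1:kmax))
  -unname(stats::coef(fit)[2])
}

# quick helper: a simple two-channel lag-coupled pair of series
coupled_pair <- function(n, lag, gain = 1, noise = 0.3, ar = 0.9) {
  x <- as.numeric(stats::arima.sim(list(ar = ar), n))
  y <- c(stats::rnorm(lag), gain * x[seq_len(n - lag)]) +
    stats::rnorm(n, sd = noise)
  list(x = x, y = y)
}
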