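#' Instantaneous phase of a broadband channel
#'
#' Phase of the analytic signal (Hilbert transform via the FFT) of one
#' channel of a filtered epoch. Connectivity is computed on the broadband
#' (0.5-40 Hz) signal, avoiding biases from band selection.
#'
#' @param x Numeric vector, one channel of an assembled epoch.
#' @return Phase series in `(-pi, pi]`, same length as `x`.
#' @export
instantaneous_phase <- function(x) {
  if (any(!is.finite(x))) stop("channel contains non-finite samples")
  if (diff(range(x)) == 0)
    stop("constant signal has no defined instantaneous phase")
  n <- length(x)
  X <- stats::fft(x)
  mult <- numeric(n)
  if (n %% 2 == 0) {
    mult[1] <- 1; mult[n / 2 + 1] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[1] <- 1
    mult[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(X * mult, inverse = TRUE) / n
  Arg(analytic)
}

# heuristic delay: samples per phase sign change, pooled over the given
# phase series (more sign changes = faster phase dynamics = shorter delay)
.pte_default_delay <- function(phases) {
  total_n <- sum(vapply(phases, length, integer(1)))
  changes <- sum(vapply(phases, function(p)
    sum(p[-length(p)] * p[-1] < 0), numeric(1)))
  max(1L, as.integer(round(total_n / max(changes, 1))))
}

# heuristic bin count for the phase histograms
.pte_default_bins <- function(n_eff) {
  max(2L, as.integer(round(exp(0.626 + 0.4 * log(n_eff)))))
}

#' Phase transfer entropy between two phase series
#'
#' Transfer entropy on binned instantaneous phases, quantifying the
#' directed influence of `phase_x` on `phase_y`:
#' \deqn{PTE_{x \to y} = \sum p(y_{t+\delta}, y_t, x_t)
#'   \log\frac{p(y_{t+\delta} \mid y_t, x_t)}{p(y_{t+\delta} \mid y_t)}}
#' estimated from a triple histogram over the whole epoch. Non-negative up
#' to estimator precision.
#'
#' @param phase_x,phase_y Equal-length phase series in `(-pi, pi]`, as from
#'   [instantaneous_phase()].
#' @param delay Prediction delay in samples; defaults to the pooled
#'   samples-per-phase-sign-change heuristic of the pair.
#' @param n_bins Number of phase bins; defaults to
#'   `round(exp(0.626 + 0.4 log(N - delay - 1)))`.
#' @return PTE from x to y, in nats.
#' @export
pte <- function(phase_x, phase_y, delay = NULL, n_bins = NULL) {
  if (length(phase_x) != length(phase_y))
    stop("phase series must have equal length")
  if (is.null(delay)) delay <- .pte_default_delay(list(phase_x, phase_y))
  n <- length(phase_x)
  if (n <= delay + 1)
    stop("phase series too short for delay = ", delay)
  if (is.null(n_bins)) n_bins <- .pte_default_bins(n - delay - 1)
  if (n_bins < 2) stop("n_bins must be at least 2")
  brk <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- function(p) pmax(1L, pmin(n_bins, findInterval(p, brk,
                                                        left.open = TRUE,
                                                        all.inside = TRUE)))
  t_idx <- seq_len(n - delay)
  x <- bin(phase_x)[t_idx]
  y <- bin(phase_y)[t_idx]
  yd <- bin(phase_y)[t_idx + delay]
  m <- length(t_idx)
  # joint counts via a single 3-digit base-n_bins index
  code <- (yd - 1L) + n_bins * ((y - 1L) + n_bins * (x - 1L))
  p_xyz <- tabulate(code + 1L, nbins = n_bins^3) / m
  dim(p_xyz) <- c(n_bins, n_bins, n_bins)   # [yd, y, x]
  p_y   <- apply(p_xyz, 2, sum)             # p(y_t)
  p_ydy <- apply(p_xyz, c(1, 2), sum)       # p(y_{t+d}, y_t)
  p_yx  <- apply(p_xyz, c(2, 3), sum)       # p(y_t, x_t)
  te <- 0
  nz <- which(p_xyz > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1]; j <- nz[r, 2]; k <- nz[r, 3]
    te <- te + p_xyz[i, j, k] *
      log(p_xyz[i, j, k] * p_y[j] / (p_yx[j, k] * p_ydy[i, j]))
  }
  te
}

#' Phase transfer entropy matrix of an epoch
#'
#' Computes [pte()] for every ordered channel pair of an assembled epoch
#' (or a channels x samples matrix), using one common delay derived from
#' the phase dynamics of all channels. PTE is estimated over the full epoch
#' rather than per 2 s window: a triple phase histogram needs more samples
#' than a single window provides.
#'
#' @param epoch An `eeg_epoch` or a channels x samples numeric matrix.
#' @param delay,n_bins Passed to [pte()]; `NULL` for the defaults.
#' @return A `pte_matrix`: channels x channels non-negative matrix with zero
#'   diagonal, entry `(i, j)` being PTE from channel i to channel j, with
#'   `delay` and `n_bins` attributes.
#' @export
pte_matrix <- function(epoch, delay = NULL, n_bins = NULL) {
  sig <- if (inherits(epoch, "eeg_epoch")) epoch$signal else epoch
  stopifnot(is.matrix(sig))
  nc <- nrow(sig)
  if (nc < 2) stop("connectivity needs at least 2 channels")
  phases <- lapply(seq_len(nc), function(ch) instantaneous_phase(sig[ch, ]))
  if (is.null(delay)) delay <- .pte_default_delay(phases)
  if (is.null(n_bins)) n_bins <- .pte_default_bins(ncol(sig) - delay - 1)
  m <- matrix(0, nc, nc)
  labels <- if (inherits(epoch, "eeg_epoch")) epoch$channel_labels
            else rownames(sig)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  for (i in seq_len(nc)) for (j in seq_len(nc)) if (i != j)
    m[i, j] <- pte(phases[[i]], phases[[j]], delay = delay, n_bins = n_bins)
  structure(m, class = c("pte_matrix", "matrix"),
            delay = delay, n_bins = n_bins)
}

#' Directed-graph measures from a PTE matrix
#'
#' Treats the PTE matrix as a weighted directed graph (edge weight = PTE,
#' zero-weight edges absent) and computes, per channel, the weighted in- and
#' out-degree, betweenness centrality, eigenvector centrality (on the weight
#' matrix, normalized to unit maximum) and eccentricity, plus the global
#' diameter. Path-based measures use edge length `1/weight`, so stronger
#' coupling means shorter distance. On graphs that are not strongly
#' connected, eccentricities and the diameter are `Inf` (flagged, not an
#' error).
#'
#' @param ptem A `pte_matrix` or any non-negative square matrix with zero
#'   diagonal.
#' @return List with `per_channel` (data frame: channel, in_degree,
#'   out_degree, betweenness, eigenvector, eccentricity), `diameter`, and
#'   `strongly_connected`.
#' @export
graph_metrics <- function(ptem) {
  W <- unclass(ptem)
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (any(W < 0)) stop("edge weights must be non-negative")
  diag(W) <- 0
  nc <- nrow(W)
  labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("Ch", seq_len(nc))

  in_degree <- colSums(W)
  out_degree <- rowSums(W)

  g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                           weighted = TRUE)
  dist_w <- 1 / igraph::E(g)$weight
  btw <- igraph::betweenness(g, directed = TRUE, weights = dist_w)
  D <- igraph::distances(g, mode = "out", weights = dist_w)
  ecc <- apply(D, 1, max)
  diam <- max(D)
  strongly_connected <- all(is.finite(D))

  # eigenvector centrality: x_i proportional to the weight-sum of the
  # centralities of the channels pointing at i, i.e. leading eigenvector
  # of t(W); normalized to unit maximum
  ev <- eigen(t(W))
  lead <- which.max(abs(Re(ev$values)))
  v <- abs(Re(ev$vectors[, lead]))
  eigenvector <- if (max(v) > 0) v / max(v) else v

  list(
    per_channel = data.frame(
      channel = labels,
      in_degree = unname(in_degree),
      out_degree = unname(out_degree),
      betweenness = unname(btw),
      eigenvector = unname(eigenvector),
      eccentricity = unname(ecc),
      row.names = NULL
    ),
    diameter = diam,
    strongly_connected = strongly_connected
  )
}

#' Median connectivity summaries for a record
#'
#' Reduces the PTE matrix and its graph measures to the per-record scalars
#' entering the risk models: median off-diagonal PTE and the median across
#' channels of each graph metric, plus the diameter.
#'
#' @param ptem A `pte_matrix`.
#' @return Named numeric vector (`med_PTE`, `med_in_degree`,
#'   `med_out_degree`, `med_betweenness`, `med_eigenvector`,
#'   `med_eccentricity`, `diameter`).
#' @export
connectivity_summary <- function(ptem) {
  gm <- graph_metrics(ptem)
  W <- unclass(ptem)
  off <- W[row(W) != col(W)]
  pc <- gm$per_channel
  c(med_PTE = stats::median(off),
    med_in_degree = stats::median(pc$in_degree),
    med_out_degree = stats::median(pc$out_degree),
    med_betweenness = stats::median(pc$betweenness),
    med_eigenvector = stats::median(pc$eigenvector),
    med_eccentricity = stats::median(pc$eccentricity),
    diameter = gm$diameter)
}
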