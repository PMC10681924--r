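# Independent oracles used across the suite. All deliberately avoid the
# package's own algorithms: distances and shortest-path counts come from
# adjacency-matrix powers (a walk of length d(s,t) is necessarily a
# shortest path), the eigenvector from a dense symmetric eigensolver, and
# the BH adjustment from a hand-written step-up.

# Build a package graph from a 0/1 adjacency matrix, keeping isolated
# nodes. Node names must sort in index order.
graph_from_adj <- function(A, names = sprintf("N%02d", seq_len(nrow(A)))) {
  w <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  netpharm:::graph_from_pairs(names[w[, 1]], names[w[, 2]], nodes = names)
}

random_adj <- function(n, p) {
  A <- matrix(0L, n, n)
  w <- which(upper.tri(A))
  A[w[stats::runif(length(w)) < p]] <- 1L
  A + t(A)
}

adj_connected <- function(A) {
  n <- nrow(A)
  reach <- c(TRUE, rep(FALSE, n - 1))
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !reach)
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  all(reach)
}

# All four centralities by brute force on an adjacency matrix.
oracle_centralities <- function(A) {
  n <- nrow(A)
  pow <- vector("list", max(1L, n - 1L))
  pow[[1]] <- A
  if (n > 2) for (k in 2:(n - 1)) pow[[k]] <- pow[[k - 1]] %*% A
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (k in seq_len(n - 1)) {
    m <- pow[[k]] > 0 & is.infinite(D)
    D[m] <- k
  }
  bc <- numeric(n)
  if (n >= 3) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      dst <- D[s, t]
      if (!is.finite(dst)) next
      sig <- pow[[dst]][s, t]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        d1 <- D[s, v]; d2 <- D[v, t]
        if (is.finite(d1) && is.finite(d2) && d1 + d2 == dst)
          bc[v] <- bc[v] + pow[[d1]][s, v] * pow[[d2]][v, t] / sig
      }
    }
  }
  cc <- vapply(seq_len(n), function(v) {
    reach <- is.finite(D[v, ])
    cs <- sum(reach)
    if (cs > 1) (cs - 1) / sum(D[v, reach]) else 0
  }, numeric(1))
  comp <- apply(is.finite(D), 1L, function(r) min(which(r)))
  sizes <- table(comp)
  big <- as.integer(names(sizes)[which.max(sizes)])  # ties: smallest index
  idx <- which(comp == big)
  ec <- numeric(n)
  if (length(idx) == 1L) ec[idx] <- 1 else {
    ev <- abs(eigen(A[idx, idx, drop = FALSE], symmetric = TRUE)$vectors[, 1])
    ec[idx] <- ev / max(ev)
  }
  list(dc = rowSums(A), bc = bc, cc = cc, ec = ec)
}

# Hand-written Benjamini-Hochberg step-up.
bh_step_up <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(adj))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exhaustive hypergeometric tail: annotated genes are 1..K of universe
# 1..N; enumerate every n-subset and count overlaps.
enum_hyper_tail <- function(k, K, n, N) {
  if (n == 0L) return(if (k == 0L) 1 else 0)
  subs <- utils::combn(N, n)
  overlaps <- colSums(subs <= K)
  mean(overlaps >= k)
}

# 4PL used by generator checks.
fourpl_curve <- function(dose, lower, upper, hill, ic50) {
  lower + (upper - lower) / (1 + exp(hill * (log(dose) - log(ic50))))
}

make_compound_df <- function(n, gi = "High", bbb = "Yes", pgp = "No",
                             dl_pass = TRUE, dl_viol = 0L,
                             area = NULL) {
  data.frame(
    name = sprintf("c%02d", seq_len(n)),
    formula = rep("C10H16O", n),
    peak_area_pct = area %||% rep(1, n),
    gi_absorption = rep(gi, length.out = n),
    bbb = rep(bbb, length.out = n),
    pgp_substrate = rep(pgp, length.out = n),
    dl_pass = rep(dl_pass, length.out = n),
    dl_violations = rep(dl_viol, length.out = n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
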