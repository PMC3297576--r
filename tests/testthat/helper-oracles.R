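# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# per-base transcript membership map of a gene: base -> sorted member ids
per_base_membership <- function(gene) {
  span <- range(unlist(lapply(gene$transcripts, function(t) t$exons)))
  bases <- seq(span[1L], span[2L] - 1L)
  mem <- lapply(bases, function(b) {
    hit <- vapply(gene$transcripts, function(t)
      any(t$exons[, 1L] <= b & b < t$exons[, 2L]), NA)
    sort(names(gene$transcripts)[hit])
  })
  names(mem) <- bases
  mem[vapply(mem, length, 0L) > 0L]
}

# membership map reconstructed from a segment table
segments_membership <- function(segments) {
  mem <- list()
  for (i in seq_len(nrow(segments))) {
    for (b in seq(segments$start[i], segments$end[i] - 1L))
      mem[[as.character(b)]] <- sort(segments$members[[i]])
  }
  mem
}

# exact NNLS by enumeration of active sets: for every subset of transcripts
# solve the unconstrained least squares on that subset, keep feasible
# solutions, return the best objective
nnls_active_set_oracle <- function(A, y) {
  k <- ncol(A)
  best <- list(obj = sum(y^2), x = numeric(k))  # empty active set
  for (bits in seq_len(2^k - 1L)) {
    S <- which(bitwAnd(bits, 2^(seq_len(k) - 1L)) > 0)
    As <- A[, S, drop = FALSE]
    xs <- tryCatch(qr.solve(crossprod(As), crossprod(As, y)),
                   error = function(e) NULL)
    if (is.null(xs) || any(xs < -1e-12)) next
    xs <- pmax(as.numeric(xs), 0)
    obj <- sum((As %*% xs - y)^2)
    if (obj < best$obj) {
      x <- numeric(k); x[S] <- xs
      best <- list(obj = obj, x = x)
    }
  }
  best
}

# two-sided Fisher exact p by explicit enumeration of the hypergeometric
# probabilities computed from binomial coefficients (no dhyper)
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), 0)
  pobs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# step-up BH from the definition: p_adj(i) = min over j >= i (by sorted
# order) of p(j) * n / j, capped at 1
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n))
    adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# random small gene model for property tests
random_gene_model <- function(gene_id = "Gr", n_tx = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_exons <- sample(3:6, 1L)
  widths <- sample(60:200, n_exons, replace = TRUE)
  gaps <- sample(20:80, n_exons, replace = TRUE)
  starts <- cumsum(gaps) + c(0, cumsum(widths))[seq_len(n_exons)]
  exons <- cbind(starts, starts + widths)
  txs <- list(new_transcript(paste0(gene_id, ".t1"), gene_id, exons))
  for (j in seq_len(n_tx - 1L)) {
    drop <- sample(seq_len(n_exons), sample(1:2, 1L))
    keep <- exons[-drop, , drop = FALSE]
    if (nrow(keep) == 0L) keep <- exons[1L, , drop = FALSE]
    txs <- c(txs, list(new_transcript(paste0(gene_id, ".t", j + 1L),
                                      gene_id, keep)))
  }
  new_gene_model(gene_id, "chrT", "+", txs)
}

# exon-union length counted base by base
gene_union_length_oracle <- function(gene) length(per_base_membership(gene))

# tiny deterministic two-transcript fixture used by several files:
# T1 = [0,100)+[200,300), T2 = [0,100)+[250,300)
fixture_gene <- function() {
  new_gene_model("GF", "chrF", "+", list(
    new_transcript("T1", "GF", rbind(c(0, 100), c(200, 300))),
    new_transcript("T2", "GF", rbind(c(0, 100), c(250, 300)))))
}
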