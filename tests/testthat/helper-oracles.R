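# Independent oracles used across tests. These are deliberately naive
# re-derivations (explicit loops / enumeration) kept separate from the
# package's own code paths.

# hypergeometric upper-tail P(X >= k) by explicit enumeration of the tail,
# via log binomial coefficients; vectorized over parallel table vectors
hyper_tail_oracle <- function(k, n, K, N) {
  hi <- pmin(n, K)
  lens <- pmax(hi - k + 1L, 0L)
  p <- numeric(length(k))
  pos <- lens > 0L
  if (any(pos)) {
    tab <- rep(which(pos), lens[pos])
    x <- sequence(lens[pos], from = k[pos])
    terms <- exp(lchoose(K[tab], x) + lchoose(N[tab] - K[tab], n[tab] - x) -
                   lchoose(N[tab], n[tab]))
    p[pos] <- as.numeric(rowsum(terms, tab))
  }
  p
}

# BH step-up written out longhand: rank ascending, scale by m/i, enforce
# monotonicity from the largest down, cap at 1, restore input order
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric())
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# naive three-formula relative quantification: loops only, observed-value
# means/medians, unique peptides from the map
quant_oracle <- function(I, map) {
  U <- I
  for (j in seq_len(nrow(I))) {
    obs <- !is.na(I[j, ])
    U[j, ] <- I[j, ] / mean(I[j, obs])
  }
  NR <- U
  for (i in seq_len(ncol(U))) {
    obs <- !is.na(U[, i])
    NR[, i] <- U[, i] / median(U[obs, i])
  }
  owners <- table(map$peptide_id)
  uniq <- names(owners)[owners == 1L]
  prot <- sort(unique(map$protein_id[map$peptide_id %in% uniq]))
  R <- matrix(NA_real_, length(prot), ncol(I),
              dimnames = list(prot, colnames(I)))
  for (kk in prot) {
    peps <- map$peptide_id[map$protein_id == kk & map$peptide_id %in% uniq]
    peps <- intersect(peps, rownames(I))
    for (i in seq_len(ncol(I))) {
      v <- NR[peps, i]
      v <- v[!is.na(v)]
      if (length(v)) R[kk, i] <- median(v)
    }
  }
  R
}
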