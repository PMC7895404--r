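# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops, linear scans and direct formula
# evaluation only.

# PHBR scoring oracle: nested loops over start positions, window lengths and
# alleles; rank lookup by linear scan over a plain data.frame.
oracle_score <- function(up, ref, alt, down, alleles, rank_df, lengths) {
  lookup <- function(pep, al) {
    for (i in seq_len(nrow(rank_df))) {
      if (rank_df$peptide[i] == pep && rank_df$allele[i] == al)
        return(rank_df$rank[i])
    }
    stop("oracle: missing pair")
  }
  one_variant <- function(x) {
    seqn <- paste0(up, x, down)
    mpos <- nchar(up) + 1
    pbrs <- numeric(0)
    for (al in alleles) {
      best <- Inf
      for (k in lengths) {
        if (nchar(seqn) < k) next
        for (s in seq_len(nchar(seqn) - k + 1)) {
          if (s <= mpos && mpos <= s + k - 1) {
            r <- lookup(substr(seqn, s, s + k - 1), al)
            if (r < best) best <- r
          }
        }
      }
      pbrs <- c(pbrs, best)
    }
    denom <- 0
    for (p in pbrs) denom <- denom + 1 / p
    list(pbrs = pbrs, phbr = length(pbrs) / denom)
  }
  mut <- one_variant(alt)
  wt <- one_variant(ref)
  list(phbr = mut$phbr, phbr_wt = wt$phbr, delta = mut$phbr - wt$phbr,
       pbrs = mut$pbrs)
}

# Step-up BH oracle: direct double-loop definition
#   q_i = min over j with p_j >= p_i of (n * p_j / rank(p_j)), capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "max")
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- 1
    for (j in seq_len(n)) {
      if (p[j] >= p[i]) cand <- min(cand, n * p[j] / r[j])
    }
    q[i] <- cand
  }
  q
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all assignments of
# the pooled ranks to the first group. p = 2 * min(P(W <= w), P(W >= w)),
# capped at 1 (no ties assumed).
oracle_wilcoxon <- function(obs, unobs) {
  pooled <- c(obs, unobs)
  rk <- rank(pooled)
  k <- length(obs)
  w_obs <- sum(rk[seq_len(k)])
  sets <- utils::combn(length(pooled), k)
  w_all <- apply(sets, 2, function(ii) sum(rk[ii]))
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

# Two-sided Fisher's exact p for a 2x2 table via explicit hypergeometric
# probabilities computed from choose().
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  pr <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  p_obs <- pr[match(a, support)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Independent enumeration of single-nucleotide missense substitution types,
# built from Biostrings' genetic code and a different traversal (all ordered
# codon pairs, filtered to Hamming distance 1).
oracle_missense_pairs <- function() {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  pairs <- character(0)
  for (c1 in codons) for (c2 in codons) {
    d <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (d != 1) next
    a1 <- unname(code[c1]); a2 <- unname(code[c2])
    if (a1 == "*" || a2 == "*" || a1 == a2) next
    pairs <- c(pairs, paste(a1, a2))
  }
  sort(unique(pairs))
}

# Small random context helper shared by several tests.
random_context_fixture <- function(id, rng_alphabet = phbrsel::AA_ALPHABET,
                                   max_flank = 14) {
  up <- paste0(sample(rng_alphabet, sample(0:max_flank, 1), TRUE),
               collapse = "")
  down <- paste0(sample(rng_alphabet, sample(0:max_flank, 1), TRUE),
                 collapse = "")
  ra <- sample(rng_alphabet, 2)
  protein_context(id, "GENE", ra[1], ra[2], 50, up, down)
}
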