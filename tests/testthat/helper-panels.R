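# small hand-built and random panels shared across tests

`%||%` <- function(x, y) if (is.null(x)) y else x

make_panel <- function(dosages, chrom = NULL, pos = NULL, pops = NULL) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  chrom <- chrom %||% rep("1", m)
  pos <- pos %||% seq(1000L, by = 1000L, length.out = m)
  pops <- pops %||% rep("pop1", n)
  genotype_panel(
    dosages,
    tibble::tibble(sample_id = sprintf("s%03d", seq_len(n)), population = pops),
    tibble::tibble(chrom = chrom, pos = as.integer(pos),
                   vid = sprintf("v%03d", seq_len(m)),
                   allele_a = "A", allele_b = "B")
  )
}

random_panel <- function(n = 8, m = 12, missing_rate = 0.1, n_chrom = 2) {
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  d[matrix(runif(n * m) < missing_rate, n, m)] <- NA_integer_
  chrom <- as.character(rep_len(seq_len(n_chrom), m))
  ord <- order(chrom)
  pos <- unlist(lapply(split(seq_len(m), chrom[ord]), function(ix)
    sort(sample.int(1e6, length(ix)))), use.names = FALSE)
  make_panel(d[, ord, drop = FALSE], chrom = chrom[ord], pos = pos,
             pops = rep_len(c("pop1", "pop2"), n))
}

# independent enumeration oracle for the HWE exact test: closed-form
# conditional probabilities via lgamma, summed over configurations whose
# probability does not exceed the observed one
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_A, 2 * n - n_A)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (rare - h) / 2
    bb <- n - aa - h
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) +
      lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# independent log-likelihood of a 3x3 genotype table given gamete freqs
loglik_oracle <- function(counts, pAB, pAb, paB, pab) {
  P <- matrix(0, 3, 3)
  P[3, 3] <- pAB^2;       P[3, 2] <- 2 * pAB * pAb; P[3, 1] <- pAb^2
  P[2, 3] <- 2 * pAB * paB
  P[2, 2] <- 2 * (pAB * pab + pAb * paB)
  P[2, 1] <- 2 * pAb * pab
  P[1, 3] <- paB^2;       P[1, 2] <- 2 * paB * pab; P[1, 1] <- pab^2
  # rows/cols here are dosage+1 at locus 1 / locus 2; clamp tiny negative
  # frequencies arising from float round-off at the parameter-space boundary
  P <- pmax(P, 0)
  sum(counts[counts > 0] * log(P[counts > 0]))
}

# grid-search maximum likelihood over p_AB with marginals fixed
grid_oracle <- function(counts, resolution = 1e-4) {
  N2 <- 2 * sum(counts)
  pA <- sum((0:2) * rowSums(counts)) / N2
  pB <- sum((0:2) * colSums(counts)) / N2
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, by = resolution)
  ll <- vapply(grid, function(g)
    loglik_oracle(counts, g, pA - g, pB - g, 1 - pA - pB + g), numeric(1))
  list(p_AB = grid[which.max(ll)], loglik = max(ll))
}

random_genotype_table <- function(n = 20) {
  f <- as.vector(stats::rmultinom(1, 4, rep(1, 4)) + 1)
  f <- f / sum(f)
  hap <- matrix(sample.int(4, 2 * n, replace = TRUE, prob = f), ncol = 2)
  a <- rowSums(hap <= 2)            # copies of allele A (haps 1=AB, 2=Ab)
  b <- rowSums(hap %% 2 == 1)       # copies of allele B (haps 1=AB, 3=aB)
  two_locus_counts(a, b)
}
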