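# Independent reference implementations ("oracles") used by the property
# tests. These deliberately share no code with the package: plain loops
# and direct transcriptions of the defining formulas.

# ---- pool-seq F_ST: loop transcription of the MoM identity estimator ----
# counts: data frame with per-site allele-1/allele-2 read counts for each
# pool (c1_1, c2_1, c1_2, c2_2); n1, n2 = pool sizes in chromosomes.
oracle_fst <- function(counts, n1, n2) {
  num_sum <- 0
  den_sum <- 0
  for (i in seq_len(nrow(counts))) {
    c11 <- counts$c1_1[i]
    c21 <- counts$c2_1[i]
    c12 <- counts$c1_2[i]
    c22 <- counts$c2_2[i]
    r1 <- c11 + c21
    r2 <- c12 + c22
    D2_1 <- (c11 * (c11 - 1) + c21 * (c21 - 1)) / (r1 * (r1 - 1))
    D2_2 <- (c12 * (c12 - 1) + c22 * (c22 - 1)) / (r2 * (r2 - 1))
    Q1_1 <- (D2_1 - 1 / n1) / (1 - 1 / n1)
    Q1_2 <- (D2_2 - 1 / n2) / (1 - 1 / n2)
    Q1 <- (Q1_1 + Q1_2) / 2
    Q2 <- (c11 / r1) * (c12 / r2) + (c21 / r1) * (c22 / r2)
    num_sum <- num_sum + (Q1 - Q2)
    den_sum <- den_sum + (1 - Q2)
  }
  num_sum / den_sum
}

# ---- diploid drive recursion: exhaustive mating-table enumeration ----
# F: 4x4 ordered-pair female genotype matrix (maternal origin in rows);
# m: male frequencies; k, costs, c as in drive_params. Types in the
# canonical order ST(ab)=1, SR(AB)=2, BM(Ab)=3, T(aB)=4.
oracle_diploid_step <- function(F, m, k, costs, c, male_expressed) {
  # viability selection
  Fs <- F
  for (i in 1:4) Fs[i, i] <- F[i, i] * (1 - costs[i])
  Fs <- Fs / sum(Fs)
  ms <- m
  if (male_expressed) {
    ms <- m * (1 - costs)
    ms <- ms / sum(ms)
  }
  # gamete output of a female with maternal-origin type i, paternal j:
  # Mendelian halves, double heterozygotes exchange at c/2 per class
  gam <- function(i, j) {
    g <- numeric(4)
    g[i] <- g[i] + 0.5
    g[j] <- g[j] + 0.5
    if ((i == 1 && j == 2) || (i == 2 && j == 1)) { # AB/ab coupling
      g[1] <- g[1] - c / 2
      g[2] <- g[2] - c / 2
      g[3] <- g[3] + c / 2
      g[4] <- g[4] + c / 2
    }
    if ((i == 3 && j == 4) || (i == 4 && j == 3)) { # Ab/aB repulsion
      g[3] <- g[3] - c / 2
      g[4] <- g[4] - c / 2
      g[1] <- g[1] + c / 2
      g[2] <- g[2] + c / 2
    }
    g
  }
  w_d <- sum(ms * k) # daughters per father-type unit
  w_s <- sum(ms * (1 - k)) # sons
  Fn <- matrix(0, 4, 4)
  mn <- numeric(4)
  for (i in 1:4) {
    for (j in 1:4) {
      if (Fs[i, j] == 0) next
      g_ij <- gam(i, j)
      for (a in 1:4) {
        if (g_ij[a] == 0) next
        for (gp in 1:4) {
          # daughters: mother (i,j) passes a, father gp passes his X,
          # sired in proportion to ms[gp] * k[gp]
          wt <- Fs[i, j] * g_ij[a] * ms[gp] * k[gp] / w_d
          Fn[a, gp] <- Fn[a, gp] + wt / 2
          Fn[gp, a] <- Fn[gp, a] + wt / 2
          # sons: receive the maternal gamete only
          mn[a] <- mn[a] + Fs[i, j] * g_ij[a] * ms[gp] * (1 - k[gp]) / w_s
        }
      }
    }
  }
  list(F = Fn, m = mn, sex_ratio = w_d)
}

# random valid diploid state + parameters for property tests
random_drive_case <- function() {
  F <- matrix(runif(16), 4, 4)
  F <- F / sum(F)
  dimnames(F) <- list(gamete_types(), gamete_types())
  m <- runif(4)
  m <- m / sum(m)
  list(
    state = diploid_state(x_male = m, F = F),
    k = setNames(runif(4, 0.1, 0.97), gamete_types()),
    costs = setNames(runif(4, 0, 0.6), gamete_types()),
    c = runif(1, 0, 0.3),
    male_expressed = sample(c(TRUE, FALSE), 1)
  )
}

# ---- haplotype-table r2: brute force from the 2x2 haplotype counts ----
oracle_r2 <- function(a, b) {
  n <- length(a)
  p <- sum(a) / n
  q <- sum(b) / n
  p11 <- sum(a == 1 & b == 1) / n
  D <- p11 - p * q
  D^2 / (p * (1 - p) * q * (1 - q))
}

# ---- Benjamini-Hochberg step-up, straight from the definition ----
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  # step-up: running minimum from the largest rank down, capped at 1
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# ---- small sync-table builder for two pools over one chromosome ----
# Each argument is a per-site read count of alleles A and T.
toy_sync <- function(a1, t1, a2, t2, n1 = 8, n2 = 8,
                     pos = seq_along(a1), chrom = "X",
                     outgroup = NA_character_, callable = TRUE) {
  L <- length(a1)
  zeros <- rep(0L, L)
  sites <- tibble::tibble(
    chrom = chrom, pos = pos, ref = "A",
    outgroup = outgroup, callable = callable,
    p1.A = as.integer(a1), p1.T = as.integer(t1), p1.C = zeros,
    p1.G = zeros, p1.N = zeros, p1.del = zeros,
    p2.A = as.integer(a2), p2.T = as.integer(t2), p2.C = zeros,
    p2.G = zeros, p2.N = zeros, p2.del = zeros
  )
  as_sync_table(sites, pool_info(c("p1", "p2"), c(n1, n2)))
}
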