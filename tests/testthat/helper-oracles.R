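# Independent brute-force oracles and shared toy fixtures. Everything here
# is deliberately naive (dense inverses, explicit enumeration, O(n^2)
# scans) so it cannot share code paths with the implementation it checks.

# dense-inverse multivariate normal log-density
brute_mvn_logpdf <- function(S, sigma) {
  S <- as.numeric(S)
  T <- length(S)
  as.numeric(-0.5 * T * log(2 * pi) - 0.5 * log(det(sigma)) -
               0.5 * t(S) %*% solve(sigma) %*% S)
}

# m-values by explicit enumeration of all 2^T configurations with dense
# densities in natural (non-log) space
brute_mvalues <- function(S, sigma_e, sigma_g_z, scale = 1) {
  T <- length(S)
  cfgs <- as.matrix(expand.grid(rep(list(0:1), T)))
  dens <- apply(cfgs, 1, function(cc) {
    sig <- sigma_e + scale * (sigma_g_z * outer(cc, cc))
    exp(brute_mvn_logpdf(S, sig))
  })
  vapply(seq_len(T), function(i) {
    sum(dens[cfgs[, i] == 1]) / sum(dens)
  }, numeric(1))
}

# exhaustive greedy-equivalent clump: repeated full scans, same tie rule
brute_clump <- function(chrom, pos, score, window_bp = 1e6,
                        decreasing = TRUE) {
  alive <- rep(TRUE, length(pos))
  leads <- integer(0)
  half <- window_bp / 2
  while (any(alive)) {
    cand <- which(alive)
    sc <- score[cand]
    best <- if (decreasing) cand[sc == max(sc)] else cand[sc == min(sc)]
    best <- best[which.min(pos[best])]
    leads <- c(leads, best)
    for (j in which(alive)) {
      if (chrom[j] == chrom[best] && pos[j] >= pos[best] - half &&
          pos[j] < pos[best] + half)
        alive[j] <- FALSE
    }
  }
  leads
}

# binomial upper-tail by direct coefficient summation (exact for small n)
brute_binom_tail <- function(n_same, n_total) {
  sum(choose(n_total, n_same:n_total)) * 0.5^n_total
}

# importance-sampling standard error of a weighted tail estimate
is_se <- function(stats, weights, threshold) {
  ind <- stats >= threshold
  W <- sum(weights)
  p <- sum(weights[ind]) / W
  sqrt(sum((weights * (ind - p))^2)) / W
}

# synthetic four-trait panel emulating large-biobank anthropometric and
# blood-pressure traits (stand-in values; see the methods vignette)
trait_panel <- function() {
  traits <- c("BMI", "DBP", "height", "SBP")
  h2 <- c(0.25, 0.15, 0.45, 0.15)
  rg <- matrix(c(1, .30, .10, .30,
                 .30, 1, 0, .75,
                 .10, 0, 1, 0,
                 .30, .75, 0, 1), 4, 4, dimnames = list(traits, traits))
  rho_e <- matrix(c(1, .25, .05, .25,
                    .25, 1, 0, .65,
                    .05, 0, 1, 0,
                    .25, .65, 0, 1), 4, 4, dimnames = list(traits, traits))
  n <- rep(360000, 4)
  n_shared <- matrix(360000, 4, 4)
  sigma_h2 <- rg * sqrt(outer(h2, h2))
  list(trait_names = traits, n = n, h2 = h2, sigma_h2 = sigma_h2,
       rho_e = rho_e, n_shared = n_shared)
}

# small exchangeable two-trait model used across tests
toy_model2 <- function(n_sigma = 1.5, rho_g = 0.5, rho_e = 0,
                       N = 10000) {
  sg2 <- n_sigma / N
  sigma_g <- matrix(c(sg2, rho_g * sg2, rho_g * sg2, sg2), 2, 2)
  re <- matrix(c(1, rho_e, rho_e, 1), 2, 2)
  ns <- if (rho_e != 0) matrix(N, 2, 2) else diag(c(N, N))
  cov_model(c(N, N), sigma_g, rho_e = re, n_shared = ns)
}

# write a small sumstats file under tempdir(); returns the path
write_toy_sumstats <- function(dt) {
  path <- tempfile("sumstats", fileext = ".tsv")
  data.table::fwrite(dt, path, sep = "\t")
  path
}
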