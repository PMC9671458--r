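#' Greedy clumping of scored variants
#'
#' Repeatedly selects the best-scoring remaining variant as a lead and
#' removes every other variant on the same chromosome within the window
#' centered on it (`[lead - window/2, lead + window/2)`, half-open).
#' Scores are m-values (largest wins, the default) or p-values
#' (`decreasing = FALSE`, smallest wins). Ties break toward the smaller
#' genomic coordinate, so the result is deterministic.
#'
#' @param chrom,pos per-variant chromosome and base-pair position.
#' @param score per-variant score (finite).
#' @param window_bp suppression window width; default 1e6 (1MB).
#' @param decreasing `TRUE` to treat larger scores as better.
#' @return integer indices of the lead variants, in selection order.
#' @export
clump <- function(chrom, pos, score, window_bp = 1e6, decreasing = TRUE) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(score),
            all(is.finite(score)))
  s <- if (decreasing) -score else score
  ord <- order(s, pos)      # best score first; coordinate breaks ties
  alive <- rep(TRUE, length(pos))
  leads <- integer(0)
  half <- window_bp / 2
  for (i in ord) {
    if (!alive[i]) next
    leads <- c(leads, i)
    hit <- alive & chrom == chrom[i] & pos >= pos[i] - half &
      pos < pos[i] + half
    alive[hit] <- FALSE
  }
  leads
}

#' One-sided directional replication test
#'
#' Tests whether the replication cohort's effect lies in the direction
#' seen at discovery: `z_rep = sign(beta_disc) * beta_rep / se_rep`,
#' `p = 1 - Phi(z_rep)`; a variant replicates when p falls below the
#' (Bonferroni-adjusted) level.
#'
#' @param beta_disc discovery effect size(s); must be nonzero (they set
#'   the direction).
#' @param beta_rep,se_rep replication effect sizes and standard errors.
#' @param alpha_adjusted the adjusted significance level, e.g.
#'   `0.05 / n_leads`.
#' @return data.table with `z_rep`, `p_one_sided`, `replicated`,
#'   `same_direction`.
#' @export
one_sided_replication_test <- function(beta_disc, beta_rep, se_rep,
                                       alpha_adjusted) {
  if (any(beta_disc == 0))
    stop("beta_disc of 0 gives no direction to test")
  if (any(se_rep <= 0)) stop("se_rep must be positive")
  z_rep <- sign(beta_disc) * beta_rep / se_rep
  p <- stats::pnorm(z_rep, lower.tail = FALSE)
  data.table::data.table(z_rep = z_rep, p_one_sided = p,
                         replicated = p < alpha_adjusted,
                         same_direction = sign(beta_disc) == sign(beta_rep) &
                           beta_rep != 0)
}

#' Exact one-sided binomial sign-concordance test
#'
#' Tests whether the proportion of effect sizes sharing the discovery
#' direction exceeds 0.5: `p = P(X >= n_same)` for
#' `X ~ Binomial(n_total, 0.5)`, exact (the printed p-values of interest
#' are far past normal-approximation validity).
#'
#' @param n_same number of leads with concordant direction.
#' @param n_total number of leads tested.
#' @return the one-sided p-value.
#' @export
concordance_binomial <- function(n_same, n_total) {
  stopifnot(n_total >= 1, n_same >= 0, n_same <= n_total)
  stats::pbinom(n_same - 1, n_total, 0.5, lower.tail = FALSE)
}

#' Approximate power of the one-sided replication test
#'
#' Assumes a standardized phenotype so a variant with effect `beta` and
#' minor allele frequency `maf` has expected replication z-score
#' `lambda = |beta| * sqrt(2 * maf * (1 - maf) * n_rep)` (genotype variance
#' `2 maf (1 - maf)`); power of the directional test at `alpha_adjusted`
#' is `1 - Phi(qnorm(1 - alpha_adjusted) - lambda)`. With `beta = 0` this
#' returns the test's size. MAF is often taken from a reference panel
#' rather than the replication cohort itself, so the value is approximate.
#'
#' @param beta_disc discovery effect size(s).
#' @param maf minor allele frequency in (0, 0.5].
#' @param n_rep replication sample size(s).
#' @param alpha_adjusted adjusted significance level.
#' @return power in \[0, 1\].
#' @export
replication_power <- function(beta_disc, maf, n_rep, alpha_adjusted) {
  stopifnot(all(maf > 0), all(maf <= 0.5), all(n_rep >= 1))
  lambda <- abs(beta_disc) * sqrt(2 * maf * (1 - maf) * n_rep)
  stats::pnorm(stats::qnorm(1 - alpha_adjusted) - lambda,
               lower.tail = FALSE)
}

#' Power-decile replication summary
#'
#' Bins lead variants into replication-power deciles ([0,10%), ...,
#' [90,100%]) and reports, per decile, the number tested, the expected
#' number of replications (the sum of per-variant power), the observed
#' replications, the number with concordant effect direction, and the
#' exact binomial concordance p-value.
#'
#' @param power per-lead replication power in \[0, 1\].
#' @param replicated per-lead logical.
#' @param same_direction per-lead logical.
#' @return data.table with one row per non-empty decile.
#' @export
power_decile_summary <- function(power, replicated, same_direction) {
  stopifnot(length(power) == length(replicated),
            length(power) == length(same_direction))
  dec <- pmin(floor(power * 10), 9)
  out <- lapply(sort(unique(dec)), function(d) {
    idx <- dec == d
    ns <- sum(same_direction[idx])
    nt <- sum(idx)
    data.table::data.table(
      decile = sprintf("%d-%d%%", d * 10, (d + 1) * 10),
      n_tested = nt,
      average_power = mean(power[idx]),
      expected_replications = sum(power[idx]),
      n_replicated = sum(replicated[idx]),
      n_same_direction = ns,
      concordance_p = concordance_binomial(ns, nt))
  })
  data.table::rbindlist(out)
}
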