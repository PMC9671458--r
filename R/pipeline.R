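#' Read a trait-by-trait covariance or correlation matrix
#'
#' Square numeric CSV with a trait-name header row and first column; the
#' trait order is validated against `trait_names` when given.
#'
#' @param path CSV file path.
#' @param trait_names expected trait order, or NULL to accept the file's.
#' @return named numeric matrix.
#' @export
read_trait_matrix <- function(path, trait_names = NULL) {
  dt <- data.table::fread(path, header = TRUE)
  rn <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- rn
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column trait names disagree in ", path)
  if (!is.null(trait_names) && !identical(colnames(m), trait_names))
    stop("trait order in ", path, " (", paste(colnames(m), collapse = ","),
         ") does not match the summary statistics (",
         paste(trait_names, collapse = ","), ")")
  storage.mode(m) <- "double"
  m
}

#' Write a trait-by-trait matrix as CSV
#' @param m named square matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_matrix <- function(m, path) {
  dt <- data.table::data.table(trait = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Generate a self-contained synthetic multi-trait fixture on disk
#'
#' Writes per-trait summary-statistics files drawn from a known generative
#' model, together with the matching covariance inputs and a per-variant
#' truth table. The files deliberately exercise the ingest path: a subset
#' of records in traits 2..T have ref/alt swapped (with the z-score
#' negated, so harmonization must flip them back), and each trait file
#' carries planted QC failures — low-MAF rows, low-INFO rows,
#' strand-ambiguous allele pairs, and an invalid ref == alt row.
#'
#' @param T number of traits (2..6).
#' @param n_variants clean variants shared by all traits.
#' @param seed integer seed.
#' @param dir output directory (created).
#' @param frac_causal fraction of variants given a true effect; default 0.1.
#' @return list describing the fixture: file paths, planted defect counts,
#'   trait names, sample sizes and the generative matrices.
#' @export
make_fixture <- function(T = 4, n_variants = 1000, seed, dir,
                         frac_causal = 0.1) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(T >= 2, T <= 6)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  trait_names <- paste0("trait", seq_len(T))
  n <- rep(50000, T)
  rho_e <- 0.3^abs(outer(seq_len(T), seq_len(T), "-"))
  n_shared <- matrix(25000, T, T)
  diag(n_shared) <- n
  h2 <- rep(0.3, T)
  rg <- 0.5^abs(outer(seq_len(T), seq_len(T), "-"))
  sigma_h2 <- rg * sqrt(outer(h2, h2))
  causal <- round(n_variants * frac_causal)
  sigma_g <- sigma_h2 / max(causal, 1)

  # variant grid on two chromosomes, non-ambiguous allele pairs
  chrom <- rep(c("1", "2"), length.out = n_variants)
  pos <- as.integer(10000 * seq_len(n_variants))
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                    "G", "A", "C", "A", "G", "T", "C", "T"),
                  ncol = 2, byrow = TRUE)
  pick <- sample(nrow(pairs), n_variants, replace = TRUE)
  ref <- pairs[pick, 1]
  alt <- pairs[pick, 2]
  ids <- sprintf("rs%06d", seq_len(n_variants))

  config_pool <- configurations(T)
  config_pool <- config_pool[rowSums(config_pool) > 0, , drop = FALSE]
  truth <- matrix(0L, n_variants, T)
  causal_idx <- sample(n_variants, causal)
  truth[causal_idx, ] <- config_pool[sample(nrow(config_pool), causal,
                                            replace = TRUE), ]

  sigma_e <- build_sigma_e(rho_e, n, n_shared)
  sg_z <- build_sigma_g_z(sigma_g, n)
  z <- matrix(stats::rnorm(n_variants * T), n_variants, T) %*% chol(sigma_e)
  for (i in causal_idx) {
    sig_c <- sigma_e + masked_sigma_g(sg_z, truth[i, ])
    z[i, ] <- stats::rnorm(T) %*% chol(sig_c)
  }

  maf <- round(stats::runif(n_variants, 0.05, 0.5), 4)
  info <- round(stats::runif(n_variants, 0.9, 1.0), 4)

  planted <- list(swapped = integer(T), qc_fail = integer(T))
  files <- character(T)
  for (t in seq_len(T)) {
    tb <- data.table::data.table(
      SNP = ids, CHR = chrom, BP = pos, A1 = ref, A2 = alt,
      Z = round(z[, t], 6), N = n[t], MAF = maf, INFO = info)
    if (t > 1) {
      sw <- sample(n_variants, max(1, round(0.05 * n_variants)))
      tb$A1[sw] <- alt[sw]
      tb$A2[sw] <- ref[sw]
      tb$Z[sw] <- -tb$Z[sw]
      planted$swapped[t] <- length(sw)
    }
    bad <- data.table::data.table(
      SNP = sprintf("rsbad%d%02d", t, 1:4),
      CHR = "1", BP = as.integer(9e7 + t * 100 + 1:4),
      A1 = c("A", "A", "A", "A"), A2 = c("G", "G", "T", "A"),
      Z = 0.1, N = n[t],
      MAF = c(0.005, 0.3, 0.3, 0.3),      # row 1 fails MAF
      INFO = c(0.99, 0.5, 0.99, 0.99))    # row 2 fails INFO; 3 ambiguous;
    planted$qc_fail[t] <- nrow(bad)       # 4 invalid (ref == alt)
    tb <- rbind(tb, bad)
    files[t] <- file.path(dir, paste0(trait_names[t], ".sumstats.tsv"))
    data.table::fwrite(tb, files[t], sep = "\t")
  }

  dimnames(rho_e) <- dimnames(sigma_g) <- dimnames(n_shared) <-
    list(trait_names, trait_names)
  write_trait_matrix(rho_e, file.path(dir, "rho_e.csv"))
  write_trait_matrix(sigma_g, file.path(dir, "sigma_g.csv"))
  write_trait_matrix(n_shared, file.path(dir, "overlap.csv"))
  truth_dt <- data.table::data.table(SNP = ids, CHR = chrom, BP = pos)
  for (t in seq_len(T)) truth_dt[[trait_names[t]]] <- truth[, t]
  data.table::fwrite(truth_dt, file.path(dir, "truth.tsv"), sep = "\t")

  list(dir = dir, sumstats = stats::setNames(files, trait_names),
       rho_e = file.path(dir, "rho_e.csv"),
       sigma_g = file.path(dir, "sigma_g.csv"),
       overlap = file.path(dir, "overlap.csv"),
       truth = file.path(dir, "truth.tsv"),
       trait_names = trait_names, n = n, causal = causal,
       planted = planted, seed = as.integer(seed))
}

# internal: default column map matching make_fixture's files
fixture_column_map <- function() {
  list(id = "SNP", chrom = "CHR", pos = "BP", ref = "A1", alt = "A2",
       z = "Z", n = "N", maf = "MAF", info = "INFO")
}

#' Validate a pipeline configuration
#'
#' @param config list with `sumstats` (named character vector of per-trait
#'   file paths), `rho_e`, `sigma_g`, `overlap` (matrix CSVs; `overlap`
#'   optional), `alpha`, `calib_n`, `r`, `seed`, `mvalue_threshold`,
#'   `out_dir`, optional `column_map`.
#' @return the config, with defaults filled in.
#' @export
validate_config <- function(config) {
  req <- c("sumstats", "rho_e", "sigma_g", "seed", "out_dir")
  for (k in req) if (is.null(config[[k]]))
    stop("pipeline config is missing '", k, "'")
  if (is.null(config$alpha)) config$alpha <- 5e-8
  if (config$alpha <= 0 || config$alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (is.null(config$calib_n)) config$calib_n <- 1e6
  if (is.null(config$r)) config$r <- 2
  if (is.null(config$mvalue_threshold)) config$mvalue_threshold <- 0.9
  if (is.null(config$column_map)) config$column_map <- fixture_column_map()
  for (p in c(config$sumstats, config$rho_e, config$sigma_g, config$overlap))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  if (length(config$sumstats) < 2)
    stop("at least two per-trait summary-statistics files are required")
  config
}

#' Run the full two-step pipeline
#'
#' Harmonize per-trait summary statistics, build the covariance model,
#' calibrate the PAT null by importance sampling, test every variant,
#' estimate the causal count Q from the hits, compute m-values and
#' per-trait assignments, and write all outputs plus a run manifest.
#' Rerunning with an identical config reproduces identical outputs.
#'
#' @param config see [validate_config()].
#' @return the manifest (invisibly also written to `manifest.txt`): a list
#'   of stage outputs and the paths written.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  trait_names <- names(config$sumstats)
  if (is.null(trait_names)) trait_names <- paste0("trait",
                                                  seq_along(config$sumstats))
  tabs <- stage("ingest", lapply(config$sumstats, function(p)
    qc_filter(read_sumstats(p, config$column_map))))
  ms <- stage("harmonize", harmonize(tabs, trait_names))
  harm_path <- file.path(config$out_dir, "harmonized.tsv")
  write_multi_sumstats(ms, harm_path)

  rho_e <- stage("covariance", read_trait_matrix(config$rho_e, trait_names))
  sigma_g <- stage("covariance", read_trait_matrix(config$sigma_g,
                                                   trait_names))
  n_shared <- if (!is.null(config$overlap))
    read_trait_matrix(config$overlap, trait_names) else NULL
  model <- stage("covariance",
                 cov_model(ms$n_per_trait, sigma_g, rho_e = rho_e,
                           n_shared = n_shared, trait_names = trait_names))

  cal <- stage("calibrate",
               simulate_null(model, n = config$calib_n, r = config$r,
                             seed = config$seed, statistic = "pat"))
  res <- stage("test", run_pat(ms, model, cal, alpha = config$alpha))
  res_path <- file.path(config$out_dir, "pat_results.tsv")
  data.table::fwrite(res, res_path, sep = "\t")

  mval_path <- file.path(config$out_dir, "mvalues.tsv")
  hits_idx <- which(res$significant)
  if (length(hits_idx) > 0) {
    hits <- structure(list(trait_names = trait_names,
                           variants = ms$variants[hits_idx, ],
                           z = ms$z[hits_idx, , drop = FALSE],
                           n = ms$n[hits_idx, , drop = FALSE],
                           n_per_trait = ms$n_per_trait),
                      class = "multi_sumstats")
    cs <- stage("mvalues", estimate_q(hits, model, M = nrow(ms$z),
                                      seed = config$seed + 1))
    m <- stage("mvalues", compute_mvalues(hits$z, model, scale = cs$scale))
    lab <- assign_mvalues(m, config$mvalue_threshold)
    mv <- data.table::as.data.table(hits$variants)
    for (i in seq_along(trait_names))
      mv[[paste0("m_", trait_names[i])]] <- m[, i]
    for (i in seq_along(trait_names))
      mv[[paste0("assignment_", trait_names[i])]] <- lab[, i]
    mv$Q <- cs$Q
    mv$scale <- cs$scale
    data.table::fwrite(mv, mval_path, sep = "\t")
    q_used <- cs$Q
  } else {
    data.table::fwrite(data.table::data.table(), mval_path, sep = "\t")
    q_used <- NA_integer_
  }

  manifest <- c(
    sprintf("patgwas pipeline manifest"),
    sprintf("traits: %s", paste(trait_names, collapse = ",")),
    sprintf("n_variants_harmonized: %d", nrow(ms$z)),
    sprintf("alpha: %g", config$alpha),
    sprintf("calibration: n=%g r=%g seed=%d", config$calib_n, config$r,
            as.integer(config$seed)),
    sprintf("n_significant: %d", length(hits_idx)),
    sprintf("Q: %s", as.character(q_used)),
    sprintf("outputs: %s", paste(c(harm_path, res_path, mval_path),
                                 collapse = " ")))
  manifest_path <- file.path(config$out_dir, "manifest.txt")
  writeLines(manifest, manifest_path)
  invisible(list(harmonized = harm_path, results = res_path,
                 mvalues = mval_path, manifest = manifest_path,
                 n_significant = length(hits_idx), Q = q_used,
                 model = model))
}
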