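#' Read one trait's GWAS summary statistics
#'
#' Reads a headered, tab- or whitespace-delimited summary-statistics table
#' (optionally gzipped) and maps its columns onto a standard layout. A
#' z-score column may be supplied directly, or derived as `beta / se`.
#' Rows whose required fields fail to parse (non-numeric z/beta/se/n,
#' non-positive se or n, invalid alleles such as ref == alt or non-ACGT
#' codes) are dropped with a message reporting the count.
#'
#' @param path file path.
#' @param column_map named list mapping standard names to file column
#'   names. Required: `id`, `chrom`, `pos`, `ref`, `alt`, `n`, and either
#'   `z` or both `beta` and `se`. Optional: `maf`, `info`.
#' @return a `data.table` of class `sumstats` with columns `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `z`, `beta`, `se`, `n`, `maf`, `info`
#'   (optional fields `NA` when absent from the file).
#' @export
read_sumstats <- function(path,
                          column_map = list(id = "SNP", chrom = "CHR",
                                            pos = "BP", ref = "A1",
                                            alt = "A2", z = "Z", n = "N")) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  if (nrow(dt) == 0) stop("empty summary-statistics file: ", path)
  need <- c("id", "chrom", "pos", "ref", "alt", "n")
  for (k in need) {
    if (is.null(column_map[[k]]))
      stop("column_map is missing required entry '", k, "'")
  }
  has_z <- !is.null(column_map$z)
  has_bse <- !is.null(column_map$beta) && !is.null(column_map$se)
  if (!has_z && !has_bse)
    stop("column_map must provide either 'z' or both 'beta' and 'se'")
  for (k in names(column_map)) {
    cn <- column_map[[k]]
    if (!is.null(cn) && !cn %in% names(dt))
      stop("column '", cn, "' (mapped from '", k, "') not found in ", path)
  }
  grab <- function(k, as = identity) {
    cn <- column_map[[k]]
    if (is.null(cn)) rep(NA_real_, nrow(dt)) else as(dt[[cn]])
  }
  out <- data.table::data.table(
    variant_id = as.character(dt[[column_map$id]]),
    chrom = as.character(dt[[column_map$chrom]]),
    pos = suppressWarnings(as.integer(dt[[column_map$pos]])),
    ref = toupper(as.character(dt[[column_map$ref]])),
    alt = toupper(as.character(dt[[column_map$alt]])),
    z = suppressWarnings(as.numeric(grab("z"))),
    beta = suppressWarnings(as.numeric(grab("beta"))),
    se = suppressWarnings(as.numeric(grab("se"))),
    n = suppressWarnings(as.numeric(grab("n"))),
    maf = suppressWarnings(as.numeric(grab("maf"))),
    info = suppressWarnings(as.numeric(grab("info")))
  )
  out$z <- ifelse(is.na(out$z) & !is.na(out$beta) & !is.na(out$se),
                  out$beta / out$se, out$z)
  ok <- !is.na(out$pos) & !is.na(out$z) & is.finite(out$z) &
    !is.na(out$n) & out$n > 0 &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
    out$ref != out$alt &
    (is.na(out$se) | out$se > 0)
  dropped <- sum(!ok)
  if (dropped > 0)
    message(sprintf("read_sumstats: dropped %d unparseable/invalid row(s) from %s",
                    dropped, basename(path)))
  out <- out[ok, ]
  data.table::setattr(out, "class", c("sumstats", class(out)))
  out[]
}

#' QC-filter summary-statistic records
#'
#' Retains biallelic SNPs passing minor-allele-frequency and imputation
#' INFO thresholds, optionally dropping strand-ambiguous allele pairs
#' (A/T, T/A, C/G, G/C). Records missing `maf` or `info` fail the
#' corresponding enabled filter (fail-closed) unless `missing_pass = TRUE`.
#'
#' @param records a `sumstats` table from [read_sumstats()].
#' @param maf_min minimum minor allele frequency (strict >); `NULL`
#'   disables the filter. Default 0.01.
#' @param info_min minimum INFO score (strict >); `NULL` disables. Default 0.8.
#' @param drop_strand_ambiguous drop A/T and C/G pairs? Default `TRUE`.
#' @param missing_pass if `TRUE`, records with missing maf/info pass the
#'   corresponding filter instead of failing it.
#' @return the filtered table (same class).
#' @export
qc_filter <- function(records, maf_min = 0.01, info_min = 0.80,
                      drop_strand_ambiguous = TRUE, missing_pass = FALSE) {
  keep <- rep(TRUE, nrow(records))
  keep <- keep & records$ref %in% c("A", "C", "G", "T") &
    records$alt %in% c("A", "C", "G", "T") & records$ref != records$alt
  if (!is.null(maf_min)) {
    stopifnot(maf_min >= 0, maf_min <= 1)
    f <- !is.na(records$maf) & records$maf > maf_min
    if (missing_pass) f <- f | is.na(records$maf)
    keep <- keep & f
  }
  if (!is.null(info_min)) {
    stopifnot(info_min >= 0, info_min <= 1)
    f <- !is.na(records$info) & records$info > info_min
    if (missing_pass) f <- f | is.na(records$info)
    keep <- keep & f
  }
  if (drop_strand_ambiguous) {
    pair <- paste0(records$ref, records$alt)
    keep <- keep & !pair %in% c("AT", "TA", "CG", "GC")
  }
  records[keep, ]
}

# join key robust to ref/alt orientation: chr:pos:sorted allele pair
variant_key <- function(chrom, pos, ref, alt) {
  a1 <- pmin(ref, alt)
  a2 <- pmax(ref, alt)
  paste(chrom, pos, a1, a2, sep = ":")
}

#' Harmonize summary statistics across traits
#'
#' Inner-joins T per-trait tables on chromosome, position and the unordered
#' allele pair, then aligns effect orientation to the first trait: when a
#' trait's ref/alt are swapped relative to trait 1 its z (and beta) are
#' negated; variants whose alleles match neither orientation are dropped
#' and counted. Output rows are (chrom, pos) sorted.
#'
#' @param tables list of T >= 2 QC-filtered `sumstats` tables.
#' @param trait_names optional character vector naming the traits.
#' @return an object of class `multi_sumstats`: a list with `trait_names`,
#'   `variants` (data.table: variant_id, chrom, pos, ref, alt), `z` (M x T
#'   matrix), `n` (M x T matrix of per-variant sample sizes) and
#'   `n_per_trait` (length-T vector of the per-trait medians).
#' @export
harmonize <- function(tables, trait_names = NULL) {
  T <- length(tables)
  if (T < 2) stop("harmonize needs at least two traits")
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(T))
  keyed <- lapply(tables, function(tb) {
    tb <- data.table::as.data.table(tb)
    tb$.key <- variant_key(tb$chrom, tb$pos, tb$ref, tb$alt)
    tb[!duplicated(tb$.key), ]
  })
  common <- Reduce(intersect, lapply(keyed, function(tb) tb$.key))
  if (length(common) == 0) stop("no variants shared across all traits")
  base <- keyed[[1]][match(common, keyed[[1]]$.key), ]
  ord <- order(base$chrom, base$pos)
  base <- base[ord, ]
  common <- base$.key
  M <- length(common)
  z <- matrix(NA_real_, M, T, dimnames = list(NULL, trait_names))
  nmat <- matrix(NA_real_, M, T, dimnames = list(NULL, trait_names))
  z[, 1] <- base$z
  nmat[, 1] <- base$n
  keep <- rep(TRUE, M)
  n_flipped <- 0L
  for (t in seq_len(T)[-1]) {
    tb <- keyed[[t]][match(common, keyed[[t]]$.key), ]
    same <- tb$ref == base$ref & tb$alt == base$alt
    swap <- tb$ref == base$alt & tb$alt == base$ref
    z[, t] <- ifelse(swap, -tb$z, tb$z)
    nmat[, t] <- tb$n
    keep <- keep & (same | swap)
    n_flipped <- n_flipped + sum(swap, na.rm = TRUE)
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("harmonize: dropped %d variant(s) with inconsistent alleles",
                    n_dropped))
  if (n_flipped > 0)
    message(sprintf("harmonize: flipped effect direction for %d record(s)",
                    n_flipped))
  variants <- data.table::data.table(
    variant_id = base$variant_id, chrom = base$chrom, pos = base$pos,
    ref = base$ref, alt = base$alt)[keep, ]
  structure(list(trait_names = trait_names, variants = variants,
                 z = z[keep, , drop = FALSE], n = nmat[keep, , drop = FALSE],
                 n_per_trait = apply(nmat[keep, , drop = FALSE], 2,
                                     stats::median),
                 n_dropped_alleles = n_dropped),
            class = "multi_sumstats")
}

#' @export
print.multi_sumstats <- function(x, ...) {
  cat(sprintf("Harmonized summary statistics: %d variant(s) x %d trait(s)\n",
              nrow(x$z), length(x$trait_names)))
  cat("  traits:", paste(x$trait_names, collapse = ", "), "\n")
  invisible(x)
}

#' Write a harmonized multi-trait table
#'
#' Tab-delimited with columns variant_id, chrom, pos, ref, alt,
#' `z_<trait>`... and `n_<trait>`....
#'
#' @param x a `multi_sumstats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multi_sumstats <- function(x, path) {
  out <- data.table::as.data.table(x$variants)
  for (i in seq_along(x$trait_names))
    out[[paste0("z_", x$trait_names[i])]] <- x$z[, i]
  for (i in seq_along(x$trait_names))
    out[[paste0("n_", x$trait_names[i])]] <- x$n[, i]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
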