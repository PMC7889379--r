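#' Subject identifiers of a family data set
#'
#' @param data a `family_data_set`.
#' @return character vector, one id per stacked subject row.
#' @export
subject_ids <- function(data) {
  if (!is.null(data$iid)) return(data$iid)
  paste0(rep(data$fid, data$n_vec), "_", sequence(data$n_vec))
}

#' Write simulated data as VCF + FAM + phenotype TSV
#'
#' Emits a minimal VCF 4.2 file (unphased GT genotypes, one ALT allele
#' per site), a PLINK-style FAM file (trio structure: rows 1-2 of each
#' family are the parents, row 3 the child), and a tab-separated
#' phenotype/covariate table, so simulator output round-trips through
#' [analyze_region()].
#'
#' @param data a `family_data_set` produced by [simulate_study()] (or of
#'   the same trio layout).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the three file paths.
#' @export
write_study_files <- function(data, dir, prefix = "region") {
  stopifnot(inherits(data, "family_data_set"))
  if (!all(data$n_vec == 3L))
    stop("file writers currently support trio-structured data")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- subject_ids(data)
  vcf <- file.path(dir, paste0(prefix, ".vcf"))
  fam <- file.path(dir, paste0(prefix, ".fam"))
  phe <- file.path(dir, paste0(prefix, ".pheno.tsv"))

  p <- data$p
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##source=famkat-simulator",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(p), function(l) {
    paste(c("1", l * 100L, paste0("var", l), "A", "T", ".", ".", ".", "GT",
            gt_code[data$G[, l] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), vcf)

  fidv <- rep(data$fid, data$n_vec)
  pat <- mat <- rep("0", length(ids))
  sex <- rep(0L, length(ids))
  child <- cumsum(data$n_vec)               # third row of each trio
  father <- child - 2L; mother <- child - 1L
  pat[child] <- ids[father]; mat[child] <- ids[mother]
  sex[father] <- 1L; sex[mother] <- 2L
  utils::write.table(data.frame(fidv, ids, pat, mat, sex, -9),
                     fam, quote = FALSE, row.names = FALSE, col.names = FALSE)

  phen <- data.frame(FID = fidv, IID = ids, data$Y,
                     data$X[, -1, drop = FALSE])
  colnames(phen) <- c("FID", "IID", paste0("trait", seq_len(data$K)),
                      paste0("cov", seq_len(data$q)))
  utils::write.table(phen, phe, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(c(vcf = vcf, fam = fam, pheno = phe))
}

#' Read genotype dosages from a VCF file
#'
#' Parses GT fields via the vcfR package and returns a dosage matrix
#' (individuals x variants), counting ALT alleles.
#'
#' @param path VCF path.
#' @return list with `G` (dosage matrix, rownames = sample ids) and
#'   `pos` (data.frame chrom/pos/id).
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  })
  G <- t(dos)
  fix <- vcfR::getFIX(v)
  list(G = G,
       pos = data.frame(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        id = fix[, "ID"], stringsAsFactors = FALSE))
}

#' Read a phenotype/covariate TSV
#'
#' Expected layout: columns `FID`, `IID`, then `n_traits` trait columns,
#' then covariate columns (the intercept is added downstream).
#'
#' @param path file path.
#' @param n_traits number of trait columns following IID.
#' @return data.frame.
#' @export
read_pheno_tsv <- function(path, n_traits) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2 + n_traits)
    stop("phenotype table must have FID, IID and ", n_traits, " trait columns")
  d$FID <- as.character(d$FID); d$IID <- as.character(d$IID)
  d
}

#' Write association results as TSV
#'
#' @param results a `famkat_results` object or a data.frame of stacked
#'   results.
#' @param path output path.
#' @param region optional region label column.
#' @export
write_results_tsv <- function(results, path, region = NA_character_) {
  df <- if (inherits(results, "famkat_results")) as.data.frame(results) else results
  if (!is.null(region) && !"region" %in% names(df))
    df <- cbind(region = region, df)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
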