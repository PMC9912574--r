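#' Read a SNP map CSV (columns snp, chrom, pos)
#' @param path file path.
#' @export
read_snp_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(map) <- tolower(names(map))
  stopifnot(all(c("snp", "chrom", "pos") %in% names(map)))
  map$pos <- as.integer(map$pos)
  map
}

#' Read genotypes in the PLINK RAW dialect
#'
#' Header `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP
#' (named `snp_counted-allele`), entries 0/1/2 counts of the counted allele,
#' `NA` = missing. Animal ids are taken from IID.
#'
#' @param path RAW file path.
#' @param map SNP map data.frame (see [read_snp_map()]).
#' @return a [geno_matrix()] object.
#' @export
read_genotypes_raw <- function(path, map) {
  raw <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           na.strings = "NA")
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  stopifnot(all(fixed %in% names(raw)))
  snp_cols <- setdiff(names(raw), fixed)
  M <- as.matrix(raw[, snp_cols, drop = FALSE])
  colnames(M) <- sub("_[ACGT0-9]+$", "", snp_cols)
  rownames(M) <- as.character(raw$IID)
  storage.mode(M) <- "integer"
  geno_matrix(M, map)
}

#' Read genotypes in the fixed-width dialect
#'
#' Each line: animal id, whitespace, then a contiguous string over {0,1,2,5}
#' with 5 = missing; SNP order follows the map (chrom, pos).
#'
#' @inheritParams read_genotypes_raw
#' @export
read_genotypes_fixed <- function(path, map) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- regmatches(lines, regexpr("^\\S+", lines))
  genos <- trimws(substring(lines, nchar(parts) + 1))
  map <- map[order(map$chrom, map$pos), , drop = FALSE]
  n_snp <- nrow(map)
  stopifnot(all(nchar(genos) == n_snp))
  M <- matrix(as.integer(unlist(strsplit(genos, ""), use.names = FALSE)),
              nrow = length(lines), ncol = n_snp, byrow = TRUE)
  M[M == 5L] <- NA_integer_
  rownames(M) <- parts
  colnames(M) <- as.character(map$snp)
  geno_matrix(M, map)
}

#' Write genotypes in the PLINK RAW dialect
#' @param g a [geno_matrix()] object.
#' @param path output path.
#' @param counted_allele allele letter appended to SNP column names.
#' @export
write_genotypes_raw <- function(g, path, counted_allele = "A") {
  M <- g$M
  hdr <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
           paste0(colnames(M), "_", counted_allele))
  body <- cbind("0", g$ids, "0", "0", "0", "-9",
                matrix(ifelse(is.na(M), "NA", as.character(M)), nrow = nrow(M)))
  writeLines(c(paste(hdr, collapse = " "),
               apply(body, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' Read a phenotype CSV
#'
#' Columns: `animal`, `family`, `line`, `hatch_year`, `harvest_group`, `age`,
#' plus one column per trait; empty cells = missing.
#' @param path file path.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("family", "line", "hatch_year", "harvest_group"),
                        names(df)))
    df[[col]] <- as.character(df[[col]])
  df$animal <- as.character(df$animal)
  df
}

#' Write a validation report as TSV (method, statistic, value, n)
#' @param reports list of validation reports (see the validation functions).
#' @param path output path.
#' @export
write_validation_tsv <- function(reports, path) {
  rows <- do.call(rbind, lapply(reports, function(r) {
    stats <- r[setdiff(names(r), c("method", "n"))]
    stats <- stats[vapply(stats, function(v) is.numeric(v) && length(v) == 1,
                          logical(1))]
    data.frame(method = r$method, statistic = names(stats),
               value = unlist(stats), n = r$n, row.names = NULL)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest (seed, config hash, package version) as JSON-ish text
#' @param path output path.
#' @param seed integer seed of the run.
#' @param config list; deparsed and hashed into the manifest.
#' @export
write_manifest <- function(path, seed, config = list()) {
  cfg <- paste(deparse(config), collapse = "")
  lines <- c("{",
             sprintf('  "package": "troutGS %s",',
                     as.character(utils::packageVersion("troutGS"))),
             sprintf('  "r_version": "%s",', R.version.string),
             sprintf('  "seed": %d,', as.integer(seed)),
             sprintf('  "config_hash": %.0f', sum(utf8ToInt(cfg) *
                       seq_along(utf8ToInt(cfg)))),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys must be arguments of [sim_config()]; an unknown key is an
#' error naming that key. The seed is mandatory.
#'
#' @param path YAML file path.
#' @return a [sim_config()] object.
#' @export
sim_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$seed)) stop("a seed is mandatory")
  do.call(sim_config, cfg)
}
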