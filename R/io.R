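# Parsing and writing of genotype matrices (CSV / VCF / HapMap), long-format
# phenotype tables, and run manifests.

#' Read a genotype matrix from CSV, VCF or HapMap
#'
#' Produces \{-1, 0, 1\} minor-allele-dosage codes (reference/major-allele
#' homozygote = -1, heterozygote = 0, minor homozygote = 1) and applies the
#' standard panel filters: multi-allelic sites dropped, markers with more
#' than `missing_max` missing calls dropped, then MAF > `maf_min` and
#' heterozygosity < `het_max`. Remaining missing entries are imputed to the
#' marker mean rounded to the nearest legal code. The filter report is kept
#' in the returned object.
#'
#' @param path Input file.
#' @param format `"csv"` (genotype ids in the first column, marker ids in
#'   the header, coded values), `"vcf"` (GT field, requires the vcfR
#'   package) or `"hapmap"` (tab format, two-letter or IUPAC genotype
#'   calls).
#' @param maf_min,het_max,missing_max Filter thresholds.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("csv", "vcf", "hapmap"),
                           maf_min = 0.05, het_max = 0.05,
                           missing_max = 0.2) {
  format <- match.arg(format)
  raw <- switch(format,
                csv = read_genotypes_csv(path),
                vcf = read_genotypes_vcf(path),
                hapmap = read_genotypes_hapmap(path))
  codes <- raw$codes
  dropped_multi <- raw$dropped_multiallelic
  # missingness filter, then rounded mean imputation
  miss_rate <- colMeans(is.na(codes))
  drop_miss <- miss_rate > missing_max
  codes <- codes[, !drop_miss, drop = FALSE]
  if (ncol(codes) == 0L)
    stop("no markers left after the missingness filter (> ",
         missing_max * 100, "% missing)")
  n_imputed <- sum(is.na(codes))
  if (n_imputed > 0) {
    for (j in which(colSums(is.na(codes)) > 0L)) {
      mj <- round(mean(codes[, j], na.rm = TRUE))
      codes[is.na(codes[, j]), j] <- max(-1L, min(1L, as.integer(mj)))
    }
  }
  geno <- genotype_matrix(codes)
  geno <- filter_markers(geno, maf_min = maf_min, het_max = het_max)
  geno$report <- c(geno$report,
                   list(dropped_multiallelic = dropped_multi,
                        dropped_missing = sum(drop_miss),
                        imputed_entries = n_imputed))
  geno
}

read_genotypes_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  codes <- as.matrix(d)
  if (!is.numeric(codes)) {
    bad <- which(!grepl("^\\s*(-1|0|1|NA)?\\s*$", as.matrix(d)))[1]
    stop("malformed genotype code near entry ", bad, " of ", path)
  }
  if (!all(codes %in% c(-1, 0, 1, NA)))
    stop("genotype CSV must contain only -1, 0, 1 or NA")
  storage.mode(codes) <- "integer"
  list(codes = codes, dropped_multiallelic = 0L)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids))
    ids <- paste0("M", seq_len(nrow(gt)))
  # alt-allele dosage 0/1/2 -> centred codes; then orient to the minor allele
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  unknown <- !is.na(clean) & !(clean %in% c("0/0", "0/1", "1/0", "1/1",
                                            "./."))
  if (any(unknown)) {
    bad <- which(unknown, arr.ind = TRUE)[1, ]
    stop("malformed GT record at marker ", ids[bad[1]], " (VCF data line ",
         bad[1], ")")
  }
  codes <- t(dose) - 1L   # genotypes in rows
  colnames(codes) <- ids
  rownames(codes) <- colnames(gt)
  # flip markers where the ALT allele is the major one
  af <- colMeans(codes + 1L, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  codes[, flip] <- -codes[, flip]
  list(codes = codes, dropped_multiallelic = sum(multi))
}

# IUPAC single-letter heterozygote codes
.iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

read_genotypes_hapmap <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE, comment.char = "")
  if (ncol(d) < 12L) stop("not a HapMap table: fewer than 12 columns")
  ids <- d[[1]]
  alleles <- strsplit(d[["alleles"]], "/", fixed = TRUE)
  multi <- lengths(alleles) != 2L
  samples <- names(d)[12:ncol(d)]
  codes <- matrix(NA_integer_, length(samples), nrow(d),
                  dimnames = list(samples, ids))
  for (i in which(!multi)) {
    a <- alleles[[i]][1]; b <- alleles[[i]][2]
    calls <- toupper(as.character(d[i, 12:ncol(d)]))
    calls[calls %in% names(.iupac_het)] <-
      .iupac_het[calls[calls %in% names(.iupac_het)]]
    calls[nchar(calls) == 1L & calls %in% c(a, b)] <-
      paste0(calls[nchar(calls) == 1L & calls %in% c(a, b)],
             substr(calls[nchar(calls) == 1L & calls %in% c(a, b)], 1, 1))
    v <- rep(NA_integer_, length(calls))
    v[calls == paste0(a, a)] <- -1L
    v[calls %in% c(paste0(a, b), paste0(b, a))] <- 0L
    v[calls == paste0(b, b)] <- 1L
    codes[, i] <- v
  }
  codes <- codes[, !multi, drop = FALSE]
  af <- colMeans(codes + 1L, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  codes[, flip] <- -codes[, flip]
  list(codes = codes, dropped_multiallelic = sum(multi))
}

#' Write a genotype matrix as CSV or plain-text VCF
#'
#' CSV: genotype ids in the first column, marker ids in the header. VCF:
#' minimal 4.2 file with GT-only fields and synthetic chromosome/position
#' metadata (one synthetic chromosome, positions in marker order).
#'
#' @param geno A `genotype_matrix`.
#' @param path Output file.
#' @param format `"csv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(geno, "genotype_matrix"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(geno$codes), path, row.names = TRUE)
    return(invisible(path))
  }
  gt_map <- c(`-1` = "0/0", `0` = "0/1", `1` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##source=gxepredict",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", geno$genotype_ids), collapse = "\t"))
  body <- vapply(seq_along(geno$marker_ids), function(j) {
    paste(c("1", j, geno$marker_ids[j], "A", "T", ".", "PASS", ".", "GT",
            gt_map[as.character(geno$codes[, j])]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' Expects the header `genotype_id,environment,year,replicate,trait,value`.
#' Duplicate design cells and non-numeric values are errors with row numbers;
#' if a genotype matrix is supplied, ids are cross-checked and unmatched
#' records excluded with a warning.
#'
#' @param path CSV file.
#' @param genotypes Optional `genotype_matrix` for id cross-checking.
#' @return A `trial_observations` data frame; the id-overlap report is in
#'   `attr(, "id_report")`.
#' @export
read_phenotypes <- function(path, genotypes = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype_id", "environment", "year", "replicate", "trait",
            "value")
  if (!identical(names(d)[seq_along(need)], need))
    stop("phenotype file must have header ", paste(need, collapse = ","))
  if (is.character(d$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(d$value))) &
                   !is.na(d$value))
    if (length(bad))
      stop("non-numeric phenotype value at data row ",
           paste(utils::head(bad, 5), collapse = ", "))
    d$value <- as.numeric(d$value)
  }
  key <- do.call(paste, c(d[c("genotype_id", "environment", "year",
                              "replicate", "trait")], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate design cells at data row(s) ",
         paste(utils::head(dup, 10), collapse = ", "))
  }
  report <- NULL
  if (!is.null(genotypes)) {
    known <- d$genotype_id %in% genotypes$genotype_ids
    report <- list(n_records = nrow(d), n_unmatched = sum(!known),
                   unmatched_ids = unique(d$genotype_id[!known]))
    if (any(!known)) {
      warning(sum(!known), " record(s) with genotype ids absent from the ",
              "genotype matrix were excluded")
      d <- d[known, , drop = FALSE]
    }
  }
  out <- structure(d, class = c("trial_observations", "data.frame"))
  attr(out, "id_report") <- report
  out
}

#' Write a long-format phenotype table
#' @param obs A `trial_observations` data frame.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(obs, path) {
  utils::write.csv(obs[c("genotype_id", "environment", "year", "replicate",
                         "trait", "value")], path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest next to an output file
#'
#' Records the seed, a hash of the configuration, package version and
#' timestamp in a small JSON sidecar (`<path>.manifest.json`), so reruns are
#' traceable to their configuration.
#'
#' @param path Output file the manifest describes.
#' @param config List of configuration values (seeds included).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(path, config = list()) {
  cfg_txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  manifest <- list(
    file = basename(path),
    config_hash = sprintf("%08x",
                          sum(utf8ToInt(cfg_txt) *
                                (seq_along(utf8ToInt(cfg_txt)) %% 97 + 1)) %%
                            .Machine$integer.max),
    seed = config$seed,
    package = as.character(utils::packageVersion("gxepredict")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mpath <- paste0(path, ".manifest.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
  } else {
    writeLines(paste0('{"file":"', manifest$file, '","config_hash":"',
                      manifest$config_hash, '"}'), mpath)
  }
  invisible(mpath)
}
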