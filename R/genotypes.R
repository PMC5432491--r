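#' Read a genotype matrix for inbred lines
#'
#' Reads genotypes of fully homozygous (inbred / doubled-haploid) lines and
#' aligns them to a marker map.  Two formats are supported:
#'
#' * a TSV matrix: first column `sample`, remaining columns named by
#'   marker id, cells in `{0, 1, NA}` (0 = reference allele, 1 = alternate);
#' * a VCF (v4.x, plain text or gzip): biallelic SNP sites are converted to
#'   the same 0/1/NA coding.  Because the lines are nominally homozygous,
#'   heterozygous calls are residual artefacts and are converted to missing
#'   (and counted in the QC summary) rather than rejected.  Non-biallelic
#'   sites are dropped with a count.
#'
#' Markers present in the file but absent from the map are a hard error
#' (the map defines the coordinate system); map markers absent from the
#' file become all-missing columns, counted in the QC summary.  Sample
#' order follows the file; marker order always follows the map.
#'
#' @param path input file; `.vcf`/`.vcf.gz` selects the VCF reader.
#' @param map a [marker_map()] defining marker order.
#' @return A list with elements
#'   \describe{
#'     \item{calls}{integer matrix, samples x markers (map order), values
#'       0/1/NA, dimnames set to sample and marker ids.}
#'     \item{qc}{list: `n_het_to_missing`, `n_sites_dropped`,
#'       `n_markers_absent`, `missing_by_sample` (named fraction).}
#'   }
#' @export
read_genotypes <- function(path, map) {
  validate_marker_map(map)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_genotypes_vcf(path, map)
  } else {
    read_genotypes_tsv(path, map)
  }
}

read_genotypes_tsv <- function(path, map) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "sample") {
    stop("genotype TSV must have a leading 'sample' column")
  }
  samples <- as.character(df$sample)
  file_markers <- names(df)[-1]
  unknown <- setdiff(file_markers, map$marker_id)
  if (length(unknown)) {
    stop("marker id(s) not in map: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  bad <- m[!is.na(m) & !(m %in% c(0L, 1L))]
  if (length(bad)) stop("genotype calls must be 0, 1 or NA")
  calls <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(map),
                  dimnames = list(samples, map$marker_id))
  calls[, file_markers] <- m
  rownames(calls) <- samples
  finish_genotypes(calls, map,
                   n_het = 0L,
                   n_dropped = 0L,
                   n_absent = length(setdiff(map$marker_id, file_markers)))
}

read_genotypes_vcf <- function(path, map) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  n_dropped <- sum(!bi)
  vcf <- vcf[bi, ]
  ids <- vcfR::getID(vcf)
  if (any(is.na(ids))) stop("VCF sites must carry marker ids in the ID column")
  unknown <- setdiff(ids, map$marker_id)
  if (length(unknown)) {
    stop("marker id(s) not in map: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # sites x samples character; normalise separators and collapse to one code
  gt <- gsub("\\|", "/", gt)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0")] <- 0L
  code[gt %in% c("1/1", "1")] <- 1L
  het <- gt %in% c("0/1", "1/0")
  n_het <- sum(het, na.rm = TRUE)
  calls <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(map),
                  dimnames = list(colnames(gt), map$marker_id))
  calls[, ids] <- t(code)
  finish_genotypes(calls, map,
                   n_het = n_het,
                   n_dropped = n_dropped,
                   n_absent = length(setdiff(map$marker_id, ids)))
}

finish_genotypes <- function(calls, map, n_het, n_dropped, n_absent) {
  miss <- rowMeans(is.na(calls))
  list(calls = calls,
       qc = list(n_het_to_missing = as.integer(n_het),
                 n_sites_dropped = as.integer(n_dropped),
                 n_markers_absent = as.integer(n_absent),
                 missing_by_sample = miss))
}

#' Write a genotype matrix to TSV
#'
#' Writes the `sample` + marker-column TSV read back by [read_genotypes()].
#'
#' @param calls integer samples x markers matrix with dimnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genotypes <- function(calls, path) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)), !is.null(colnames(calls)))
  df <- data.frame(sample = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
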